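make_db <- function(ids, seqs, lineages, focal = FALSE, comparison = FALSE) {
  reference_db(ids, seqs, lineages, focal, comparison)
}

test_that("homology screen applies identity and coverage thresholds", {
  set.seed(20)
  q <- random_aa(200)
  # flip whole blocks so conserved stretches remain (periodic single-site
  # substitution would leave nothing for seed-based search to anchor on,
  # in this engine as in any BLAST-like tool)
  block_flip <- function(s, cycle, keep) {
    x <- strsplit(s, "")[[1]]
    flip <- (seq_along(x) - 1) %% cycle >= keep
    x[flip] <- vapply(x[flip], function(ch) if (ch == "A") "V" else "A",
                      character(1))
    paste(x, collapse = "")
  }
  s50 <- block_flip(q, 8, 4)    # 50% identity in 4-residue blocks
  s25 <- block_flip(q, 16, 4)   # 25% identity in 4-residue blocks
  short <- substr(q, 1, 100)      # identical but only 50% of query length
  db <- make_db(c("hit50", "hit25", "short"), c(s50, s25, short),
                rep("Bacteria;Proteobacteria", 3))
  fam <- seq_records("G|q", "G", q)
  hits <- homology_screen(fam, db)
  expect_equal(hits$subject_id, "hit50")
  expect_gte(hits$query_coverage[1], 0.7)
  # relaxing thresholds only adds hits (screen is monotone)
  relaxed <- homology_screen(fam, db, min_identity = 10, min_coverage = 0.3)
  expect_true(all(hits$subject_id %in% relaxed$subject_id))
  expect_gt(nrow(relaxed), nrow(hits))
  # empty database is valid and yields no hits
  expect_equal(nrow(homology_screen(fam, db[0, ])), 0L)
})

test_that("greedy clustering matches an independent oracle and its invariant", {
  set.seed(21)
  anc <- random_aa(120)
  seqs <- c(setNames(lapply(1:4, function(i) anc), paste0("c1_", 1:4)),
            list(c2 = random_aa(130), c3 = random_aa(110)))
  # push two sequences just under / over the threshold
  near <- strsplit(anc, "")[[1]]
  near[1:4] <- "W"
  seqs$near <- paste(near, collapse = "")   # ~96.7% identity to anc
  far <- strsplit(anc, "")[[1]]
  far[1:12] <- "W"
  seqs$far <- paste(far, collapse = "")     # ~90% identity to anc
  seqs <- vapply(seqs, identity, character(1))
  got <- greedy_cluster(seqs, threshold = 95)
  want <- greedy_oracle(seqs, threshold = 95)
  expect_setequal(names(got$centroids), want$centroids)
  expect_equal(got$membership[names(want$membership)], want$membership)
  # post-hoc invariant: every member is >= threshold to its centroid
  sc <- scoring_scheme("aa")
  for (id in names(got$membership)) {
    cid <- got$membership[[id]]
    if (cid == id) next
    a <- align_local(list(id = id, seq = seqs[[id]]),
                     list(id = cid, seq = seqs[[cid]]), sc)
    expect_gte(a$percent_identity, 95)
  }
  one <- greedy_cluster(setNames(rep(anc, 5), paste0("s", 1:5)))
  expect_length(one$centroids, 1L)
})

test_that("family trees recover planted pairs and need 4 sequences", {
  set.seed(22)
  anc <- random_nt(360)
  other <- random_nt(360)
  fam <- seq_records(
    c("G1|f", "G2|f"), c("G1", "G2"),
    c(translate_seq(evolve_sequence(anc, 0.03)),
      translate_seq(evolve_sequence(anc, 0.03))))
  cents <- c(o1 = translate_seq(evolve_sequence(other, 0.03)),
             o2 = translate_seq(evolve_sequence(other, 0.03)))
  tr <- build_family_tree(fam, cents, n_reps = 20, seed = 1)
  expect_true(is_monophyletic(tr, fam$id))
  expect_true(is_monophyletic(tr, names(cents)))
  expect_error(build_family_tree(fam, cents[1], n_reps = 10), "at least 4")
  ident <- seq_records(paste0("G", 1:4, "|x"), paste0("G", 1:4),
                       rep(strrep("MKVLITGGAG", 12), 4))
  star <- build_family_tree(ident, n_reps = 10, seed = 1)
  expect_equal(sum(star$edge.length), 0)
})

test_that("classification follows the rule order on planted cases", {
  sim <- small_sim()
  orth <- small_orth()
  excl <- group_specific_core(orth$presence, small_config()$clades$focal)
  calls <- classify_origins(orth$families, excl, sim$genomes, sim$db,
                            seed = 2, n_reps = 50)
  tally <- summarize_origins(calls)
  expect_equal(sum(tally), length(excl))
  # planted strata: map each inferred family to its truth stratum
  memb <- family_membership(orth$families)
  truth_origin <- setNames(sim$truth$families$origin,
                           sim$truth$families$family_id)
  got <- vapply(calls, function(x) x$category, character(1))
  planted <- vapply(names(calls), function(fid) {
    truth_origin[[truth_family_of(names(memb)[memb == fid][1])]]
  }, character(1))
  expect_equal(unname(got[planted == "hgt"]),
               rep("hgt", sum(planted == "hgt")))
  expect_equal(unname(got[planted == "divergent"]),
               rep("divergent_ingroup_homolog", sum(planted == "divergent")))
  expect_true(all(got[planted %in% c("novel", "low_identity")] %in%
                    c("clade_specific_novel", "low_identity_unresolved")))
  # donor lineages recovered for hgt calls
  for (fid in names(calls)[got == "hgt"]) {
    expect_equal(calls[[fid]]$donor_lineage, "Thermoplasmatales")
    expect_false(is.null(calls[[fid]]$tree))
    expect_gte(calls[[fid]]$support, 0.7)
  }
  # donor lineage present iff category is hgt
  for (cl in calls)
    expect_equal(!is.na(cl$donor_lineage), cl$category == "hgt")
})

test_that("a family with no database homologue is clade-specific novel", {
  fam <- seq_records("G|q", "G", random_aa(150))
  call <- classify_origin(fam, make_db(character(0), character(0),
                                       character(0)))
  expect_equal(call$category, "clade_specific_novel")
  expect_equal(call$n_db_homologues, 0L)
  expect_true(is.na(call$donor_lineage))
})

test_that("origin tallies are exhaustive and zero on empty input", {
  z <- summarize_origins(list())
  expect_equal(sum(z), 0L)
  expect_setequal(names(z),
                  c("clade_specific_novel", "low_identity_unresolved",
                    "divergent_ingroup_homolog", "hgt", "ambiguous"))
})

test_that("deepest shared lineage label is the donor call", {
  expect_equal(
    pancore:::deepest_shared_lineage(
      c("Archaea;Euryarchaeota;Thermoplasmatales",
        "Archaea;Euryarchaeota;Thermoplasmatales")),
    "Thermoplasmatales")
  expect_equal(
    pancore:::deepest_shared_lineage(
      c("Archaea;Euryarchaeota;Thermoplasmatales",
        "Archaea;Euryarchaeota;Methanosarcinales")),
    "Euryarchaeota")
  expect_true(is.na(pancore:::deepest_shared_lineage(
    c("Archaea;X", "Bacteria;Y"))))
})
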