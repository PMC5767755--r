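two_identical_genomes <- function() {
  s <- strrep("MKVLITGGAGFIGSHLVDRL", 10)
  genome_set(
    contigs = list(),
    proteomes = list(A = seq_records("A|p1", "A", s),
                     B = seq_records("B|p1", "B", s)))
}

test_that("all_vs_all reports self and reciprocal hits deterministically", {
  gs <- two_identical_genomes()
  hits <- all_vs_all(gs)
  # 2 self hits + 2 cross hits
  expect_equal(nrow(hits), 4L)
  expect_setequal(paste(hits$qseqid, hits$sseqid),
                  c("A|p1 A|p1", "B|p1 B|p1", "A|p1 B|p1", "B|p1 A|p1"))
  expect_true(all(hits$pident == 100))
  expect_true(all(hits$evalue <= 1e-5))
  # 1-based inclusive coordinates in the tabular layout
  expect_true(all(hits$qstart == 1 & hits$qend == 200))
  expect_identical(hits, all_vs_all(gs))
})

test_that("unrelated proteins produce no cross hits", {
  set.seed(5)
  gs <- genome_set(
    contigs = list(),
    proteomes = list(A = seq_records("A|p1", "A", random_aa(200)),
                     B = seq_records("B|p1", "B", random_aa(200))))
  hits <- all_vs_all(gs)
  expect_true(all(hits$qgenome == hits$sgenome))
})

test_that("graph edges follow ortholog / in-paralog / co-ortholog rules", {
  set.seed(6)
  base <- random_nt(450)
  a1 <- translate_seq(base)
  a2 <- translate_seq(evolve_sequence(base, 0.03))
  b1 <- translate_seq(evolve_sequence(base, 0.22))
  gs <- genome_set(
    contigs = list(),
    proteomes = list(A = seq_records(c("A|a1", "A|a2"), "A", c(a1, a2)),
                     B = seq_records("B|b1", "B", b1)))
  g <- build_graph(all_vs_all(gs), gs)
  expect_equal(nrow(g$edges), 3L)
  # a1/a2 are mutually closer than either is to b1 -> in-paralog edge
  ip <- g$edges[g$edges$kind == "in-paralog", ]
  expect_equal(nrow(ip), 1L)
  expect_setequal(c(ip$from, ip$to), c("A|a1", "A|a2"))
  # exactly one reciprocal best hit across genomes -> ortholog edge
  ortho <- g$edges[g$edges$kind == "ortholog", ]
  expect_equal(nrow(ortho), 1L)
  expect_true("B|b1" %in% c(ortho$from, ortho$to))
  # the remaining A protein joins b1 as a co-ortholog
  co <- g$edges[g$edges$kind == "co-ortholog", ]
  expect_equal(nrow(co), 1L)
  expect_true("B|b1" %in% c(co$from, co$to))
  expect_false(setequal(c(co$from, co$to), c(ortho$from, ortho$to)))
  expect_true(all(is.finite(g$edges$weight)))
  bad <- all_vs_all(gs)
  bad$qseqid[1] <- "A|ghost"
  expect_error(build_graph(bad, gs), "absent")
})

test_that("no reciprocal hit means no edge", {
  set.seed(7)
  gs <- genome_set(
    contigs = list(),
    proteomes = list(A = seq_records("A|p1", "A", random_aa(180)),
                     B = seq_records("B|p1", "B", random_aa(180))))
  g <- build_graph(all_vs_all(gs), gs)
  expect_equal(nrow(g$edges), 0L)
  fams <- mcl_cluster(g)
  expect_equal(length(fams), 2L)
})

test_that("MCL separates disconnected triangles", {
  nodes <- data.frame(id = letters[1:6], genome = rep(c("g1", "g2"), 3))
  tri <- function(v) data.frame(from = v[c(1, 2, 1)], to = v[c(2, 3, 3)],
                                kind = "ortholog", weight = 1)
  g <- structure(list(nodes = nodes,
                      edges = rbind(tri(letters[1:3]), tri(letters[4:6]))),
                 class = "similarity_graph")
  fams <- mcl_cluster(g)
  expect_equal(length(fams), 2L)
  expect_equal(canon_partition(fams),
               canon_partition(list(letters[1:3], letters[4:6])))
})

test_that("families partition the protein set and refine components", {
  orth <- small_orth()
  prot <- unlist(orth$families, use.names = FALSE)
  expect_equal(sort(prot), sort(pancore:::all_proteins(small_sim()$genomes)$id))
  expect_false(anyDuplicated(prot) > 0)
  # clustering refines connected components
  g <- igraph::graph_from_data_frame(
    orth$graph$edges[, c("from", "to")], directed = FALSE,
    vertices = orth$graph$nodes$id)
  comp <- igraph::components(g)$membership
  for (fam in orth$families)
    expect_equal(length(unique(comp[fam])), 1L)
  # presence matrix column sums equal proteome sizes
  expect_equal(unname(colSums(orth$presence)),
               unname(vapply(small_sim()$genomes$proteomes, nrow, integer(1))))
})

test_that("the partition is invariant under protein relabelling", {
  set.seed(8)
  sim <- small_sim()
  gs <- sim$genomes
  # reverse the row order of every proteome
  gs2 <- genome_set(gs$contigs,
                    lapply(gs$proteomes, function(p) p[rev(seq_len(nrow(p))), ]))
  f1 <- infer_families(gs)$families
  f2 <- infer_families(gs2)$families
  expect_equal(canon_partition(f1), canon_partition(f2))
})

test_that("a single genome clusters into in-paralog groups", {
  set.seed(9)
  base <- random_nt(420)
  gs <- genome_set(
    contigs = list(),
    proteomes = list(A = seq_records(
      c("A|p1", "A|p2", "A|p3"), "A",
      c(translate_seq(base), translate_seq(evolve_sequence(base, 0.05)),
        random_aa(140)))))
  fams <- infer_families(gs)$families
  expect_equal(canon_partition(fams),
               canon_partition(list(c("A|p1", "A|p2"), "A|p3")))
})

test_that("low-divergence simulated families are recovered exactly", {
  orth <- small_orth()
  memb <- family_membership(orth$families)
  expect_equal(mclust::adjustedRandIndex(memb, truth_family_of(names(memb))),
               1)
})

test_that("families TSV lists every protein with its genome", {
  orth <- small_orth()
  f <- tempfile(fileext = ".tsv")
  write_families_tsv(orth$families, small_sim()$genomes, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), sum(lengths(orth$families)))
  expect_true(all(tab$genome_id == sub("\\|.*$", "", tab$protein_id)))
})
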