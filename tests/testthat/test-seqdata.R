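test_that("FASTA round-trip preserves ids and sequences exactly", {
  f <- tempfile(fileext = ".faa")
  recs <- seq_records(c("g1|p1", "g1|p2"), "g1",
                      c("MKVLITGGAGFIG", "MRTWQ"),
                      description = c("first protein", ""))
  write_fasta(recs, f)
  back <- read_fasta(f, "aa")
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
  expect_equal(back$genome_id, c("g1", "g1"))
  expect_equal(back$description, recs$description)
  expect_equal(nchar(back$seq), c(13L, 5L))
  # second round trip is byte-identical
  f2 <- tempfile(fileext = ".faa")
  write_fasta(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("lowercase residues are uppercased with a message", {
  f <- tempfile(fileext = ".fna")
  writeLines(c(">g1|x", "acgTT"), f)
  expect_message(r <- read_fasta(f, "nt"), "uppercased")
  expect_equal(r$seq, "ACGTT")
})

test_that("malformed files and alphabet violations are rejected", {
  f <- tempfile()
  writeLines(c("not fasta at all", "ACGT"), f)
  expect_error(read_fasta(f, "nt"), "malformed|Malformed|valid")
  expect_error(read_fasta(tempfile(), "nt"), "no such file")
  f2 <- tempfile()
  writeLines(c(">g1|x", "MKVLQ"), f2)
  expect_error(read_fasta(f2, "nt"), "alphabet")
  expect_error(seq_records("a", "g", ""), "empty")
  expect_error(seq_records(c("a", "a"), "g", c("MK", "ML")), "unique")
})

test_that("local alignment handles identity and single substitutions", {
  sc <- scoring_scheme("aa")
  a <- list(id = "a", seq = strrep("MKVLITGGAG", 5))
  r <- align_local(a, a, sc)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$query_span, c(0, 50))
  expect_equal(r$subject_span, c(0, 50))
  expect_gt(r$bit_score, 50)
  expect_lt(r$e_value, 1e-10)

  set.seed(1)
  s1 <- random_aa(100)
  s2 <- s1
  substr(s2, 37, 37) <- if (substr(s1, 37, 37) == "A") "C" else "A"
  expect_equal(pairwise_identity(list(seq = s1), list(seq = s2)), 99)
  expect_error(align_local(list(id = "x", seq = ""), a, sc), "empty")
})

test_that("global identity is symmetric, bounded and alphabet-checked", {
  set.seed(2)
  a <- list(seq = random_nt(300))
  b <- list(seq = evolve_sequence(a$seq, 0.2, stop_free = FALSE))
  sc <- scoring_scheme("nt")
  ab <- pairwise_identity(a, b, "nt", sc)
  ba <- pairwise_identity(b, a, "nt", sc)
  expect_equal(ab, ba)
  expect_gte(ab, 0); expect_lte(ab, 100)
  expect_equal(pairwise_identity(a, a, "nt", sc), 100)
  expect_error(pairwise_identity(a, list(seq = "MKVLQW"), "nt", sc),
               "alphabet")
})

test_that("simulated pairs match planted divergence within 1.5 points", {
  set.seed(3)
  anc <- random_nt(3000)
  der <- evolve_sequence(anc, 0.15, stop_free = FALSE)
  expected <- 100 * (1 / 4 + 3 / 4 * exp(-4 * 0.15 / 3))
  expect_lt(abs(pairwise_identity(list(seq = anc), list(seq = der), "nt") -
                  expected), 1.5)
})

test_that("ANI is 100 for self and tracks planted divergence", {
  sim <- small_sim()
  self <- compute_ani(sim$genomes, "FOC1", "FOC1")
  expect_equal(self$ani, 100)
  expect_equal(self$fraction_fragments_used, 1)

  v <- compute_ani(sim$genomes, "FOC1", "FOC2")
  id <- sim$truth$identities
  planted <- mean(id$nt_identity[id$g1 == "FOC1" & id$g2 == "FOC2"])
  expect_lt(abs(v$ani - planted), 1)
  # symmetry is by construction: mean of both directions
  v2 <- compute_ani(sim$genomes, "FOC2", "FOC1")
  expect_equal(v$ani, v2$ani)
  expect_error(
    compute_ani(genome_set(
      contigs = list(g1 = seq_records("g1|c", "g1", random_nt(200),
                                      alphabet = "nt")),
      proteomes = list(g1 = seq_records("g1|p", "g1", "MKV"))), "g1", "g1"),
    "fragment")
})

test_that("AAI is 100/100 for self and NA with no reciprocal hits", {
  sim <- small_sim()
  p <- sim$genomes$proteomes$FOC1
  self <- compute_aai(p, p)
  expect_equal(self$aai, 100)
  expect_equal(self$fraction_genes_aligned, 100)

  v <- compute_aai(p, sim$genomes$proteomes$FOC2)
  id <- sim$truth$identities
  planted <- mean(id$aa_identity[id$g1 == "FOC1" & id$g2 == "FOC2"])
  expect_lt(abs(v$aai - planted), 1.5)

  set.seed(4)
  pa <- seq_records("a|x", "a", random_aa(150))
  pb <- seq_records("b|y", "b", random_aa(150))
  none <- compute_aai(pa, pb)
  expect_true(is.na(none$aai))
  expect_equal(none$n_rbh, 0L)
})

test_that("identity dendrograms agglomerate by complete linkage", {
  m2 <- matrix(c(100, 91, 91, 100), 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  t2 <- identity_dendrogram(m2)
  expect_setequal(t2$tip.label, c("a", "b"))
  # single join at distance 9: both tip branches 4.5
  expect_equal(sum(t2$edge.length), 9)

  # two obvious pairs
  lab <- c("a1", "a2", "b1", "b2")
  m4 <- matrix(80, 4, 4, dimnames = list(lab, lab))
  diag(m4) <- 100
  m4["a1", "a2"] <- m4["a2", "a1"] <- 98
  m4["b1", "b2"] <- m4["b2", "b1"] <- 97
  t4 <- identity_dendrogram(m4)
  expect_true(is_monophyletic(t4, c("a1", "a2")))
  expect_true(is_monophyletic(t4, c("b1", "b2")))
  # complete-linkage merge heights are monotone
  hc <- hclust(as.dist(100 - m4), method = "complete")
  expect_true(all(diff(hc$height) >= 0))

  ident <- matrix(100, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  t0 <- identity_dendrogram(ident)
  expect_equal(sum(t0$edge.length), 0)
  expect_error(identity_dendrogram(matrix(1, 2, 3)), "square")
})

test_that("identity matrix TSV round-trips", {
  sim <- small_sim()
  m <- matrix(c(100, 85.5, 85.5, 100), 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  f <- tempfile(fileext = ".tsv")
  write_identity_tsv(m, f)
  expect_equal(read_identity_tsv(f), m)
})
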