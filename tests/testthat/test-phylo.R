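test_that("Poisson-corrected distances follow the closed form", {
  aln <- c(a = strrep("A", 100), b = strrep("A", 100))
  expect_true(all(aa_distance(aln) == 0))

  set.seed(15)
  s <- random_aa(100)
  t <- s
  pos <- sample(100, 10)
  for (p in pos) substr(t, p, p) <- if (substr(s, p, p) == "W") "Y" else "W"
  d <- aa_distance(c(a = s, b = t))
  expect_equal(d["a", "b"], -log(0.9))

  # gapped columns are excluded pairwise
  aln2 <- c(a = "AAAA-AA", b = "AAAAAA-")
  expect_equal(aa_distance(aln2)["a", "b"], 0)

  # saturation sentinel
  aln3 <- c(a = strrep("A", 50), b = strrep("W", 50))
  expect_equal(aa_distance(aln3)["a", "b"], -log(0.01))

  # random alignments match a direct counting oracle
  set.seed(16)
  for (trial in 1:5) {
    aln4 <- setNames(replicate(4, random_aa(60)), letters[1:4])
    d4 <- aa_distance(aln4)
    for (i in 1:3) for (j in (i + 1):4) {
      p <- mean(strsplit(aln4[i], "")[[1]] != strsplit(aln4[j], "")[[1]])
      expect_equal(d4[i, j], if (p >= 0.99) -log(0.01) else -log(1 - p))
    }
  }
})

test_that("NJ recovers 4-taxon additive trees with exact branch lengths", {
  # ((A,B),(C,D)) with branches A=1, B=2, internal=3, C=4, D=5
  lab <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- 3; d["A", "C"] <- 8; d["A", "D"] <- 9
  d["B", "C"] <- 9; d["B", "D"] <- 10; d["C", "D"] <- 9
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_equal(sum(tr$edge.length), 1 + 2 + 3 + 4 + 5)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[lab, lab], d)
})

test_that("3 taxa give the unique closed-form solution", {
  lab <- c("a", "b", "c")
  d <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  # x+y=5, x+z=7, y+z=8 -> x=2, y=3, z=5
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[lab]), c(2, 3, 5))
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("degenerate all-zero matrices give zero-length stars", {
  lab <- letters[1:4]
  tr <- nj_tree(matrix(0, 4, 4, dimnames = list(lab, lab)))
  expect_equal(sum(tr$edge.length), 0)
  expect_setequal(tr$tip.label, lab)
})

test_that("bootstrap supports are reproducible frequencies in [0,1]", {
  set.seed(17)
  anc <- random_nt(300)
  tips <- list(a = anc, b = evolve_sequence(anc, 0.05, stop_free = FALSE))
  tips$c <- evolve_sequence(anc, 0.4, stop_free = FALSE)
  tips$d <- evolve_sequence(tips$c, 0.05, stop_free = FALSE)
  aln <- vapply(tips, translate_seq, character(1))
  t1 <- bootstrap_nj(aln, n_reps = 50, seed = 5)
  t2 <- bootstrap_nj(aln, n_reps = 50, seed = 5)
  expect_equal(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 1))
  expect_true(is_monophyletic(t1, c("a", "b")))
  # identical sequences: supports still attached, zero-length branches
  same <- c(x = strrep("MKV", 40), y = strrep("MKV", 40),
            z = strrep("MKV", 40), w = strrep("MKV", 40))
  t0 <- bootstrap_nj(same, n_reps = 10, seed = 1)
  expect_equal(sum(t0$edge.length), 0)
  expect_length(t0$node.label, t0$Nnode)
})

test_that("newick serialisation round-trips topology, lengths and supports", {
  set.seed(18)
  tr <- ape::rtree(8)
  tr$node.label <- round(runif(tr$Nnode), 3)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  o <- match(back$tip.label, tr$tip.label)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_equal(as.numeric(back$node.label), as.numeric(tr$node.label))
})

test_that("monophyly and sister groups behave on a known rooted tree", {
  tr <- ape::read.tree(text = "(((A:1,B:1)ab:1,C:2)abc:1,(D:1,E:1)de:2)r;")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, tr$tip.label))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
  sis <- sister_group(tr, c("A", "B"))
  expect_equal(as.character(sis), "C")
  expect_setequal(as.character(sister_group(tr, c("D", "E"))),
                  c("A", "B", "C"))
  expect_error(sister_group(tr, c("A", "C")), "not monophyletic")
  expect_error(sister_group(tr, tr$tip.label), "no sister")
})

test_that("marker concatenation tiles widths and gap-fills absences", {
  a1 <- c(g1 = "MKV", g2 = "MRV", g3 = "MKI")
  a2 <- c(g1 = "WWYY", g2 = "WWYF")  # g3 missing
  conc <- concatenate_markers(list(m1 = a1, m2 = a2))
  expect_equal(unname(nchar(conc$alignment)), rep(7L, 3))
  expect_equal(conc$partition$start, c(1L, 4L))
  expect_equal(conc$partition$end, c(3L, 7L))
  expect_equal(unname(conc$alignment["g3"]), "MKI----")
  expect_error(concatenate_markers(list(m1 = c(g1 = "MK", g1 = "ML"))),
               "single-copy")
  # marker order does not change the distances
  d1 <- aa_distance(conc$alignment[c("g1", "g2")])
  conc2 <- concatenate_markers(list(m2 = a2, m1 = a1))
  d2 <- aa_distance(conc2$alignment[c("g1", "g2")])
  expect_equal(d1, d2)
})

test_that("midpoint rooting keeps supports and roots the longest path", {
  tr <- ape::read.tree(text = "((A:1,B:1)0.9:4,(C:1,D:1)0.8:1);")
  rooted <- midpoint_root(tr)
  expect_true(ape::is.rooted(rooted))
  expect_true(is_monophyletic(rooted, c("A", "B")))
})
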