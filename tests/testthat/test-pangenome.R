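test_that("core families and strata match set definitions", {
  ones <- matrix(1L, 5, 3, dimnames = list(paste0("f", 1:5), paste0("g", 1:3)))
  expect_setequal(core_families(ones), paste0("f", 1:5))
  expect_error(core_families(ones, c("g1", "gX")), "unknown genome")

  single <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("f1", "f2"), "g1"))
  pc <- partition_counts(single)
  expect_equal(pc$n_unique, 2L)  # every family is unique
  expect_equal(pc$n_core, 2L)    # with one genome, present = core
  zero_row <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("f1", "f2"), "g1"))
  expect_error(partition_counts(zero_row), "no genome")
})

test_that("group-specific core is exclusive and disjoint from the core", {
  m <- rbind(f1 = c(1, 1, 1, 1), f2 = c(1, 1, 0, 0), f3 = c(0, 0, 2, 1),
             f4 = c(1, 0, 0, 0))
  colnames(m) <- paste0("g", 1:4)
  expect_equal(group_specific_core(m, c("g1", "g2")), "f2")
  expect_equal(group_specific_core(m, c("g3", "g4")), "f3")
  expect_error(group_specific_core(m, paste0("g", 1:4)), "core_families")
  # disjoint groups give disjoint exclusive cores, and neither intersects
  # the universe core
  expect_length(intersect(group_specific_core(m, c("g1", "g2")),
                          group_specific_core(m, c("g3", "g4"))), 0)
  expect_length(intersect(core_families(m),
                          group_specific_core(m, c("g1", "g2"))), 0)
})

test_that("set logic equals brute-force enumeration on random matrices", {
  set.seed(10)
  for (trial in 1:30) {
    m <- random_presence_matrix(sample(10:25, 1), sample(3:7, 1))
    expect_setequal(core_families(m), core_oracle(m))
    grp <- sample(colnames(m), sample(seq_len(ncol(m) - 1), 1))
    expect_setequal(group_specific_core(m, grp), group_core_oracle(m, grp))
    pc <- partition_counts(m)
    po <- partition_oracle(m)
    expect_equal(pc[c("n_unique", "n_flexible", "n_core")], po)
    expect_equal(pc$n_total, pc$n_unique + pc$n_flexible + pc$n_core)
  }
})

test_that("adding a genome can only shrink the core", {
  set.seed(11)
  for (trial in 1:10) {
    m <- random_presence_matrix(30, 6)
    u <- sample(colnames(m), 4)
    extra <- sample(setdiff(colnames(m), u), 1)
    expect_true(all(core_families(m, c(u, extra)) %in% core_families(m, u)))
  }
})

test_that("resampled group cores match exhaustive brute force", {
  set.seed(12)
  for (trial in 1:5) {
    m <- random_presence_matrix(40, 8)
    gens <- colnames(m)
    aai <- matrix(runif(64, 60, 90), 8, 8, dimnames = list(gens, gens))
    aai <- (aai + t(aai)) / 2
    diag(aai) <- 100
    pool <- gens[1:6]
    ref <- gens[7:8]
    r <- resampled_group_core(m, pool, 3, aai, ref)
    expect_equal(r$max_core_size, resampled_oracle(m, pool, 3, aai, ref))
    expect_equal(nrow(r$table) > 0, !is.na(r$max_core_size))
  }
})

test_that("a pool of exactly k genomes yields its single group core", {
  m <- rbind(f1 = c(1, 1, 0, 1), f2 = c(1, 1, 0, 0))
  colnames(m) <- paste0("g", 1:4)
  aai <- matrix(70, 4, 4, dimnames = list(colnames(m), colnames(m)))
  diag(aai) <- 100
  r <- resampled_group_core(m, c("g1", "g2"), 2, aai, c("g3", "g4"))
  expect_equal(nrow(r$table), 1L)
  expect_equal(r$max_core_size, 1L)  # f2 only
  # no qualifying combination -> NA sentinel
  aai["g1", "g2"] <- aai["g2", "g1"] <- 99
  aai["g3", "g4"] <- aai["g4", "g3"] <- 60
  r2 <- resampled_group_core(m, c("g1", "g2"), 2, aai, c("g3", "g4"))
  expect_true(is.na(r2$max_core_size))
  expect_equal(nrow(r2$table), 0L)
})

test_that("rarefaction curves are monotone and seeded", {
  set.seed(13)
  m <- random_presence_matrix(50, 8)
  r <- rarefaction(m, n_orderings = 5, seed = 99)
  for (o in unique(r$ordering)) {
    expect_true(all(diff(r$core[r$ordering == o]) <= 0))
    expect_true(all(diff(r$pan[r$ordering == o]) >= 0))
  }
  expect_identical(as.data.frame(r),
                   as.data.frame(rarefaction(m, n_orderings = 5, seed = 99)))
})

test_that("an all-core matrix fits a flat curve (omega = n, kappa ~ 0)", {
  m <- matrix(1L, 40, 8, dimnames = list(sprintf("f%02d", 1:40),
                                         sprintf("g%d", 1:8)))
  r <- rarefaction(m, n_orderings = 3, seed = 1)
  expect_true(all(r$core == 40) && all(r$pan == 40))
  fit <- fit_rarefaction(r, "tettelin_exp", "core")
  expect_true(fit$converged)
  expect_equal(fit$omega, 40, tolerance = 1e-3)
  expect_lt(fit$kappa, 0.1)
})

test_that("both fitting protocols recover planted curve parameters", {
  set.seed(14)
  kappa <- 900; tau <- 2.5; omega <- 740
  n <- rep(1:20, each = 10)
  core <- kappa * exp(-n / tau) + omega + rnorm(length(n), 0, 4)
  samples <- data.frame(ordering = rep(1:10, times = 20), n = n, core = core,
                        pan = 2000 - kappa * exp(-n / tau) +
                          rnorm(length(n), 0, 4))
  for (model in c("tettelin_exp", "willenbrock_exp")) {
    fit <- fit_rarefaction(samples, model, "core")
    expect_true(fit$converged)
    expect_lt(abs(fit$kappa - kappa) / kappa, 0.05)
    expect_lt(abs(fit$tau - tau) / tau, 0.05)
    expect_lt(abs(fit$omega - omega) / omega, 0.05)
    pfit <- fit_rarefaction(samples, model, "pan")
    expect_lt(abs(pfit$omega - 2000) / 2000, 0.05)
  }
})
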