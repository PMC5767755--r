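#' Core, group-exclusive and partition set logic on a presence matrix
#'
#' `core_families` returns the families present (copy count >= 1) in every
#' genome of the universe. `group_specific_core` returns the families present
#' in every member of a proper subset of genomes and absent (count 0) from
#' all other genomes of the matrix — the group-exclusive core.
#' `partition_counts` splits all families into unique (exactly one genome),
#' flexible (two or more but not all) and core strata; the three always sum
#' to the total.
#'
#' @param m presence matrix (families x genomes, copy counts) as produced by
#'   [presence_matrix].
#' @param universe genome ids defining the comparison set (default: all
#'   columns).
#' @return `core_families` / `group_specific_core`: character vector of
#'   family ids. `partition_counts`: list of totals and per-group tallies.
#' @examples
#' m <- rbind(F1 = c(1, 1, 1), F2 = c(2, 0, 1), F3 = c(0, 1, 0))
#' colnames(m) <- c("g1", "g2", "g3")
#' core_families(m)
#' group_specific_core(m, c("g2"))
#' partition_counts(m)$n_core
#' @export
core_families <- function(m, universe = colnames(m)) {
  check_genomes(m, universe)
  rownames(m)[rowSums(m[, universe, drop = FALSE] >= 1) == length(universe)]
}

#' @param group genome ids of the group; must be a proper subset of the
#'   matrix genomes (use [core_families] for the whole universe).
#' @rdname core_families
#' @export
group_specific_core <- function(m, group) {
  check_genomes(m, group)
  rest <- setdiff(colnames(m), group)
  if (length(rest) == 0L)
    stop("group equals the whole universe; use core_families() instead")
  present_all <- rowSums(m[, group, drop = FALSE] >= 1) == length(group)
  absent_rest <- rowSums(m[, rest, drop = FALSE]) == 0
  rownames(m)[present_all & absent_rest]
}

#' @param groups optional named list of genome-id vectors; for each group the
#'   tallies include the number of families containing any of its genes and
#'   the number common to all its members.
#' @rdname core_families
#' @export
partition_counts <- function(m, groups = NULL) {
  if (nrow(m) == 0L) stop("empty presence matrix")
  n_gen <- rowSums(m >= 1)
  if (any(n_gen == 0))
    stop("families present in no genome: ",
         paste(head(rownames(m)[n_gen == 0], 5), collapse = ", "))
  out <- list(n_total = nrow(m),
              n_unique = sum(n_gen == 1),
              n_flexible = sum(n_gen > 1 & n_gen < ncol(m)),
              n_core = sum(n_gen == ncol(m)))
  if (!is.null(groups)) {
    out$per_group <- lapply(groups, function(g) {
      check_genomes(m, g)
      sub <- m[, g, drop = FALSE]
      list(n_containing = sum(rowSums(sub) > 0),
           n_common = sum(rowSums(sub >= 1) == length(g)),
           n_exclusive = if (length(g) < ncol(m))
             length(group_specific_core(m, g)) else out$n_core)
    })
  }
  out
}

check_genomes <- function(m, g) {
  missing <- setdiff(g, colnames(m))
  if (length(missing))
    stop("unknown genome id(s): ", paste(missing, collapse = ", "))
  if (length(g) == 0L) stop("empty genome set")
  invisible(TRUE)
}

#' Sampling-bias-controlled group cores by resampling
#'
#' Enumerates every k-genome combination from a pool and keeps the
#' combinations no more similar internally than a reference group: a
#' combination qualifies when its maximum pairwise AAI does not exceed the
#' maximum pairwise AAI within `reference_group`. For every qualifying
#' combination the group-exclusive core against the full matrix is computed.
#' This mimics the reference group's diversity when comparing group-core
#' sizes between clades of different sampling depth.
#'
#' @inheritParams core_families
#' @param pool genome ids to draw combinations from.
#' @param k combination size.
#' @param aai symmetric AAI matrix covering `pool` and `reference_group`.
#' @param reference_group genome ids whose maximum pairwise AAI sets the
#'   dissimilarity bar.
#' @return List with `max_core_size` (NA when no combination qualifies) and
#'   `table`, one row per qualifying combination with its core size.
#' @export
resampled_group_core <- function(m, pool, k, aai, reference_group) {
  check_genomes(m, pool)
  stopifnot(k >= 1, length(pool) >= k)
  need <- union(pool, reference_group)
  if (!all(need %in% rownames(aai)))
    stop("AAI matrix does not cover: ",
         paste(setdiff(need, rownames(aai)), collapse = ", "))
  ref <- aai[reference_group, reference_group, drop = FALSE]
  bar <- if (length(reference_group) > 1)
    max(ref[upper.tri(ref)]) else Inf
  combs <- combn(sort(pool), k, simplify = FALSE)
  rows <- lapply(combs, function(cmb) {
    sub <- aai[cmb, cmb, drop = FALSE]
    max_aai <- if (k > 1) max(sub[upper.tri(sub)]) else 0
    if (max_aai > bar) return(NULL)
    core <- group_specific_core(m, cmb)
    data.frame(combination = paste(cmb, collapse = ","),
               max_pairwise_aai = max_aai, core_size = length(core),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(max_core_size = if (is.null(tab)) NA_integer_ else max(tab$core_size),
       table = tab %||% data.frame(combination = character(0),
                                   max_pairwise_aai = numeric(0),
                                   core_size = integer(0)))
}

#' Core/pan rarefaction curves and exponential model fits
#'
#' `rarefaction` samples random genome orderings and records, at each number
#' of genomes n, the cumulative core (intersection) and pan (union) family
#' counts. `fit_rarefaction` fits the exponential decay
#' `core(n) = kappa * exp(-n / tau) + omega` to the core curve by nonlinear
#' least squares, and the saturating form
#' `pan(n) = omega - kappa * exp(-n / tau)` to the pan curve. Two fitting
#' protocols are available: `tettelin_exp` fits the mean curve across
#' orderings with equal weights; `willenbrock_exp` fits the per-n medians
#' weighted by inverse variance across orderings.
#'
#' @inheritParams core_families
#' @param n_orderings number of random genome orderings (10 by default).
#' @param seed integer seed; recorded in the result.
#' @return `rarefaction`: a `rarefaction_samples` data.frame with columns
#'   `ordering`, `n`, `core`, `pan`. `fit_rarefaction`: a `rarefaction_fit`
#'   list with `kappa`, `tau`, `omega`, `rss`, `model`, `curve`, `converged`
#'   (non-convergence yields NaN parameters and `converged = FALSE`).
#' @export
rarefaction <- function(m, n_orderings = 10, seed = 1L) {
  stopifnot(n_orderings >= 1)
  ng <- ncol(m)
  pres <- m >= 1
  set.seed(seed)
  rows <- vector("list", n_orderings)
  for (o in seq_len(n_orderings)) {
    ord <- sample(ng)
    core <- rep(TRUE, nrow(m))
    pan <- rep(FALSE, nrow(m))
    cs <- ps <- integer(ng)
    for (i in seq_len(ng)) {
      core <- core & pres[, ord[i]]
      pan <- pan | pres[, ord[i]]
      cs[i] <- sum(core); ps[i] <- sum(pan)
    }
    rows[[o]] <- data.frame(ordering = o, n = seq_len(ng), core = cs,
                            pan = ps)
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("rarefaction_samples", "data.frame")
  out
}

#' @param samples output of [rarefaction] (or a data.frame with `n` plus a
#'   `core`/`pan` column).
#' @param model fitting protocol, see Details.
#' @param curve `"core"` or `"pan"`.
#' @rdname rarefaction
#' @export
fit_rarefaction <- function(samples, model = c("tettelin_exp",
                                               "willenbrock_exp"),
                            curve = c("core", "pan")) {
  model <- match.arg(model)
  curve <- match.arg(curve)
  y_all <- samples[[curve]]
  n_all <- samples$n
  if (model == "tettelin_exp") {
    y <- tapply(y_all, n_all, mean)
    wts <- rep(1, length(y))
  } else {
    y <- tapply(y_all, n_all, median)
    v <- as.numeric(tapply(y_all, n_all, stats::var))
    v[is.na(v)] <- 0
    if (all(v < 1e-8)) v[] <- 1 else v[v < 1e-8] <- min(v[v >= 1e-8])
    wts <- 1 / v
  }
  n <- as.numeric(names(y))
  y <- as.numeric(y)
  if (max(y) - min(y) < 1e-8) {
    # flat curve: the decay term vanishes and tau is unidentifiable
    return(structure(list(model = model, curve = curve, kappa = 0,
                          tau = 1, omega = mean(y), rss = 0,
                          converged = TRUE,
                          n_orderings = length(unique(samples$ordering)),
                          seed = attr(samples, "seed")),
                     class = "rarefaction_fit"))
  }
  sgn <- if (curve == "core") 1 else -1
  k0 <- max(abs(y[1] - y[length(y)]), 1)
  o0 <- if (curve == "core") max(min(y), 1) else max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ sgn * kappa * exp(-n / tau) + omega,
      start = list(kappa = k0, tau = max(1, length(y) / 3), omega = o0),
      weights = wts,
      lower = c(kappa = 0, tau = 1e-3, omega = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(model = model, curve = curve, kappa = NaN,
                          tau = NaN, omega = NaN, rss = NaN,
                          converged = FALSE,
                          n_orderings = length(unique(samples$ordering)),
                          seed = attr(samples, "seed")),
                     class = "rarefaction_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(model = model, curve = curve,
                 kappa = unname(cf["kappa"]), tau = unname(cf["tau"]),
                 omega = unname(cf["omega"]),
                 rss = sum(stats::residuals(fit)^2), converged = TRUE,
                 n_orderings = length(unique(samples$ordering)),
                 seed = attr(samples, "seed")),
            class = "rarefaction_fit")
}

#' @export
print.rarefaction_fit <- function(x, ...) {
  cat(sprintf(
    "<rarefaction_fit> %s %s: kappa=%.1f tau=%.2f omega=%.1f (rss %.2f)\n",
    x$model, x$curve, x$kappa, x$tau, x$omega, x$rss))
  invisible(x)
}
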