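# independent oracles the implementation is checked against

# exhaustive Smith-Waterman / Needleman-Wunsch score via Biostrings
sw_score_oracle <- function(a, b, type = "local") {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = type,
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
}

# dense-matrix MCL reference: full adjacency over all nodes, expansion /
# inflation / pruning / renormalisation, clusters from the limit matrix
mcl_dense_oracle <- function(nodes, edges, inflation = 1.5,
                             pruning = 1e-4, max_iter = 100, tol = 1e-8) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges$from[r], edges$to[r]] <- edges$weight[r]
      A[edges$to[r], edges$from[r]] <- edges$weight[r]
    }
  }
  for (v in seq_len(n)) {
    mx <- max(A[, v])
    A[v, v] <- if (mx > 0) mx else 1
  }
  M <- A %*% diag(1 / colSums(A), n)
  for (it in seq_len(max_iter)) {
    M2 <- (M %*% M)^inflation
    M2[M2 < pruning] <- 0
    M2 <- M2 %*% diag(1 / colSums(M2), n)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  keep <- (M > 1e-6) | t(M > 1e-6)
  # connected components of the limit structure, by hand (BFS)
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(cluster[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(cluster[v])) next
      cluster[v] <- cid
      queue <- c(queue, which(keep[v, ] & is.na(cluster)))
    }
  }
  unname(split(nodes, cluster))
}

# canonical form of a partition (list of member vectors) for comparison
canon_partition <- function(fams) {
  fams <- lapply(unname(fams), function(x) sort(unname(x)))
  fams[order(vapply(fams, `[`, character(1), 1))]
}

# brute-force pangenome set logic
core_oracle <- function(m, universe = colnames(m)) {
  out <- character(0)
  for (f in rownames(m)) {
    if (all(vapply(universe, function(g) m[f, g] >= 1, logical(1))))
      out <- c(out, f)
  }
  out
}

group_core_oracle <- function(m, group) {
  rest <- setdiff(colnames(m), group)
  out <- character(0)
  for (f in rownames(m)) {
    if (all(m[f, group] >= 1) && sum(m[f, rest]) == 0) out <- c(out, f)
  }
  out
}

partition_oracle <- function(m) {
  u <- fl <- co <- 0L
  for (f in rownames(m)) {
    k <- sum(m[f, ] >= 1)
    if (k == 1) u <- u + 1L
    else if (k == ncol(m)) co <- co + 1L
    else if (k > 1) fl <- fl + 1L
  }
  list(n_unique = u, n_flexible = fl, n_core = co)
}

resampled_oracle <- function(m, pool, k, aai, reference_group) {
  ref <- aai[reference_group, reference_group]
  bar <- max(ref[upper.tri(ref)])
  best <- NA_integer_
  combs <- combn(sort(pool), k, simplify = FALSE)
  for (cmb in combs) {
    ok <- TRUE
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (aai[cmb[i], cmb[j]] > bar) ok <- FALSE
      }
    }
    if (!ok) next
    size <- length(group_core_oracle(m, cmb))
    if (is.na(best) || size > best) best <- size
  }
  best
}

random_presence_matrix <- function(n_fam, n_gen, p_zero = 0.4) {
  m <- matrix(rbinom(n_fam * n_gen, 3, 0.4), n_fam, n_gen)
  m[matrix(runif(n_fam * n_gen) < p_zero, n_fam, n_gen)] <- 0L
  # every family exists somewhere (presence matrices come from clustering
  # actual proteins)
  for (r in which(rowSums(m) == 0)) m[r, sample.int(n_gen, 1)] <- 1L
  rownames(m) <- sprintf("f%03d", seq_len(n_fam))
  colnames(m) <- sprintf("g%02d", seq_len(n_gen))
  m
}

# independent greedy clustering oracle (same stated order, separate code)
greedy_oracle <- function(seqs, threshold = 95) {
  sc <- scoring_scheme("aa")
  ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
  centroids <- character(0)
  assign <- setNames(character(length(ids)), ids)
  for (id in ids) {
    hit <- NA_character_
    for (cid in centroids) {
      a <- align_local(list(id = id, seq = seqs[[id]]),
                       list(id = cid, seq = seqs[[cid]]), sc)
      if (a$percent_identity >= threshold) { hit <- cid; break }
    }
    if (is.na(hit)) { centroids <- c(centroids, id); hit <- id }
    assign[id] <- hit
  }
  list(centroids = centroids, membership = assign)
}
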