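#' Markov-clustering parameters
#'
#' @param inflation MCL inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param e_value_cutoff maximum expectation value for a hit to be retained.
#' @param min_match_fraction minimum fraction of the shorter protein that the
#'   alignment must cover.
#' @param pruning_threshold matrix entries below this are zeroed after each
#'   inflation step.
#' @param max_iterations,convergence_tol iteration cap and the maximum
#'   absolute matrix change at which iteration stops.
#' @return A validated `mcl_params` list.
#' @export
mcl_params <- function(inflation = 1.5, e_value_cutoff = 1e-5,
                       min_match_fraction = 0.5, pruning_threshold = 1e-4,
                       max_iterations = 100L, convergence_tol = 1e-8) {
  stopifnot(inflation > 1, e_value_cutoff > 0,
            min_match_fraction >= 0, min_match_fraction <= 1,
            pruning_threshold >= 0, pruning_threshold < 1,
            max_iterations >= 1, convergence_tol > 0)
  structure(list(inflation = inflation, e_value_cutoff = e_value_cutoff,
                 min_match_fraction = min_match_fraction,
                 pruning_threshold = pruning_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "mcl_params")
}

# weight used throughout the similarity graph
MINUS_LOG10_EVALUE_CAP <- 300

#' All-against-all protein similarity search
#'
#' Aligns every candidate protein pair across (and within) the proteomes of a
#' genome set and reports hits in the standard 12-column tabular layout
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore; coordinates 1-based inclusive, gapopen holding the
#' number of gap columns). Each retained unordered pair yields two ordered
#' rows whose e-values use the respective subject proteome's residue count as
#' search-space size. Candidate pairs are found by a shared k-mer filter;
#' each candidate is then aligned by exact Smith-Waterman, so the search has
#' no alignment-level heuristics. Self hits (a protein against itself) are
#' included. Deterministic given its inputs.
#'
#' @param genomes a [genome_set] with at least one proteome.
#' @param scoring protein [scoring_scheme].
#' @param params an [mcl_params] object (only the hit filters are used here).
#' @param kmer,min_shared_kmers candidate filter: pairs sharing fewer than
#'   `min_shared_kmers` distinct `kmer`-mers are never aligned.
#' @return A data.frame hit table with the 12 standard columns plus
#'   `qgenome`, `sgenome` and the raw `score`.
#' @export
all_vs_all <- function(genomes, scoring = scoring_scheme("aa"),
                       params = mcl_params(), kmer = 4,
                       min_shared_kmers = 6) {
  prot <- all_proteins(genomes)
  n_res <- vapply(split(nchar(prot$seq), prot$genome_id), sum, numeric(1))
  cand <- cpp_candidate_pairs(prot$seq, kmer, min_shared_kmers)
  cand <- rbind(cand, data.frame(i = seq_len(nrow(prot)),
                                 j = seq_len(nrow(prot)),
                                 shared = NA_integer_))
  aln <- cpp_align_batch(prot$seq, prot$seq, cand$i, cand$j, scoring$matrix,
                         scoring$gap_open, scoring$gap_ext, local = TRUE)
  len_i <- nchar(prot$seq)[cand$i]
  len_j <- nchar(prot$seq)[cand$j]
  pident <- ifelse(aln$aln_len > 0, 100 * aln$n_ident / aln$aln_len, 0)
  bits <- bit_score(aln$score, scoring)
  long_enough <- aln$aln_len >= params$min_match_fraction * pmin(len_i, len_j)

  fwd <- data.frame(
    qseqid = prot$id[cand$i], sseqid = prot$id[cand$j], pident = pident,
    length = aln$aln_len, mismatch = aln$aln_len - aln$n_ident - aln$n_gap_cols,
    gapopen = aln$n_gap_cols,
    qstart = aln$qstart + 1L, qend = aln$qend,
    sstart = aln$sstart + 1L, send = aln$send,
    evalue = pmax(0, len_i * n_res[prot$genome_id[cand$j]] * 2^(-bits)),
    bitscore = bits, qgenome = prot$genome_id[cand$i],
    sgenome = prot$genome_id[cand$j], score = aln$score,
    stringsAsFactors = FALSE)
  rev <- fwd
  rev[, c("qseqid", "sseqid", "qgenome", "sgenome")] <-
    fwd[, c("sseqid", "qseqid", "sgenome", "qgenome")]
  rev[, c("qstart", "qend", "sstart", "send")] <-
    fwd[, c("sstart", "send", "qstart", "qend")]
  rev$evalue <- pmax(0, len_j * n_res[prot$genome_id[cand$i]] * 2^(-bits))
  self <- fwd$qseqid == fwd$sseqid
  hits <- rbind(fwd[long_enough, ], rev[long_enough & !self, ])
  hits <- hits[hits$evalue <= params$e_value_cutoff, , drop = FALSE]
  rownames(hits) <- NULL
  hits[order(hits$qseqid, hits$sseqid), , drop = FALSE]
}

#' Build the OrthoMCL-style similarity graph
#'
#' Classifies edges from an all-against-all hit table. Ortholog edges connect
#' inter-genome reciprocal best hits; in-paralog edges connect intra-genome
#' reciprocal hits whose mutual weight exceeds either protein's best
#' inter-genome hit; co-ortholog edges connect (in-)paralogs of connected
#' orthologs where a hit exists. Edge weight is the average of
#' `-log10(evalue)` over the available directions, capped at 300. Ortholog
#' and co-ortholog weights are rescaled by the genome pair's mean ortholog
#' weight and in-paralog weights by the genome's mean in-paralog weight among
#' proteins that have orthologs (the OrthoMCL normalisation).
#'
#' @param hits hit table from [all_vs_all].
#' @param genomes the [genome_set] the hits came from.
#' @return A `similarity_graph`: list of `nodes` (id, genome) and `edges`
#'   (from, to, weight, kind).
#' @export
build_graph <- function(hits, genomes) {
  prot <- all_proteins(genomes)
  if (!all(hits$qseqid %in% prot$id) || !all(hits$sseqid %in% prot$id))
    stop("hit table references proteins absent from the genome set")
  nodes <- data.frame(id = prot$id, genome = prot$genome_id,
                      stringsAsFactors = FALSE)
  h <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  h$w <- pmin(-log10(pmax(h$evalue, 10^-MINUS_LOG10_EVALUE_CAP)),
              MINUS_LOG10_EVALUE_CAP)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  # average weight over the directions present, per unordered pair
  pair_w <- tapply(h$w, key(h$qseqid, h$sseqid), mean)

  inter <- h[h$qgenome != h$sgenome, , drop = FALSE]
  intra <- h[h$qgenome == h$sgenome, , drop = FALSE]

  # reciprocal best inter-genome hits (per query and subject genome)
  ortho <- data.frame(from = character(0), to = character(0))
  if (nrow(inter)) {
    grp <- paste(inter$qseqid, inter$sgenome, sep = "\r")
    ord <- order(grp, -inter$bitscore, inter$evalue, inter$sseqid)
    best <- inter[ord, ][!duplicated(grp[ord]), , drop = FALSE]
    fk <- paste(best$qseqid, best$sseqid, sep = "\r")
    rk <- paste(best$sseqid, best$qseqid, sep = "\r")
    rec <- best[fk %in% rk, , drop = FALSE]
    pick <- rec$qseqid < rec$sseqid
    ortho <- data.frame(from = rec$qseqid[pick], to = rec$sseqid[pick],
                        stringsAsFactors = FALSE)
  }
  ortho_key <- key(ortho$from, ortho$to)
  best_inter <- if (nrow(inter)) tapply(inter$w, inter$qseqid, max)
                else setNames(numeric(0), character(0))

  # intra-genome reciprocal pairs beating both proteins' best inter hits
  inpar <- data.frame(from = character(0), to = character(0))
  if (nrow(intra)) {
    fk <- paste(intra$qseqid, intra$sseqid, sep = "\r")
    rk <- paste(intra$sseqid, intra$qseqid, sep = "\r")
    rec <- intra[fk %in% rk & intra$qseqid < intra$sseqid, , drop = FALSE]
    if (nrow(rec)) {
      w <- pair_w[key(rec$qseqid, rec$sseqid)]
      bi_q <- best_inter[rec$qseqid]
      bi_s <- best_inter[rec$sseqid]
      bi_q[is.na(bi_q)] <- -Inf
      bi_s[is.na(bi_s)] <- -Inf
      keep <- w > bi_q & w > bi_s
      inpar <- data.frame(from = rec$qseqid[keep], to = rec$sseqid[keep],
                          stringsAsFactors = FALSE)
    }
  }
  inpar_key <- key(inpar$from, inpar$to)

  # co-orthologs: in-paralogs of one end of an ortholog edge against the
  # other end (and against its in-paralogs), where any hit exists
  co <- data.frame(from = character(0), to = character(0))
  if (nrow(ortho) && nrow(inpar)) {
    partners <- rbind(inpar, data.frame(from = inpar$to, to = inpar$from))
    expand <- function(p) {
      ip <- partners$to[partners$from == p]
      c(p, ip)
    }
    cand_from <- character(0); cand_to <- character(0)
    for (r in seq_len(nrow(ortho))) {
      ea <- expand(ortho$from[r])
      eb <- expand(ortho$to[r])
      grid <- expand.grid(a = ea, b = eb, stringsAsFactors = FALSE)
      cand_from <- c(cand_from, grid$a)
      cand_to <- c(cand_to, grid$b)
    }
    ck <- key(cand_from, cand_to)
    ok <- !duplicated(ck) & ck %in% names(pair_w) &
      !(ck %in% ortho_key) & cand_from != cand_to
    co <- data.frame(from = pmin(cand_from[ok], cand_to[ok]),
                     to = pmax(cand_from[ok], cand_to[ok]),
                     stringsAsFactors = FALSE)
  }

  genome_of <- setNames(nodes$genome, nodes$id)
  edges <- rbind(
    if (nrow(ortho)) cbind(ortho, kind = "ortholog"),
    if (nrow(inpar)) cbind(inpar, kind = "in-paralog"),
    if (nrow(co)) cbind(co, kind = "co-ortholog"))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0), weight = numeric(0))
    return(structure(list(nodes = nodes, edges = edges),
                     class = "similarity_graph"))
  }
  edges$weight <- unname(pair_w[key(edges$from, edges$to)])

  # normalisation
  gp <- function(a, b) {
    ga <- genome_of[a]; gb <- genome_of[b]
    paste(pmin(ga, gb), pmax(ga, gb), sep = "\r")
  }
  is_ortho <- edges$kind == "ortholog"
  mean_ortho <- tapply(edges$weight[is_ortho], gp(edges$from[is_ortho],
                                                  edges$to[is_ortho]), mean)
  cross <- edges$kind != "in-paralog"
  norm <- mean_ortho[gp(edges$from, edges$to)]
  edges$weight[cross] <- edges$weight[cross] /
    ifelse(is.na(norm[cross]) | norm[cross] <= 0, 1, norm[cross])
  if (any(!cross)) {
    has_ortho <- unique(c(edges$from[is_ortho], edges$to[is_ortho]))
    ip <- edges[!cross, , drop = FALSE]
    g_ip <- genome_of[ip$from]
    anchored <- ip$from %in% has_ortho | ip$to %in% has_ortho
    mean_ip <- tapply(ip$weight[anchored], g_ip[anchored], mean)
    mean_ip_all <- tapply(ip$weight, g_ip, mean)
    denom <- mean_ip[g_ip]
    denom[is.na(denom)] <- mean_ip_all[g_ip][is.na(denom)]
    denom[is.na(denom) | denom <= 0] <- 1
    edges$weight[!cross] <- ip$weight / denom
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d proteins, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(names(table(x$edges$kind)), table(x$edges$kind),
                    sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Markov clustering of a similarity graph
#'
#' Runs MCL independently on each connected component: the column-stochastic
#' weight matrix (self-loops set to each node's maximum incident weight) is
#' alternately squared (expansion) and raised element-wise to the inflation
#' power with column renormalisation (inflation), pruning entries below
#' `pruning_threshold`, until the maximum absolute change falls below
#' `convergence_tol`. Clusters are the connected components of the limit
#' matrix's nonzero structure. The partition is invariant under node
#' relabelling; isolated nodes become singleton families.
#'
#' @param graph a `similarity_graph` from [build_graph].
#' @param params an [mcl_params] object.
#' @return An `ortholog_families` object: named list of member protein-id
#'   vectors (families sorted by size then lexicographically), with attribute
#'   `converged` (FALSE triggers a warning but still returns the clustering).
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  nodes <- graph$nodes$id
  if (length(nodes) == 0L) stop("empty graph")
  edges <- graph$edges
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  members <- split(nodes, comp$membership)
  fams <- list()
  all_converged <- TRUE
  for (cm in members) {
    if (length(cm) == 1L) { fams <- c(fams, list(cm)); next }
    sub <- edges[edges$from %in% cm & edges$to %in% cm, , drop = FALSE]
    r <- mcl_component(cm, sub, params)
    if (!r$converged) all_converged <- FALSE
    fams <- c(fams, r$clusters)
  }
  if (!all_converged)
    warning("MCL did not converge within max_iterations; ",
            "returning the current clustering")
  as_ortholog_families(fams, converged = all_converged)
}

mcl_component <- function(ids, edges, params) {
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  W[cbind(edges$from, edges$to)] <- edges$weight
  W[cbind(edges$to, edges$from)] <- edges$weight
  diag(W) <- apply(W, 2, max)
  M <- sweep(W, 2, colSums(W), "/")
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^params$inflation           # inflation
    M2[M2 < params$pruning_threshold] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  S <- (M > 1e-6) | t(M > 1e-6)
  gg <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                            diag = FALSE)
  cl <- igraph::components(gg)$membership
  list(clusters = split(ids, cl), converged = converged)
}

as_ortholog_families <- function(fams, converged = TRUE) {
  fams <- lapply(fams, function(x) sort(unname(x)))
  ord <- order(-vapply(fams, length, integer(1)),
               vapply(fams, `[`, character(1), 1))
  fams <- fams[ord]
  names(fams) <- sprintf("F%05d", seq_along(fams))
  structure(fams, class = "ortholog_families", converged = converged)
}

#' @export
print.ortholog_families <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("<ortholog_families> %d families over %d proteins (max size %d)\n",
              length(x), sum(sizes), max(sizes)))
  invisible(x)
}

#' Infer ortholog families for a genome set
#'
#' Composition of [all_vs_all], [build_graph] and [mcl_cluster], returning
#' both the family partition and the family-by-genome copy-count matrix.
#' Proteins with no retained edges become singleton families, so the families
#' always partition the full protein set.
#'
#' @inheritParams all_vs_all
#' @return List with `families`, `presence` (see [presence_matrix]), `graph`
#'   and `hits`.
#' @export
infer_families <- function(genomes, scoring = scoring_scheme("aa"),
                           params = mcl_params(), ...) {
  hits <- all_vs_all(genomes, scoring, params, ...)
  graph <- build_graph(hits, genomes)
  families <- mcl_cluster(graph, params)
  list(families = families,
       presence = presence_matrix(families, genomes),
       graph = graph, hits = hits)
}

#' Family-by-genome copy-count matrix
#'
#' @param families an `ortholog_families` object.
#' @param genomes the [genome_set] providing the protein-to-genome mapping.
#' @return Integer matrix, rows = families, columns = genomes; column sums
#'   equal the proteome sizes of the clustered proteins.
#' @export
presence_matrix <- function(families, genomes) {
  prot <- all_proteins(genomes)
  genome_of <- setNames(prot$genome_id, prot$id)
  gids <- genome_ids(genomes)
  m <- matrix(0L, length(families), length(gids),
              dimnames = list(names(families), gids))
  for (f in names(families)) {
    tb <- table(genome_of[families[[f]]])
    m[f, names(tb)] <- as.integer(tb)
  }
  m
}

#' Write ortholog families as TSV (family_id, genome_id, protein_id)
#' @inheritParams presence_matrix
#' @param path output path.
#' @export
write_families_tsv <- function(families, genomes, path) {
  prot <- all_proteins(genomes)
  genome_of <- setNames(prot$genome_id, prot$id)
  df <- data.frame(
    family_id = rep(names(families), lengths(families)),
    protein_id = unlist(families, use.names = FALSE))
  df$genome_id <- unname(genome_of[df$protein_id])
  write.table(df[, c("family_id", "genome_id", "protein_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
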