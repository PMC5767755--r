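#' Average nucleotide identity between two genomes
#'
#' Fragment-based ANI: the query genome is cut into consecutive fixed-length
#' fragments, each fragment is locally aligned to the best-matching region of
#' the subject genome (found by shared k-mer seeding on both strands), and
#' fragments aligned at >= `min_identity` percent identity over >=
#' `min_coverage` of their length contribute their identity. The reported ANI
#' is the mean of the two directions, so it is symmetric; a genome against
#' itself gives 100.
#'
#' @param genomes a [genome_set] with nucleotide contigs.
#' @param a,b genome ids within `genomes`.
#' @param fragment_length fragment size in nt (1,020 by default, the
#'   convention of fragment-based ANI).
#' @param min_identity,min_coverage fragment retention filter: percent
#'   identity threshold and minimum aligned fraction of the fragment.
#' @param kmer,margin seeding word size and window margin (nt) used to locate
#'   the candidate subject region before exact local alignment.
#' @param scoring nucleotide [scoring_scheme].
#' @return List with `ani` (percent), `fraction_fragments_used` (mean over
#'   both directions), and the per-direction values.
#' @export
compute_ani <- function(genomes, a, b, fragment_length = 1020,
                        min_identity = 30, min_coverage = 0.7,
                        kmer = 12, margin = 150,
                        scoring = scoring_scheme("nt")) {
  ca <- contig_seqs(genomes, a)
  cb <- contig_seqs(genomes, b)
  d1 <- ani_one_direction(ca, cb, fragment_length, min_identity, min_coverage,
                          kmer, margin, scoring)
  d2 <- ani_one_direction(cb, ca, fragment_length, min_identity, min_coverage,
                          kmer, margin, scoring)
  list(ani = mean(c(d1$ani, d2$ani)),
       fraction_fragments_used = mean(c(d1$fraction, d2$fraction)),
       forward = d1, reverse = d2)
}

contig_seqs <- function(genomes, g) {
  ct <- genomes$contigs[[g]]
  if (is.null(ct) || nrow(ct) == 0L)
    stop("genome ", g, " has no nucleotide contigs")
  ct$seq
}

ani_one_direction <- function(query_contigs, subject_contigs, fragment_length,
                              min_identity, min_coverage, kmer, margin,
                              scoring) {
  frags <- unlist(lapply(query_contigs, function(s) {
    n <- nchar(s)
    starts <- seq(1L, n, by = fragment_length)
    f <- substring(s, starts, pmin(starts + fragment_length - 1L, n))
    f[nchar(f) >= fragment_length / 3]
  }))
  if (length(frags) == 0L)
    stop("genome shorter than one ", fragment_length, " nt fragment")
  subject <- paste(subject_contigs, collapse = strrep("N", 50))
  hits <- cpp_map_fragments(frags, subject, kmer, margin, scoring$matrix,
                            scoring$gap_open, scoring$gap_ext)
  keep <- !is.na(hits$identity) & hits$identity >= min_identity &
    hits$coverage >= min_coverage
  list(ani = if (any(keep)) mean(hits$identity[keep]) else NA_real_,
       fraction = mean(keep), n_fragments = length(frags))
}

#' Average amino-acid identity between two proteomes
#'
#' Reciprocal best hits (RBH) between the two proteomes, retaining hits with
#' >= `min_identity` percent identity over >= `min_coverage` of the shorter
#' protein. AAI is the mean percent identity over RBH pairs;
#' `fraction_genes_aligned` is the number of RBH pairs over the size of the
#' smaller proteome, in percent. Symmetric by construction. With zero RBH
#' pairs, `aai` is `NA` (undefined), not an error.
#'
#' @param prot_a,prot_b amino-acid [seq_records] tables (one proteome each).
#' @param min_identity,min_coverage RBH retention filters.
#' @param scoring protein [scoring_scheme].
#' @param kmer,min_shared_kmers candidate-pair seeding filter: only pairs
#'   sharing at least `min_shared_kmers` distinct `kmer`-mers are aligned.
#' @return List with `aai`, `fraction_genes_aligned`, `n_rbh` and the RBH
#'   pair table.
#' @export
compute_aai <- function(prot_a, prot_b, min_identity = 30, min_coverage = 0.7,
                        scoring = scoring_scheme("aa"),
                        kmer = 4, min_shared_kmers = 4) {
  stopifnot(nrow(prot_a) > 0, nrow(prot_b) > 0)
  cand <- cpp_candidate_pairs_xy(prot_a$seq, prot_b$seq, kmer,
                                 min_shared_kmers)
  if (nrow(cand) == 0L)
    return(list(aai = NA_real_, fraction_genes_aligned = 0, n_rbh = 0L,
                pairs = NULL))
  aln <- cpp_align_batch(prot_a$seq, prot_b$seq, cand$i, cand$j,
                         scoring$matrix, scoring$gap_open, scoring$gap_ext,
                         local = TRUE)
  pident <- ifelse(aln$aln_len > 0, 100 * aln$n_ident / aln$aln_len, 0)
  shorter <- pmin(nchar(prot_a$seq)[cand$i], nchar(prot_b$seq)[cand$j])
  keep <- pident >= min_identity & aln$aln_len >= min_coverage * shorter
  if (!any(keep))
    return(list(aai = NA_real_, fraction_genes_aligned = 0, n_rbh = 0L,
                pairs = NULL))
  tab <- data.frame(i = cand$i[keep], j = cand$j[keep],
                    pident = pident[keep], score = aln$score[keep])
  tab$qid <- prot_a$id[tab$i]
  tab$sid <- prot_b$id[tab$j]
  # best hit per query / per subject; ties broken by score then id
  best_j_for_i <- best_by(tab, tab$i, tab$sid)
  best_i_for_j <- best_by(tab, tab$j, tab$qid)
  rbh <- tab[best_j_for_i & best_i_for_j, , drop = FALSE]
  n_min <- min(nrow(prot_a), nrow(prot_b))
  list(aai = mean(rbh$pident),
       fraction_genes_aligned = 100 * nrow(rbh) / n_min,
       n_rbh = nrow(rbh),
       pairs = rbh[, c("qid", "sid", "pident", "score")])
}

# logical marker of the best row within each group: highest score,
# then lexicographically smallest partner id (deterministic)
best_by <- function(tab, group, partner_id) {
  ord <- order(group, -tab$score, partner_id)
  first <- !duplicated(group[ord])
  out <- logical(nrow(tab))
  out[ord] <- first
  out
}

#' Whole-set identity matrices and dendrograms
#'
#' `identity_matrix` computes all pairwise ANI or AAI values for a genome
#' set; `identity_dendrogram` turns such a matrix into an ultrametric
#' complete-linkage dendrogram on the distance `100 - identity`.
#'
#' @param genomes a [genome_set].
#' @param kind `"ANI"` or `"AAI"`.
#' @param ... passed on to [compute_ani] or [compute_aai].
#' @return `identity_matrix`: a symmetric percent-identity matrix with a
#'   `kind` attribute and 100 on the diagonal. `identity_dendrogram`: an
#'   [ape::phylo] tree whose leaves are the matrix labels.
#' @export
identity_matrix <- function(genomes, kind = c("AAI", "ANI"), ...) {
  kind <- match.arg(kind)
  ids <- genome_ids(genomes)
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        v <- if (kind == "ANI") {
          compute_ani(genomes, ids[i], ids[j], ...)$ani
        } else {
          compute_aai(genomes$proteomes[[ids[i]]],
                      genomes$proteomes[[ids[j]]], ...)$aai
        }
        m[i, j] <- m[j, i] <- v
      }
    }
  }
  structure(m, kind = kind)
}

#' @param m a square symmetric percent-identity matrix (diagonal 100).
#' @rdname identity_matrix
#' @export
identity_dendrogram <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("identity matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("identity matrix must be symmetric")
  hc <- hclust(as.dist(100 - m), method = "complete")
  ape::as.phylo(hc)
}

#' @rdname identity_matrix
#' @param path TSV path (labels in the first row and column).
#' @export
write_identity_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname identity_matrix
#' @export
read_identity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
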