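#' Marker-based completeness and contamination
#'
#' Given single-copy marker counts for a genome, completeness is the
#' percentage of markers present at least once, and contamination the summed
#' surplus copies as a percentage of the marker count (a marker seen three
#' times adds two surplus copies). Adding genes can only raise completeness;
#' adding duplicates can only raise contamination.
#'
#' @param counts named integer vector of per-marker copy counts (markers
#'   absent from the vector count as 0).
#' @param markers character vector of expected single-copy marker ids.
#' @return List with `completeness` and `contamination`, both in percent.
#' @examples
#' assess_completeness(c(m1 = 1, m2 = 2), markers = c("m1", "m2", "m3", "m4"))
#' @export
assess_completeness <- function(counts, markers) {
  if (length(markers) == 0L) stop("marker set must be nonempty")
  if (anyDuplicated(markers)) stop("marker ids must be unique")
  k <- counts[markers]
  k[is.na(k)] <- 0L
  list(completeness = 100 * sum(k >= 1) / length(markers),
       contamination = 100 * sum(pmax(k - 1, 0)) / length(markers))
}

#' Detect single-copy markers in a proteome by similarity search
#'
#' Assigns each protein to the best-matching marker reference (highest score,
#' then smallest marker id) among hits with more than `min_identity` percent
#' identity over at least `min_coverage` of the shorter sequence, and counts
#' assignments per marker.
#'
#' @param proteome amino-acid [seq_records] of one genome.
#' @param marker_refs data.frame with columns `marker_id`, `id`, `seq`
#'   (reference sequences, possibly several per marker).
#' @param min_identity,min_coverage hit filters.
#' @param scoring protein [scoring_scheme].
#' @param kmer,min_shared_kmers candidate seeding filter.
#' @return Named integer vector of copy counts over all markers in
#'   `marker_refs` (zeros included), suitable for [assess_completeness].
#' @export
detect_markers <- function(proteome, marker_refs, min_identity = 30,
                           min_coverage = 0.70,
                           scoring = scoring_scheme("aa"),
                           kmer = 4, min_shared_kmers = 4) {
  stopifnot(all(c("marker_id", "id", "seq") %in% names(marker_refs)))
  markers <- sort(unique(marker_refs$marker_id))
  counts <- setNames(integer(length(markers)), markers)
  cand <- cpp_candidate_pairs_xy(proteome$seq, marker_refs$seq, kmer,
                                 min_shared_kmers)
  if (nrow(cand) == 0L) return(counts)
  aln <- cpp_align_batch(proteome$seq, marker_refs$seq, cand$i, cand$j,
                         scoring$matrix, scoring$gap_open, scoring$gap_ext,
                         local = TRUE)
  pid <- ifelse(aln$aln_len > 0, 100 * aln$n_ident / aln$aln_len, 0)
  shorter <- pmin(nchar(proteome$seq)[cand$i], nchar(marker_refs$seq)[cand$j])
  keep <- pid > min_identity & aln$aln_len >= min_coverage * shorter
  if (!any(keep)) return(counts)
  tab <- data.frame(protein = cand$i[keep],
                    marker = marker_refs$marker_id[cand$j[keep]],
                    score = aln$score[keep])
  ord <- order(tab$protein, -tab$score, tab$marker)
  best <- tab[ord, ][!duplicated(tab$protein[ord]), , drop = FALSE]
  tb <- table(best$marker)
  counts[names(tb)] <- as.integer(tb)
  counts
}
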