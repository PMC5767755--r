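#' Pairwise local alignment
#'
#' Exact affine-gap Smith-Waterman alignment (full dynamic programming, no
#' heuristic seeding), with bit score and expectation value computed from the
#' scheme's Karlin-Altschul parameters over a search space of
#' `nchar(a) * search_space_n` residues.
#'
#' @param a,b single rows of a [seq_records] table, or plain lists/rows with
#'   `id` and `seq` elements.
#' @param scoring a [scoring_scheme]; must match the sequence alphabet.
#' @param search_space_n subject search-space size in residues; defaults to
#'   the subject length (a single-sequence search).
#' @return A `local_alignment` list: `query_id`, `subject_id`, `query_span`
#'   and `subject_span` (0-based half-open), `percent_identity` over aligned
#'   columns, `aln_length`, `score`, `bit_score`, `e_value`.
#' @examples
#' sc <- scoring_scheme("aa")
#' a <- list(id = "x", seq = "MKVLITGGAGFIGSHLVD")
#' align_local(a, a, sc)$percent_identity
#' @export
align_local <- function(a, b, scoring = scoring_scheme("aa"),
                        search_space_n = NULL) {
  sa <- seq_of(a); sb <- seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  r <- cpp_align(sa, sb, scoring$matrix, scoring$gap_open, scoring$gap_ext,
                 local = TRUE)
  n <- search_space_n %||% nchar(sb)
  as_local_alignment(r, id_of(a), id_of(b), nchar(sa), n, scoring)
}

as_local_alignment <- function(r, qid, sid, m, n, scoring) {
  structure(list(
    query_id = qid, subject_id = sid,
    query_span = c(r$qstart, r$qend), subject_span = c(r$sstart, r$send),
    percent_identity = if (r$aln_len > 0) 100 * r$n_ident / r$aln_len else 0,
    aln_length = r$aln_len, n_ident = r$n_ident, n_gap_cols = r$n_gap_cols,
    score = r$score,
    bit_score = bit_score(r$score, scoring),
    e_value = max(0, e_value(r$score, m, n, scoring))
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "<local_alignment> %s vs %s: score %g (%.1f bits, E=%.2g), %.1f%% id over %d cols\n",
    x$query_id, x$subject_id, x$score, x$bit_score, x$e_value,
    x$percent_identity, x$aln_length))
  invisible(x)
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment (affine gaps, end gaps penalised);
#' identity is the percentage of identical columns over all alignment
#' columns, including gap columns. Symmetric in its arguments.
#'
#' @inheritParams align_local
#' @param alphabet `"aa"` or `"nt"`; both sequences must share it.
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, alphabet = c("aa", "nt"),
                              scoring = NULL) {
  alphabet <- match.arg(alphabet)
  scoring <- scoring %||% scoring_scheme(alphabet)
  if (scoring$alphabet != alphabet)
    stop("scoring scheme alphabet does not match the sequences")
  sa <- seq_of(a); sb <- seq_of(b)
  for (s in c(sa, sb)) {
    looks_nt <- !grepl(paste0("[^", paste(nt_letters(), collapse = ""), "]"), s)
    if (alphabet == "nt" && !looks_nt)
      stop("sequence contains non-nucleotide characters; mixed alphabets?")
  }
  r <- cpp_align(sa, sb, scoring$matrix, scoring$gap_open, scoring$gap_ext,
                 local = FALSE)
  if (r$aln_len == 0) return(0)
  100 * r$n_ident / r$aln_len
}

seq_of <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) return(x)
  if (!is.null(x$seq)) return(as.character(x$seq)[1])
  stop("expected a sequence record with a $seq element or a bare string")
}

id_of <- function(x) {
  if (is.character(x) && length(x) == 1L) return(unname(x))
  if (!is.null(x$id)) return(as.character(x$id)[1])
  NA_character_
}
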