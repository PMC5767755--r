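#' Alignment scoring schemes
#'
#' Bundles a substitution matrix, affine gap costs and Karlin-Altschul
#' statistical parameters into a scoring scheme used by all alignment-based
#' operations. The protein default is BLOSUM62 with gap open 11 / extend 1;
#' the nucleotide default scores match +2 / mismatch -3 with gap open 5 /
#' extend 2. A gap of length L costs `gap_open + L * gap_ext`.
#'
#' The Karlin-Altschul parameters lambda and K convert raw scores S into bit
#' scores `(lambda * S - ln K) / ln 2` and expectation values
#' `E = m * n * 2^-bitscore` over a search space of m query and n subject
#' residues. The constants are the standard gapped values for these two
#' scoring systems; no finite-size length adjustment is applied.
#'
#' @param alphabet `"aa"` for protein or `"nt"` for nucleotide scoring.
#' @param gap_open,gap_ext affine gap costs (positive numbers).
#' @param match,mismatch nucleotide match/mismatch scores (ignored for
#'   `"aa"`, which always uses BLOSUM62).
#'
#' @return An object of class `scoring_scheme`: a list with elements
#'   `alphabet`, `matrix`, `gap_open`, `gap_ext`, `lambda`, `K`.
#' @examples
#' sc <- scoring_scheme("aa")
#' sc$matrix["W", "W"]
#' @export
scoring_scheme <- function(alphabet = c("aa", "nt"),
                           gap_open = NULL, gap_ext = NULL,
                           match = 2, mismatch = -3) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "aa") {
    mat <- blosum62_matrix()
    sc <- list(alphabet = "aa", matrix = mat,
               gap_open = gap_open %||% 11, gap_ext = gap_ext %||% 1,
               lambda = 0.267, K = 0.041)
  } else {
    bases <- c("A", "C", "G", "T", "N")
    mat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
    diag(mat) <- match
    mat["N", ] <- 0
    mat[, "N"] <- 0
    sc <- list(alphabet = "nt", matrix = mat,
               gap_open = gap_open %||% 5, gap_ext = gap_ext %||% 2,
               lambda = 0.625, K = 0.41)
  }
  structure(sc, class = "scoring_scheme")
}

# BLOSUM62 from Biostrings, restricted to residues with defined scores
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  storage.mode(m) <- "double"
  m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s, gap open %g / extend %g, lambda=%g K=%g\n",
              if (x$alphabet == "aa") "BLOSUM62" else "match/mismatch",
              x$gap_open, x$gap_ext, x$lambda, x$K))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bit score and e-value from a raw alignment score
bit_score <- function(score, scoring) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

e_value <- function(score, m, n, scoring) {
  m * n * 2^(-bit_score(score, scoring))
}
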