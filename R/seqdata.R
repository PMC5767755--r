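#' Sequence record tables and genome sets
#'
#' Sequences are carried in plain data frames ("seq_records") with columns
#' `id`, `genome_id`, `seq` and `description`, one row per sequence. A
#' `genome_set` groups, per genome, the nucleotide contigs and the proteome.
#'
#' @param id,genome_id,seq,description character vectors of equal length
#'   (`description` may be omitted).
#' @param alphabet `"aa"` or `"nt"`; residues are validated against it
#'   (IUPAC ambiguity codes are allowed).
#' @return A data.frame of class `seq_records`.
#' @export
seq_records <- function(id, genome_id, seq, description = "",
                        alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  df <- data.frame(id = as.character(id), genome_id = as.character(genome_id),
                   seq = toupper(as.character(seq)),
                   description = as.character(description),
                   stringsAsFactors = FALSE)
  validate_seq_records(df, alphabet)
  structure(df, class = c("seq_records", "data.frame"), alphabet = alphabet)
}

aa_letters <- function() strsplit("ACDEFGHIKLMNPQRSTVWYBZJUOX*", "")[[1]]
nt_letters <- function() strsplit("ACGTUNRYSWKMBDHV", "")[[1]]

validate_seq_records <- function(df, alphabet) {
  if (anyDuplicated(df$id))
    stop("sequence ids must be unique within a collection: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!nzchar(df$seq))) stop("empty sequence for id: ",
                                 paste(df$id[!nzchar(df$seq)], collapse = ", "))
  allowed <- if (alphabet == "aa") aa_letters() else nt_letters()
  bad <- vapply(df$seq, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    any(!ch %in% allowed)
  }, logical(1))
  if (any(bad))
    stop("sequences contain characters outside the ", alphabet,
         " alphabet: ", paste(df$id[bad], collapse = ", "))
  invisible(df)
}

#' Read and write FASTA files
#'
#' Headers follow the convention `>{genome_id}|{gene_id} description`; when a
#' header contains no `|`, the whole first word is used as the record id and
#' `genome_id` is set to `NA`. Lowercase residues are uppercased and a
#' message names the affected records. Writing then re-reading a file
#' preserves ids and sequences exactly.
#'
#' @param path file path.
#' @param alphabet `"aa"` or `"nt"`.
#' @return `read_fasta`: a [seq_records] data frame. `write_fasta`: the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' recs <- seq_records(c("g1|p1", "g1|p2"), "g1", c("MKL", "MRT"))
#' write_fasta(recs, f)
#' read_fasta(f, "aa")
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  headers <- names(set)
  seqs <- as.character(set)
  lower <- grepl("[a-z]", seqs)
  if (any(lower))
    message("uppercased lowercase residues in: ",
            paste(sub("\\s.*$", "", headers[lower]), collapse = ", "))
  first <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  genome <- ifelse(grepl("|", first, fixed = TRUE),
                   sub("\\|.*$", "", first), NA_character_)
  seq_records(first, genome, toupper(seqs), desc, alphabet = alphabet)
}

#' @param records a [seq_records] data frame.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Assemble a genome set
#'
#' @param contigs named list (by genome id) of nucleotide [seq_records].
#' @param proteomes named list (by genome id) of amino-acid [seq_records];
#'   every genome must have a nonempty proteome and every record's
#'   `genome_id` must match the genome it is filed under.
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(contigs, proteomes) {
  ids <- names(proteomes)
  if (is.null(ids) || anyDuplicated(ids))
    stop("proteomes must be a uniquely named list")
  if (!all(names(contigs) %in% ids) && length(contigs))
    stop("contig genome ids not present among proteomes: ",
         paste(setdiff(names(contigs), ids), collapse = ", "))
  for (g in ids) {
    p <- proteomes[[g]]
    if (is.null(p) || nrow(p) == 0L) stop("empty proteome for genome ", g)
    if (!all(p$genome_id == g))
      stop("proteome records of genome ", g, " carry a different genome_id")
    if (!is.null(contigs[[g]]) && nrow(contigs[[g]]) &&
        !all(contigs[[g]]$genome_id == g))
      stop("contig records of genome ", g, " carry a different genome_id")
  }
  structure(list(contigs = contigs, proteomes = proteomes),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  n <- length(x$proteomes)
  np <- vapply(x$proteomes, nrow, integer(1))
  cat(sprintf("<genome_set> %d genomes, %d proteins total\n", n, sum(np)))
  invisible(x)
}

#' @export
genome_ids <- function(x) UseMethod("genome_ids")

#' @export
genome_ids.genome_set <- function(x) names(x$proteomes)

# all proteins of a genome_set as one seq_records table
all_proteins <- function(genomes) {
  do.call(rbind, lapply(unname(genomes$proteomes), as.data.frame))
}
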