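#' Labelled reference protein database
#'
#' A reference database is a data.frame with one row per protein: `id`,
#' `seq`, `lineage` (ordered taxonomy labels joined by `;`, most inclusive
#' first), `in_focal_clade` (does the record come from the focal clade whose
#' exclusive core is being classified?) and `in_comparison_set` (does it come
#' from the wider in-group of genomes the pangenome was built from, e.g.
#' other ammonia-oxidising archaea?).
#'
#' @param id,seq,lineage,in_focal_clade,in_comparison_set vectors of equal
#'   length.
#' @return A data.frame of class `reference_db`.
#' @export
reference_db <- function(id, seq, lineage, in_focal_clade = FALSE,
                         in_comparison_set = FALSE) {
  id <- as.character(id)
  df <- data.frame(id = id, seq = toupper(as.character(seq)),
                   lineage = as.character(lineage),
                   in_focal_clade = rep_len(as.logical(in_focal_clade),
                                            length(id)),
                   in_comparison_set = rep_len(as.logical(in_comparison_set),
                                               length(id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicated reference db ids")
  if (any(!nzchar(df$lineage))) stop("every record needs a nonempty lineage")
  structure(df, class = c("reference_db", "data.frame"))
}

#' Screen a gene family for database homologues
#'
#' Local-aligns every family member against candidate database records and
#' keeps, deduplicated by subject, the records hit by at least one query over
#' at least `min_coverage` of the query's length and above `min_identity`
#' percent identity (identity computed on the aligned region). Relaxing
#' either threshold can only add hits. An empty database yields an empty hit
#' table.
#'
#' @param family_seqs amino-acid [seq_records] for one family.
#' @param db a [reference_db].
#' @param min_identity percent identity strictly required (hits must exceed
#'   it).
#' @param min_coverage minimum aligned fraction of the query length.
#' @param scoring protein [scoring_scheme].
#' @param kmer,min_shared_kmers candidate seeding filter before exact
#'   alignment.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity` (best over queries), `query_coverage`, `lineage`,
#'   `in_focal_clade`, `in_comparison_set`.
#' @export
homology_screen <- function(family_seqs, db, min_identity = 30,
                            min_coverage = 0.70,
                            scoring = scoring_scheme("aa"),
                            kmer = 4, min_shared_kmers = 1) {
  stopifnot(nrow(family_seqs) > 0)
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0),
                      query_coverage = numeric(0), lineage = character(0),
                      in_focal_clade = logical(0),
                      in_comparison_set = logical(0))
  if (nrow(db) == 0L) return(empty)
  cand <- cpp_candidate_pairs_xy(family_seqs$seq, db$seq, kmer,
                                 min_shared_kmers)
  if (nrow(cand) == 0L) return(empty)
  aln <- cpp_align_batch(family_seqs$seq, db$seq, cand$i, cand$j,
                         scoring$matrix, scoring$gap_open, scoring$gap_ext,
                         local = TRUE)
  pid <- ifelse(aln$aln_len > 0, 100 * aln$n_ident / aln$aln_len, 0)
  cov <- (aln$qend - aln$qstart) / nchar(family_seqs$seq)[cand$i]
  keep <- pid > min_identity & cov >= min_coverage
  if (!any(keep)) return(empty)
  hits <- data.frame(query_id = family_seqs$id[cand$i][keep],
                     subject_id = db$id[cand$j][keep],
                     percent_identity = pid[keep], query_coverage = cov[keep],
                     stringsAsFactors = FALSE)
  # deduplicate by subject, keeping the best-identity query
  ord <- order(hits$subject_id, -hits$percent_identity, hits$query_id)
  hits <- hits[ord, ][!duplicated(hits$subject_id[ord]), , drop = FALSE]
  ix <- match(hits$subject_id, db$id)
  hits$lineage <- db$lineage[ix]
  hits$in_focal_clade <- db$in_focal_clade[ix]
  hits$in_comparison_set <- db$in_comparison_set[ix]
  rownames(hits) <- NULL
  hits[order(hits$subject_id), , drop = FALSE]
}

#' Greedy centroid clustering at an identity threshold
#'
#' Processes sequences in deterministic order (length descending, ties by
#' id): each sequence joins the first existing centroid it matches at or
#' above `threshold` percent identity (local alignment), otherwise it founds
#' a new centroid. Every member therefore has >= threshold identity to its
#' centroid.
#'
#' @param seqs named character vector (or [seq_records]) of amino-acid
#'   sequences.
#' @param threshold percent identity for joining a centroid (95 by default,
#'   the usual redundancy-removal level before tree building).
#' @param scoring protein [scoring_scheme].
#' @return List with `centroids` (named character vector) and `membership`
#'   (named character vector mapping every input id to its centroid id).
#' @export
greedy_cluster <- function(seqs, threshold = 95,
                           scoring = scoring_scheme("aa")) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  centroid_ids <- character(0)
  membership <- setNames(character(length(seqs)), names(seqs))
  for (i in seq_along(seqs)) {
    assigned <- NA_character_
    for (cid in centroid_ids) {
      r <- cpp_align(seqs[[i]], seqs[[cid]], scoring$matrix,
                     scoring$gap_open, scoring$gap_ext, local = TRUE)
      pid <- if (r$aln_len > 0) 100 * r$n_ident / r$aln_len else 0
      if (pid >= threshold) { assigned <- cid; break }
    }
    if (is.na(assigned)) {
      centroid_ids <- c(centroid_ids, names(seqs)[i])
      assigned <- names(seqs)[i]
    }
    membership[names(seqs)[i]] <- assigned
  }
  list(centroids = seqs[centroid_ids], membership = membership)
}

#' Bootstrap NJ tree for a gene family and its database homologues
#'
#' Aligns the family sequences together with the homologue centroids (MAFFT),
#' builds a neighbor-joining tree on Poisson-corrected distances, attaches
#' bootstrap clade frequencies and midpoint-roots the result.
#'
#' @param family_seqs amino-acid [seq_records] of the family.
#' @param centroid_seqs named character vector of homologue centroids.
#' @param n_reps bootstrap replicates.
#' @param seed integer seed.
#' @return A rooted [ape::phylo] tree with support values in \[0, 1\] as node
#'   labels.
#' @export
build_family_tree <- function(family_seqs, centroid_seqs = character(0),
                              n_reps = 100, seed = 1L) {
  seqs <- c(setNames(family_seqs$seq, family_seqs$id), centroid_seqs)
  if (length(seqs) < 4)
    stop("need at least 4 sequences for a resolvable topology")
  if (anyDuplicated(names(seqs))) stop("duplicated sequence ids")
  aln <- align_sequences(seqs)
  tree <- bootstrap_nj(aln, n_reps = n_reps, seed = seed)
  midpoint_root(tree)
}

origin_categories <- function() {
  c("clade_specific_novel", "low_identity_unresolved",
    "divergent_ingroup_homolog", "hgt", "ambiguous")
}

#' Classify the origin of a clade-exclusive core family
#'
#' Decision procedure, applied strictly in order:
#' 1. screen the family against the reference database, ignoring records from
#'    the focal clade itself; no outside-clade homologue at all means the
#'    family is novel (`clade_specific_novel`);
#' 2. one to three hits, all within the low-identity band (30-45 percent),
#'    cannot support a phylogeny (`low_identity_unresolved`);
#' 3. otherwise the homologues are clustered at 95 percent identity, the
#'    centroids and family are aligned and a bootstrap NJ tree is built and
#'    midpoint-rooted. If the family is not recovered as a clade, or the
#'    support of the grouping with its sister falls below
#'    `support_threshold`, the call is `ambiguous`. A sister group containing
#'    any comparison-set (in-group) record makes the family a
#'    `divergent_ingroup_homolog`; otherwise the family is called `hgt` and
#'    the donor lineage is the deepest taxonomy label shared by all sister
#'    records.
#'
#' @param family_seqs amino-acid [seq_records] of one clade-exclusive family.
#' @param db a [reference_db].
#' @param family_id identifier recorded in the call.
#' @param min_identity,min_coverage screen thresholds (see
#'   [homology_screen]).
#' @param low_identity_band percent-identity interval defining rule 2.
#' @param max_low_hits maximum hit count for rule 2.
#' @param cluster_threshold centroid clustering identity.
#' @param support_threshold minimum sister support for a confident call.
#' @param n_reps,seed bootstrap parameters.
#' @param scoring protein [scoring_scheme].
#' @return An `origin_call` list: `family_id`, `category`, `donor_lineage`
#'   (non-NA only for hgt), `n_db_homologues`, `n_centroids`, `sister_ids`,
#'   `support`, `tree` (NULL when no tree was built).
#' @export
classify_origin <- function(family_seqs, db, family_id = "family",
                            min_identity = 30, min_coverage = 0.70,
                            low_identity_band = c(30, 45), max_low_hits = 3,
                            cluster_threshold = 95, support_threshold = 0.7,
                            n_reps = 100, seed = 1L,
                            scoring = scoring_scheme("aa")) {
  hits <- homology_screen(family_seqs, db, min_identity, min_coverage,
                          scoring)
  hits <- hits[!hits$in_focal_clade, , drop = FALSE]
  call <- function(category, donor = NA_character_, n_centroids = 0L,
                   sister = character(0), support = NA_real_, tree = NULL) {
    structure(list(family_id = family_id, category = category,
                   donor_lineage = donor, n_db_homologues = nrow(hits),
                   n_centroids = n_centroids, sister_ids = sister,
                   support = support, tree = tree), class = "origin_call")
  }
  if (nrow(hits) == 0L) return(call("clade_specific_novel"))
  low <- hits$percent_identity >= low_identity_band[1] &
    hits$percent_identity <= low_identity_band[2]
  if (nrow(hits) <= max_low_hits && all(low))
    return(call("low_identity_unresolved"))
  hit_seqs <- setNames(db$seq[match(hits$subject_id, db$id)],
                       hits$subject_id)
  cl <- greedy_cluster(hit_seqs, cluster_threshold, scoring)
  n_centroids <- length(cl$centroids)
  if (nrow(family_seqs) + n_centroids < 4)
    return(call("ambiguous", n_centroids = n_centroids))
  tree <- build_family_tree(family_seqs, cl$centroids, n_reps = n_reps,
                            seed = seed)
  if (!is_monophyletic(tree, family_seqs$id))
    return(call("ambiguous", n_centroids = n_centroids, tree = tree))
  sister <- tryCatch(sister_group(tree, family_seqs$id),
                     error = function(e) NULL)
  if (is.null(sister) || length(sister) == 0L)
    return(call("ambiguous", n_centroids = n_centroids, tree = tree))
  support <- attr(sister, "support")
  if (!is.na(support) && support < support_threshold)
    return(call("ambiguous", n_centroids = n_centroids,
                sister = as.character(sister), support = support,
                tree = tree))
  in_group <- db$in_comparison_set[match(sister, db$id)]
  if (any(in_group, na.rm = TRUE))
    return(call("divergent_ingroup_homolog", n_centroids = n_centroids,
                sister = as.character(sister), support = support,
                tree = tree))
  donor <- deepest_shared_lineage(db$lineage[match(sister, db$id)])
  call("hgt", donor = donor, n_centroids = n_centroids,
       sister = as.character(sister), support = support, tree = tree)
}

# deepest (most specific) taxonomy label shared by all lineages
deepest_shared_lineage <- function(lineages) {
  lineages <- lineages[!is.na(lineages)]
  if (length(lineages) == 0L) return(NA_character_)
  parts <- strsplit(lineages, ";", fixed = TRUE)
  depth <- min(lengths(parts))
  shared <- NA_character_
  for (k in seq_len(depth)) {
    lab <- unique(vapply(parts, `[`, character(1), k))
    if (length(lab) == 1) shared <- lab else break
  }
  shared
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("<origin_call> %s: %s%s (%d db homologues, %d centroids)\n",
              x$family_id, x$category,
              if (!is.na(x$donor_lineage))
                paste0(" from ", x$donor_lineage) else "",
              x$n_db_homologues, x$n_centroids))
  invisible(x)
}

#' Tally origin calls by category
#'
#' @param calls list of `origin_call` objects.
#' @return Named integer vector over all categories (zeros included); sums to
#'   `length(calls)`.
#' @export
summarize_origins <- function(calls) {
  cats <- vapply(calls, function(x) x$category, character(1))
  bad <- setdiff(cats, origin_categories())
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  tab <- table(factor(cats, levels = origin_categories()))
  setNames(as.integer(tab), names(tab))
}

#' Classify every family of a clade-exclusive core
#'
#' @param families `ortholog_families` partition.
#' @param family_ids ids of the families to classify (e.g. the output of
#'   [group_specific_core]).
#' @param genomes the [genome_set] holding the member sequences.
#' @param db a [reference_db].
#' @param seed base seed; family k uses `seed + k` for its bootstrap.
#' @param ... passed to [classify_origin].
#' @return Named list of `origin_call` objects.
#' @export
classify_origins <- function(families, family_ids, genomes, db, seed = 1L,
                             ...) {
  prot <- all_proteins(genomes)
  out <- vector("list", length(family_ids))
  names(out) <- family_ids
  for (k in seq_along(family_ids)) {
    fid <- family_ids[k]
    members <- families[[fid]]
    fs <- prot[prot$id %in% members, , drop = FALSE]
    out[[fid]] <- classify_origin(fs, db, family_id = fid,
                                  seed = seed + k, ...)
  }
  out
}
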