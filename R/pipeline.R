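#' Run the full comparative-genomics pipeline
#'
#' Orchestrates the stages end to end on a genome set: all-against-all
#' orthology inference and Markov clustering; pangenome partitioning (core /
#' flexible / unique, per-group tallies, focal-group exclusive core); AAI
#' matrix and dendrogram; optional fragment-based ANI within the focal group;
#' origin classification of every focal-exclusive family against a labelled
#' reference database; marker-based completeness; core/pan rarefaction with
#' exponential fits; and a concatenated single-copy-marker NJ tree with a
#' monophyly/sister assessment of the focal group. All randomness is driven
#' by `seed`; rerunning with identical inputs gives identical results.
#'
#' @param genomes a [genome_set].
#' @param focal_group genome ids of the focal clade.
#' @param db optional [reference_db]; when NULL the origin-classification
#'   stage is skipped.
#' @param groups optional named list of genome-id vectors for per-group
#'   tallies (the focal group is always included).
#' @param params [mcl_params] for orthology.
#' @param marker_refs optional marker reference table for [detect_markers];
#'   when NULL completeness is skipped.
#' @param do_ani compute ANI for all focal-group pairs (fragment-based; the
#'   slowest stage on large genomes).
#' @param n_concat_markers maximum number of single-copy core families used
#'   for the concatenated marker tree.
#' @param n_orderings rarefaction orderings.
#' @param n_boot bootstrap replicates for trees.
#' @param seed integer seed.
#' @return A `pancore_result` list; see the elements set below.
#' @export
run_pipeline <- function(genomes, focal_group, db = NULL, groups = NULL,
                         params = mcl_params(), marker_refs = NULL,
                         do_ani = TRUE, n_concat_markers = 30,
                         n_orderings = 10, n_boot = 100, seed = 1L) {
  gids <- genome_ids(genomes)
  stopifnot(all(focal_group %in% gids))
  groups <- groups %||% list()
  groups$focal <- focal_group

  orth <- infer_families(genomes, params = params)
  m <- orth$presence
  partition <- partition_counts(m, groups)
  core <- core_families(m)
  exclusive <- group_specific_core(m, focal_group)

  aai <- identity_matrix(genomes, kind = "AAI")
  dendro <- identity_dendrogram(aai)

  ani <- NULL
  if (do_ani && length(focal_group) > 1) {
    pairs <- combn(sort(focal_group), 2)
    ani <- data.frame(g1 = pairs[1, ], g2 = pairs[2, ],
                      ani = NA_real_, fraction_fragments = NA_real_)
    for (r in seq_len(ncol(pairs))) {
      v <- compute_ani(genomes, pairs[1, r], pairs[2, r])
      ani$ani[r] <- v$ani
      ani$fraction_fragments[r] <- v$fraction_fragments_used
    }
  }

  origin_calls <- NULL; origin_summary <- NULL
  if (!is.null(db) && length(exclusive)) {
    origin_calls <- classify_origins(orth$families, exclusive, genomes, db,
                                     seed = seed, n_reps = n_boot)
    origin_summary <- summarize_origins(origin_calls)
  }

  completeness <- NULL
  if (!is.null(marker_refs)) {
    completeness <- do.call(rbind, lapply(gids, function(g) {
      counts <- detect_markers(genomes$proteomes[[g]], marker_refs)
      a <- assess_completeness(counts, unique(marker_refs$marker_id))
      data.frame(genome = g, completeness = a$completeness,
                 contamination = a$contamination)
    }))
  }

  raref <- rarefaction(m, n_orderings = n_orderings, seed = seed)
  fits <- list(
    core_tettelin = fit_rarefaction(raref, "tettelin_exp", "core"),
    core_willenbrock = fit_rarefaction(raref, "willenbrock_exp", "core"),
    pan_tettelin = fit_rarefaction(raref, "tettelin_exp", "pan"),
    pan_willenbrock = fit_rarefaction(raref, "willenbrock_exp", "pan"))

  concat <- concat_marker_tree(genomes, orth$families, m, focal_group,
                               n_concat_markers, n_boot, seed)

  structure(list(
    genomes = gids, focal_group = focal_group,
    families = orth$families, presence = m, graph = orth$graph,
    hits = orth$hits, partition = partition, core = core,
    exclusive_core = exclusive, aai = aai, aai_dendrogram = dendro,
    ani = ani, origin_calls = origin_calls, origin_summary = origin_summary,
    completeness = completeness, rarefaction = raref,
    rarefaction_fits = fits, concat = concat, seed = seed,
    params = params), class = "pancore_result")
}

# concatenated single-copy core marker alignment, NJ tree and focal-clade
# monophyly/sister assessment
concat_marker_tree <- function(genomes, families, m, focal_group,
                               n_markers, n_boot, seed) {
  single_copy <- rownames(m)[rowSums(m == 1) == ncol(m)]
  if (length(single_copy) < 2) return(NULL)
  single_copy <- head(sort(single_copy), n_markers)
  prot <- all_proteins(genomes)
  seq_of_id <- setNames(prot$seq, prot$id)
  genome_of <- setNames(prot$genome_id, prot$id)
  alns <- lapply(families[single_copy], function(members) {
    s <- setNames(seq_of_id[members], genome_of[members])
    if (length(unique(nchar(s))) == 1) s else align_sequences(s)
  })
  names(alns) <- single_copy
  conc <- concatenate_markers(alns, genome_roster = genome_ids(genomes))
  tree <- midpoint_root(bootstrap_nj(conc$alignment, n_reps = n_boot,
                                     seed = seed))
  mono <- is_monophyletic(tree, focal_group)
  sister <- if (mono && !setequal(focal_group, tree$tip.label))
    tryCatch(sister_group(tree, focal_group), error = function(e) NULL)
  else NULL
  list(alignment = conc, tree = tree, n_markers = length(single_copy),
       focal_monophyletic = mono, focal_sister = sister)
}

#' @export
print.pancore_result <- function(x, ...) {
  cat(sprintf(
    "<pancore_result> %d genomes, %d families (core %d, exclusive core %d)\n",
    length(x$genomes), x$partition$n_total, x$partition$n_core,
    length(x$exclusive_core)))
  if (!is.null(x$origin_summary)) {
    cat("  origins:",
        paste(names(x$origin_summary), x$origin_summary, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a pipeline result as a directory of plain-text artifacts
#'
#' Emits deterministic, timestamp-free TSV/JSON/newick files: the AAI matrix
#' and dendrogram, optional ANI table, family membership, presence matrix,
#' partition counts, origin calls (one row per exclusive-core family, in the
#' layout of a gene-exchange table: family, category, donor, homologue and
#' centroid counts), completeness table, rarefaction samples and fits, the
#' concatenated-marker tree, and the run parameters. Rerunning with the same
#' inputs and seed reproduces every file byte for byte.
#'
#' @param result a `pancore_result`.
#' @param dir output directory (created if needed).
#' @param genomes the [genome_set] used (for family membership output).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir, genomes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_identity_tsv(result$aai, p("aai.tsv"))
  write_newick(result$aai_dendrogram, p("aai_dendrogram.nwk"))
  if (!is.null(result$ani))
    write.table(result$ani, p("ani_focal.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(genomes))
    write_families_tsv(result$families, genomes, p("families.tsv"))
  write.table(data.frame(family_id = rownames(result$presence),
                         result$presence, check.names = FALSE),
              p("presence.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(partition = result$partition[c("n_total", "n_unique", "n_flexible",
                                        "n_core")],
         n_exclusive_core = length(result$exclusive_core),
         origin_summary = as.list(result$origin_summary %||% list()),
         seed = result$seed,
         params = unclass(result$params)),
    p("summary.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(result$origin_calls)) {
    oc <- do.call(rbind, lapply(result$origin_calls, function(cl)
      data.frame(family_id = cl$family_id, category = cl$category,
                 donor_lineage = cl$donor_lineage,
                 n_db_homologues = cl$n_db_homologues,
                 n_centroids = cl$n_centroids,
                 sister_support = cl$support %||% NA_real_)))
    write.table(oc, p("origin_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(result$completeness))
    write.table(result$completeness, p("completeness.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(result$rarefaction), p("rarefaction.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(result$rarefaction_fits, function(f)
      f[c("model", "curve", "kappa", "tau", "omega", "rss", "converged")]),
    p("rarefaction_fits.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(result$concat)) {
    write_newick(result$concat$tree, p("concat_marker_tree.nwk"))
    jsonlite::write_json(
      list(n_markers = result$concat$n_markers,
           focal_monophyletic = result$concat$focal_monophyletic,
           focal_sister = as.character(result$concat$focal_sister %||%
                                         character(0)),
           sister_support = attr(result$concat$focal_sister, "support") %||%
             NA_real_),
      p("concat_assessment.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  invisible(dir)
}

#' Protein-to-family membership vector
#'
#' @param families an `ortholog_families` object.
#' @return Named character vector mapping every protein id to its family id.
#' @export
family_membership <- function(families) {
  setNames(rep(names(families), lengths(families)),
           unlist(families, use.names = FALSE))
}
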