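#' Poisson-corrected amino-acid distances
#'
#' Pairwise p-distances over the columns where neither sequence has a gap,
#' corrected as `d = -ln(1 - p)`. Saturated pairs (p at or above
#' `1 - exp(-max_distance)`, including pairs with no shared ungapped columns)
#' are assigned the sentinel `max_distance`.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param max_distance saturation sentinel (default `-log(0.01)`).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
aa_distance <- function(aln, max_distance = -log(0.01)) {
  stopifnot(length(aln) >= 2, !is.null(names(aln)))
  w <- unique(nchar(aln))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  M <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(M) <- names(aln)
  poisson_dist_matrix(M, max_distance)
}

# Poisson-corrected distances from an alignment character matrix
poisson_dist_matrix <- function(M, max_distance = -log(0.01)) {
  gap <- M == "-" | M == "."
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      nn <- sum(ok)
      p <- if (nn == 0) 1 else sum(M[i, ok] != M[j, ok]) / nn
      dij <- if (p >= 1 - exp(-max_distance)) max_distance else -log(1 - p)
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining trees with bootstrap support
#'
#' `nj_tree` builds an unrooted neighbor-joining tree (negative branch
#' lengths clamped to zero); on additive distance matrices it recovers the
#' generating topology and branch lengths. `bootstrap_nj` resamples alignment
#' columns with replacement, rebuilds the NJ tree for each replicate and
#' attaches clade frequencies in \[0, 1\] as node labels of the full-data
#' tree. `midpoint_root` roots at the midpoint of the longest leaf-to-leaf
#' path, carrying support labels along.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d)) stop("distance matrix must be square")
    if (nrow(d) < 3) stop("need at least 3 taxa")
    d <- as.dist(d)
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' @param aln named character vector of aligned sequences.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed for column resampling.
#' @param dist_fun function mapping an alignment to a distance matrix.
#' @rdname nj_tree
#' @export
bootstrap_nj <- function(aln, n_reps = 100, seed = 1L,
                         dist_fun = aa_distance) {
  tree <- nj_tree(dist_fun(aln))
  M <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(M) <- names(aln)
  use_fast <- identical(dist_fun, aa_distance)
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample(ncol(M), ncol(M), replace = TRUE)
    Mb <- M[, cols, drop = FALSE]
    boots[[r]] <- tryCatch({
      d <- if (use_fast) poisson_dist_matrix(Mb)
           else dist_fun(setNames(apply(Mb, 1, paste, collapse = ""),
                                  names(aln)))
      nj_tree(d)
    }, error = function(e) NULL)
  }
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- counts / length(boots)
  attr(tree, "n_reps") <- n_reps
  tree
}

#' @param tree an [ape::phylo] tree.
#' @rdname nj_tree
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree, node.labels = "support")
}

#' Clade tests on phylogenies
#'
#' `is_monophyletic` tests whether a taxon set forms a clade: a subtree test
#' on rooted trees, a bipartition (split) test on unrooted trees.
#' `sister_group` returns, in a rooted tree, the leaves of the other child of
#' the clade's parent node, with the bootstrap support of the parent clade
#' attached as attribute `support` (when the parent is the root, the clade's
#' own support is used, as the root split carries no label of its own).
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa,clade character vector of leaf labels.
#' @return `is_monophyletic`: logical. `sister_group`: character vector of
#'   leaf labels with attribute `support`.
#' @export
is_monophyletic <- function(tree, taxa) {
  tl <- tree$tip.label
  unknown <- setdiff(taxa, tl)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) <= 1 || setequal(taxa, tl)) return(TRUE)
  target <- sort(match(taxa, tl))
  parts <- lapply(ape::prop.part(tree), sort)
  if (any(vapply(parts, identical, logical(1), target))) return(TRUE)
  if (!ape::is.rooted(tree)) {
    comp <- sort(setdiff(seq_along(tl), target))
    return(any(vapply(parts, identical, logical(1), comp)))
  }
  FALSE
}

#' @rdname is_monophyletic
#' @export
sister_group <- function(tree, clade) {
  if (!ape::is.rooted(tree)) stop("sister_group needs a rooted tree")
  tl <- tree$tip.label
  unknown <- setdiff(clade, tl)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (setequal(clade, tl)) stop("clade covers all leaves; no sister group")
  ntip <- length(tl)
  if (length(clade) == 1) {
    node <- match(clade, tl)
  } else {
    node <- ape::getMRCA(tree, clade)
    tips <- tl[phangorn::Descendants(tree, node, "tips")[[1]]]
    if (!setequal(tips, clade))
      stop("clade is not monophyletic in this rooted tree")
  }
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(parent) == 0L) stop("clade spans the root; no sister group")
  kids <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], node)
  sis <- sort(unique(unlist(lapply(
    phangorn::Descendants(tree, kids, "tips"), function(ix) tl[ix]))))
  root <- ntip + 1L
  sup_node <- if (parent == root && node > ntip) node else parent
  structure(sis, support = node_support(tree, sup_node, ntip))
}

node_support <- function(tree, node, ntip) {
  if (node <= ntip || is.null(tree$node.label)) return(NA_real_)
  suppressWarnings(as.numeric(tree$node.label[node - ntip]))
}

#' Concatenate single-copy marker alignments
#'
#' Builds one concatenated alignment row per genome from per-marker
#' alignments whose sequence names are genome ids. Markers missing from a
#' genome are filled with gaps of the marker's width; a genome appearing
#' twice in one marker is an error (violates single copy).
#'
#' @param alignments named list of named character vectors (one aligned,
#'   equal-width sequence set per marker).
#' @param genome_roster genome ids to include (default: union over markers).
#' @return A `concat_alignment` list: `alignment` (named character vector,
#'   one row per genome) and `partition` (marker, start, end; 1-based
#'   inclusive column intervals tiling the width).
#' @export
concatenate_markers <- function(alignments, genome_roster = NULL) {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  genome_roster <- genome_roster %||%
    sort(unique(unlist(lapply(alignments, names))))
  pieces <- matrix("", length(genome_roster), length(alignments),
                   dimnames = list(genome_roster, names(alignments)))
  widths <- integer(length(alignments))
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    if (anyDuplicated(names(a)))
      stop("marker ", names(alignments)[k],
           " has multiple sequences for one genome (not single-copy)")
    w <- unique(nchar(a))
    if (length(w) != 1)
      stop("marker ", names(alignments)[k], " rows differ in width")
    widths[k] <- w
    filler <- strrep("-", w)
    pieces[, k] <- ifelse(genome_roster %in% names(a),
                          a[genome_roster], filler)
  }
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  aln <- setNames(apply(pieces, 1, paste, collapse = ""), genome_roster)
  structure(list(alignment = aln,
                 partition = data.frame(marker = names(alignments),
                                        start = starts, end = ends)),
            class = "concat_alignment")
}

#' Multiple sequence alignment via MAFFT
#'
#' Thin wrapper around the external `mafft` binary (auto strategy, input
#' order preserved). Sequences already of equal length pass through MAFFT
#' unchanged in the no-indel case.
#'
#' @param seqs named character vector of unaligned amino-acid sequences.
#' @return Named character vector of aligned sequences (equal width).
#' @export
align_sequences <- function(seqs) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  if (Sys.which("mafft") == "")
    stop("the 'mafft' executable is required but was not found on PATH")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", seqs), fin)
  status <- system2("mafft", c("--auto", "--quiet", "--amino", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  out <- Biostrings::readBStringSet(fout)
  setNames(toupper(as.character(out)), sub("\\s.*$", "", names(out)))
}

#' Read and write trees in newick format
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
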