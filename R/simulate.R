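#' Configuration for the pangenome simulator
#'
#' The simulator emulates a small set of "genera" (clades) of genomes with a
#' known guide tree, gene families stratified into core / clade-exclusive /
#' accessory / unique, nucleotide evolution at calibrated divergence
#' (Jukes-Cantor substitutions at codon level, no indels, stop codons
#' avoided), horizontally transferred families planted at the focal clade's
#' stem from a labelled donor clade, and a labelled reference protein
#' database with planted homologues and random decoys. Every quantity the
#' pipeline estimates is therefore known exactly and recorded in a truth
#' table.
#'
#' The default layout has three clades of four genomes: the focal clade and
#' its true sister clade `alpha` join first, with `beta` outside. Default
#' branch lengths (substitutions/site: tips 0.04, clade stems 0.03-0.05)
#' give within-clade nucleotide divergence 0.08 and cross-clade divergence
#' 0.14-0.18, keeping within-family amino-acid identity comfortably above
#' the level at which graph-based orthology is reliable while separating
#' clades clearly.
#'
#' The focal clade carries `n_exclusive["focal"]` exclusive families whose
#' database footprint follows `focal_origin_profile`: novel families have no
#' database homologue; low-identity families have 1-3 homologues planted in
#' the 30-45 percent identity band; divergent families have in-group
#' (comparison-set) homologues at 50-68 percent; hgt families descend from a
#' donor-clade ancestral gene, with donor database records and two distant
#' out-of-donor context records.
#'
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param clades named list of genome-id vectors; the first clade is focal.
#' @param tip_branch,clade_stem,inner_stem guide-tree branch lengths
#'   (substitutions/site).
#' @param n_core_families,n_accessory,n_unique_per_genome stratum sizes.
#' @param n_exclusive named vector of clade-exclusive family counts.
#' @param focal_origin_profile named vector (novel, low_identity, divergent,
#'   hgt) summing to `n_exclusive` of the focal clade.
#' @param accessory_loss_prob per-branch loss probability of accessory
#'   families.
#' @param duplication_prob per-genome probability that a core family gains an
#'   in-paralog copy.
#' @param gene_length_codons mean gene length in codons.
#' @param donor_lineage taxonomy string of the HGT donor clade.
#' @param n_donor_records,donor_radiation,hgt_residence_divergence donor
#'   clade size, its internal divergence, and the divergence accumulated on
#'   the transferred copy before the focal radiation.
#' @param n_ingroup_records in-group homologues per divergent family.
#' @param n_decoys random unrelated database records.
#' @param n_marker_families core families also used as single-copy marker
#'   references.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       clades = list(focal = paste0("FOC", 1:4),
                                     alpha = paste0("ALP", 1:4),
                                     beta = paste0("BET", 1:4)),
                       tip_branch = 0.04, clade_stem = 0.03,
                       inner_stem = 0.02,
                       n_core_families = 60,
                       n_exclusive = c(focal = 103, alpha = 12, beta = 12),
                       focal_origin_profile = c(novel = 38, low_identity = 12,
                                                divergent = 45, hgt = 8),
                       n_accessory = 20, accessory_loss_prob = 0.25,
                       n_unique_per_genome = 2, duplication_prob = 0,
                       gene_length_codons = 250,
                       donor_lineage =
                         "Archaea;Euryarchaeota;Thermoplasmata;Thermoplasmatales",
                       n_donor_records = 5, donor_radiation = 0.06,
                       hgt_residence_divergence = 0.05,
                       n_ingroup_records = 4, n_decoys = 60,
                       n_marker_families = 40) {
  stopifnot(length(clades) >= 2, !is.null(names(clades)),
            !anyDuplicated(unlist(clades)),
            all(names(n_exclusive) %in% names(clades)),
            sum(focal_origin_profile) == n_exclusive[[names(clades)[1]]],
            accessory_loss_prob >= 0, accessory_loss_prob <= 1,
            duplication_prob >= 0, duplication_prob <= 1,
            tip_branch >= 0, n_core_families >= 1,
            n_marker_families <= n_core_families)
  structure(as.list(environment()), class = "sim_config")
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G"))[, 3:1], 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# codons grouped by the amino acid they encode
CODONS_BY_AA <- split(SENSE_CODONS,
                      Biostrings::GENETIC_CODE[SENSE_CODONS])

# ancestral genes encode uniformly drawn amino acids (with a random
# synonymous codon each), so proteins have even residue usage rather than
# the codon-count-skewed usage uniform codon sampling would give
random_gene <- function(n_codons) {
  aa <- sample(names(CODONS_BY_AA), n_codons, replace = TRUE)
  paste(vapply(CODONS_BY_AA[aa], function(cs)
    cs[[sample.int(length(cs), 1)]], character(1)), collapse = "")
}

translate_nt <- function(s) {
  n <- nchar(s)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Evolve a nucleotide sequence at a given divergence
#'
#' Jukes-Cantor substitution: each site experiences a Poisson(divergence)
#' number of substitution events, equivalent to keeping the original base
#' with probability `1/4 + 3/4 * exp(-4 d / 3)` and otherwise drawing
#' uniformly among the three alternatives. With `stop_free = TRUE` (for
#' coding sequences) any codon mutated into a stop has its changed sites
#' redrawn, which leaves the expected fraction of differing sites essentially
#' at the Jukes-Cantor value `3/4 * (1 - exp(-4 d / 3))`.
#'
#' @param seq nucleotide string (length a multiple of 3 when
#'   `stop_free = TRUE`).
#' @param divergence expected substitutions per site, in \[0, 3\].
#' @param seed optional integer seed for this call only.
#' @param stop_free avoid creating in-frame stop codons.
#' @return The evolved sequence string, with attribute `realized_identity`
#'   (fraction of unchanged sites).
#' @export
evolve_sequence <- function(seq, divergence, seed = NULL, stop_free = TRUE) {
  stopifnot(divergence >= 0, divergence <= 3)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * divergence / 3)
  change <- runif(n) > p_same
  if (any(change)) {
    # uniform draw among the three alternative bases: shift the base index
    # by 1..3 modulo 4
    pick <- function(cur) {
      idx0 <- match(cur, bases) - 1L
      bases[(idx0 + sample.int(3, length(cur), replace = TRUE)) %% 4L + 1L]
    }
    x[change] <- pick(x[change])
    if (stop_free && n %% 3 == 0) {
      for (tries in 1:10) {
        codon_start <- seq(1, n, by = 3)
        codons <- paste0(x[codon_start], x[codon_start + 1],
                         x[codon_start + 2])
        bad <- which(codons %in% c("TAA", "TAG", "TGA"))
        if (length(bad) == 0) break
        for (b in bad) {
          sites <- (3 * (b - 1) + 1):(3 * b)
          ch <- sites[change[sites]]
          if (length(ch) == 0) { # ancestral stop cannot occur; safety net
            ch <- sites[1]; change[ch] <- TRUE
          }
          x[ch] <- pick(x[ch])
        }
      }
      # final safety: revert any codon still a stop
      codon_start <- seq(1, n, by = 3)
      codons <- paste0(x[codon_start], x[codon_start + 1], x[codon_start + 2])
      orig <- strsplit(seq, "")[[1]]
      for (b in which(codons %in% c("TAA", "TAG", "TGA"))) {
        sites <- (3 * (b - 1) + 1):(3 * b)
        x[sites] <- orig[sites]
      }
    }
  }
  out <- paste(x, collapse = "")
  attr(out, "realized_identity") <- cpp_hamming_identity(seq, out)
  out
}

# nested guide tree: first two clades are sisters, others attach at the root
make_sim_tree <- function(clades, tip_branch, clade_stem, inner_stem) {
  clade_node <- function(name) {
    list(name = paste0("anc_", name), bl = clade_stem,
         children = lapply(clades[[name]], function(g)
           list(name = g, bl = tip_branch, children = NULL)))
  }
  nm <- names(clades)
  inner <- list(name = "anc_inner", bl = inner_stem,
                children = list(clade_node(nm[1]), clade_node(nm[2])))
  rest <- lapply(nm[-(1:2)], clade_node)
  list(name = "root", bl = 0, children = c(list(inner), rest))
}

tree_to_newick <- function(node) {
  if (is.null(node$children)) return(sprintf("%s:%g", node$name, node$bl))
  inner <- paste(vapply(node$children, tree_to_newick, character(1)),
                 collapse = ",")
  if (node$name == "root") sprintf("(%s)root;", inner)
  else sprintf("(%s)%s:%g", inner, node$name, node$bl)
}

# evolve a root sequence down the (sub)tree; returns named list tip -> seq
evolve_down <- function(node, seq) {
  if (is.null(node$children)) return(setNames(list(seq), node$name))
  out <- list()
  for (ch in node$children)
    out <- c(out, evolve_down(ch, evolve_sequence(seq, ch$bl)))
  out
}

# presence pattern of an accessory family: present at the root, lost with
# probability p on each branch
presence_down <- function(node, present, p) {
  if (is.null(node$children)) return(setNames(present, node$name))
  out <- logical(0)
  for (ch in node$children) {
    child_present <- present && (runif(1) > p)
    out <- c(out, presence_down(ch, child_present, p))
  }
  out
}

find_node <- function(node, name) {
  if (node$name == name) return(node)
  for (ch in node$children %||% list()) {
    r <- find_node(ch, name)
    if (!is.null(r)) return(r)
  }
  NULL
}

# evolve until the translated product's identity to the ancestor's product
# falls inside [window] (percent); the divergence is nudged toward the window
evolve_to_aa_window <- function(anc_nt, d0, window, max_tries = 60) {
  d <- d0
  best <- NULL; best_gap <- Inf
  anc_aa <- translate_nt(anc_nt)
  for (i in seq_len(max_tries)) {
    cand <- evolve_sequence(anc_nt, min(d, 3))
    idy <- 100 * cpp_hamming_identity(translate_nt(cand), anc_aa)
    if (idy >= window[1] && idy <= window[2]) return(cand)
    gap <- min(abs(idy - window))
    if (gap < best_gap) { best <- cand; best_gap <- gap }
    d <- d * if (idy > window[2]) 1.12 else 0.89
  }
  best
}

#' Simulate a pangenome with planted truth
#'
#' Generates, from a [sim_config], a [genome_set] (nucleotide contig plus
#' proteome per genome), a labelled [reference_db] and a truth table. Genes
#' are ancestral random codon sequences evolved along the guide tree;
#' horizontally transferred families descend from the donor clade's ancestral
#' gene rather than the focal backbone; each genome's contig is its genes
#' concatenated with short random intergenic spacers. Identical seeds give
#' byte-identical output.
#'
#' @param config a [sim_config].
#' @return List with elements `genomes`, `db`, `truth`. The truth table is a
#'   list holding the family strata and donor assignments (`families`), the
#'   true presence matrix (`presence`), realized per-pair nucleotide and
#'   amino-acid identities per family (`identities`), the database record
#'   roles (`db_truth`), marker reference sequences (`marker_refs`), the
#'   guide tree (`guide_tree`, ape phylo) with the focal clade's true sister
#'   clade (`true_sister`), and the config.
#' @export
simulate_pangenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  clades <- config$clades
  focal <- names(clades)[1]
  genomes <- unlist(clades, use.names = FALSE)
  tree <- make_sim_tree(clades, config$tip_branch, config$clade_stem,
                        config$inner_stem)
  clade_of <- setNames(rep(names(clades), lengths(clades)), genomes)

  ingroup_lineages <- setNames(
    paste0("Archaea;Thaumarchaeota;Nitrososphaerales;Clade_", names(clades)),
    names(clades))
  decoy_lineages <- c(
    "Bacteria;Proteobacteria;Rhizobiales;Sneathiella",
    "Bacteria;Firmicutes;Bacillales;Bacillus",
    "Bacteria;Dependentiae;Babeliales;Babelia",
    "Archaea;Euryarchaeota;Methanosarcinales;Methanosarcina",
    "Archaea;Woesearchaeota;Woesearchaeales;Woesearchaeum",
    "Bacteria;Actinobacteria;Streptomycetales;Streptomyces")

  gene_len <- function(n) {
    pmax(120L, pmin(600L, round(rgamma(n, shape = 8,
                                       scale = config$gene_length_codons / 8))))
  }

  fam_rows <- list(); gene_pool <- list(); spacer_pool <- list()
  db_rows <- list()
  marker_refs <- list()
  presence <- NULL
  add_family <- function(fid, stratum, clade, origin, donor, tip_seqs,
                         subtree) {
    fam_rows[[fid]] <<- data.frame(
      family_id = fid, stratum = stratum, clade = clade, origin = origin,
      donor_lineage = donor, stringsAsFactors = FALSE)
    gene_pool[[fid]] <<- tip_seqs
    # intergenic spacer upstream of the gene, evolved along the same tree so
    # that genome-wide identity tracks the configured divergence
    spacer <- paste(sample(c("A", "C", "G", "T"), 30 + sample.int(50, 1),
                           replace = TRUE), collapse = "")
    spacer_pool[[fid]] <<- evolve_down(subtree, spacer)
  }

  fam_counter <- 0L
  next_fid <- function() {
    fam_counter <<- fam_counter + 1L
    sprintf("OG%04d", fam_counter)
  }

  # --- core families ------------------------------------------------------
  core_ids <- character(config$n_core_families)
  for (k in seq_len(config$n_core_families)) {
    fid <- next_fid(); core_ids[k] <- fid
    anc <- random_gene(gene_len(1))
    tips <- evolve_down(tree, anc)
    add_family(fid, "core", NA_character_, NA_character_, NA_character_,
               tips, tree)
    if (k <= config$n_marker_families)
      marker_refs[[fid]] <- data.frame(marker_id = fid,
                                       id = paste0("ref|", fid),
                                       seq = translate_nt(anc),
                                       stringsAsFactors = FALSE)
  }

  # --- clade-exclusive families ------------------------------------------
  origin_plan <- rep(names(config$focal_origin_profile),
                     config$focal_origin_profile)
  low_hit_plan <- rep_len(1:3, sum(origin_plan == "low_identity"))
  low_i <- 0L
  for (cl in names(config$n_exclusive)) {
    anc_node <- find_node(tree, paste0("anc_", cl))
    sub <- list(name = anc_node$name, bl = 0, children = anc_node$children)
    for (k in seq_len(config$n_exclusive[[cl]])) {
      fid <- next_fid()
      origin <- if (cl == focal) origin_plan[k] else NA_character_
      if (identical(origin, "hgt")) {
        donor_anc <- random_gene(gene_len(1))
        recipient <- evolve_sequence(donor_anc,
                                     config$hgt_residence_divergence)
        tips <- evolve_down(sub, recipient)
        add_family(fid, "clade_exclusive", cl, "hgt", config$donor_lineage,
                   tips, sub)
        # donor records form a coherent clade (crown radiating from a stem
        # below the transfer point), as homologues within one donor lineage
        # would in reality
        donor_crown <- evolve_sequence(donor_anc, 0.12)
        for (r in seq_len(config$n_donor_records)) {
          rid <- sprintf("%s_donor%02d", fid, r)
          db_rows[[rid]] <- data.frame(
            id = rid, seq = translate_nt(
              evolve_sequence(donor_crown, config$donor_radiation)),
            lineage = config$donor_lineage, in_focal_clade = FALSE,
            in_comparison_set = FALSE, family_id = fid, role = "donor",
            stringsAsFactors = FALSE)
        }
        # a distant outgroup pair rooting the family tree
        ctx_anc <- evolve_to_aa_window(donor_anc, 0.5, c(34, 44))
        for (r in 1:2) {
          rid <- sprintf("%s_ctx%02d", fid, r)
          db_rows[[rid]] <- data.frame(
            id = rid,
            seq = translate_nt(evolve_sequence(ctx_anc, 0.06)),
            lineage = decoy_lineages[1 + (r %% length(decoy_lineages))],
            in_focal_clade = FALSE, in_comparison_set = FALSE,
            family_id = fid, role = "outgroup_context",
            stringsAsFactors = FALSE)
        }
      } else {
        anc <- random_gene(gene_len(1))
        tips <- evolve_down(sub, anc)
        add_family(fid, "clade_exclusive", cl, origin,
                   NA_character_, tips, sub)
        if (identical(origin, "divergent")) {
          # the in-group homologues descend from one divergent ancestor and
          # radiate mildly, forming a clade sister to the family
          other <- setdiff(names(clades), focal)
          div_anc <- evolve_to_aa_window(anc, 0.30, c(52, 68))
          for (r in seq_len(config$n_ingroup_records)) {
            rid <- sprintf("%s_ing%02d", fid, r)
            src <- other[1 + (r %% length(other))]
            db_rows[[rid]] <- data.frame(
              id = rid,
              seq = translate_nt(evolve_sequence(div_anc, 0.06)),
              lineage = ingroup_lineages[[src]], in_focal_clade = FALSE,
              in_comparison_set = TRUE, family_id = fid,
              role = "ingroup_homolog", stringsAsFactors = FALSE)
          }
        } else if (identical(origin, "low_identity")) {
          low_i <- low_i + 1L
          for (r in seq_len(low_hit_plan[low_i])) {
            rid <- sprintf("%s_low%02d", fid, r)
            db_rows[[rid]] <- data.frame(
              id = rid,
              seq = translate_nt(evolve_to_aa_window(anc, 0.55, c(33, 41))),
              lineage = decoy_lineages[1 + (r %% length(decoy_lineages))],
              in_focal_clade = FALSE, in_comparison_set = FALSE,
              family_id = fid, role = "low_identity",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  # --- accessory families -------------------------------------------------
  for (k in seq_len(config$n_accessory)) {
    fid <- next_fid()
    pattern <- NULL
    for (tries in 1:20) {
      pattern <- presence_down(tree, TRUE, config$accessory_loss_prob)
      if (sum(pattern) >= 2) break
    }
    anc <- random_gene(gene_len(1))
    tips <- evolve_down(tree, anc)
    tips <- tips[names(pattern)[pattern]]
    add_family(fid, "accessory", NA_character_, NA_character_,
               NA_character_, tips, tree)
  }

  # --- unique families ----------------------------------------------------
  for (g in genomes) {
    for (k in seq_len(config$n_unique_per_genome)) {
      fid <- next_fid()
      add_family(fid, "unique", NA_character_, NA_character_, NA_character_,
                 setNames(list(random_gene(gene_len(1))), g),
                 list(name = g, bl = 0, children = NULL))
    }
  }

  families <- do.call(rbind, fam_rows)
  rownames(families) <- NULL
  aa_pool <- lapply(gene_pool, function(tips) lapply(tips, translate_nt))

  # --- optional in-paralog duplications -----------------------------------
  dup_rows <- list()
  if (config$duplication_prob > 0) {
    for (fid in core_ids) {
      for (g in genomes) {
        if (runif(1) < config$duplication_prob) {
          dup_rows[[paste(fid, g)]] <-
            list(fid = fid, g = g,
                 seq = evolve_sequence(gene_pool[[fid]][[g]], 0.01))
        }
      }
    }
  }

  # --- assemble genomes ---------------------------------------------------
  presence <- matrix(0L, nrow(families), length(genomes),
                     dimnames = list(families$family_id, genomes))
  contigs <- list(); proteomes <- list()
  for (g in genomes) {
    gene_ids <- character(0); nt <- character(0); aa <- character(0)
    for (fid in families$family_id) {
      s <- gene_pool[[fid]][[g]]
      if (is.null(s)) next
      presence[fid, g] <- presence[fid, g] + 1L
      gene_ids <- c(gene_ids, paste0(g, "|", fid))
      nt <- c(nt, as.character(s))
      aa <- c(aa, aa_pool[[fid]][[g]])
    }
    for (d in dup_rows) {
      if (d$g != g) next
      presence[d$fid, g] <- presence[d$fid, g] + 1L
      gene_ids <- c(gene_ids, paste0(g, "|", d$fid, ".2"))
      nt <- c(nt, as.character(d$seq))
      aa <- c(aa, translate_nt(d$seq))
    }
    fams_here <- sub("\\.\\d+$", "", sub("^.*\\|", "", gene_ids))
    spacers <- vapply(fams_here, function(fid)
      as.character(spacer_pool[[fid]][[g]]), character(1))
    contig <- paste(rbind(spacers, nt), collapse = "")
    contigs[[g]] <- seq_records(paste0(g, "|c1"), g, contig, alphabet = "nt")
    proteomes[[g]] <- seq_records(gene_ids, g, aa, alphabet = "aa")
  }
  gs <- genome_set(contigs, proteomes)

  # --- reference database -------------------------------------------------
  for (k in seq_len(config$n_decoys)) {
    rid <- sprintf("decoy%03d", k)
    db_rows[[rid]] <- data.frame(
      id = rid, seq = translate_nt(random_gene(gene_len(1))),
      lineage = if (k %% 4 == 0)
        ingroup_lineages[[1 + (k %% length(clades))]]
      else decoy_lineages[1 + (k %% length(decoy_lineages))],
      in_focal_clade = FALSE, in_comparison_set = k %% 4 == 0,
      family_id = NA_character_, role = "decoy", stringsAsFactors = FALSE)
  }
  db_all <- do.call(rbind, db_rows)
  rownames(db_all) <- NULL
  db <- reference_db(db_all$id, db_all$seq, db_all$lineage,
                     db_all$in_focal_clade, db_all$in_comparison_set)

  # --- realized identities (self-audit source) ----------------------------
  id_rows <- lapply(families$family_id, function(fid) {
    present <- sort(names(gene_pool[[fid]]))
    if (length(present) < 2) return(NULL)
    cmb <- combn(present, 2)
    data.frame(
      family_id = fid, g1 = cmb[1, ], g2 = cmb[2, ],
      nt_identity = 100 * mapply(function(a, b) cpp_hamming_identity(
        as.character(gene_pool[[fid]][[a]]),
        as.character(gene_pool[[fid]][[b]])), cmb[1, ], cmb[2, ]),
      aa_identity = 100 * mapply(function(a, b) cpp_hamming_identity(
        aa_pool[[fid]][[a]], aa_pool[[fid]][[b]]), cmb[1, ], cmb[2, ]),
      stringsAsFactors = FALSE)
  })

  guide <- ape::read.tree(text = tree_to_newick(tree))
  truth <- list(families = families, presence = presence,
                identities = do.call(rbind, id_rows),
                db_truth = db_all[, c("id", "family_id", "role", "lineage")],
                marker_refs = do.call(rbind, marker_refs),
                guide_tree = guide, focal_clade = focal,
                true_sister = names(clades)[2], clade_of = clade_of,
                config = config)
  rownames(truth$identities) <- NULL
  class(truth) <- "sim_truth"
  list(genomes = gs, db = db, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d families / %d genomes; strata: %s\n",
    nrow(x$families), ncol(x$presence),
    paste(names(table(x$families$stratum)), table(x$families$stratum),
          sep = "=", collapse = ", ")))
  invisible(x)
}
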