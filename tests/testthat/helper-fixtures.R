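# shared fixtures, computed once per test run

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 3) {
  sim_config(
    seed = seed,
    clades = list(focal = paste0("FOC", 1:3), alpha = paste0("ALP", 1:3),
                  beta = paste0("BET", 1:3)),
    n_core_families = 12,
    n_exclusive = c(focal = 9, alpha = 3, beta = 3),
    focal_origin_profile = c(novel = 2, low_identity = 2, divergent = 3,
                             hgt = 2),
    n_accessory = 5, n_unique_per_genome = 1, n_decoys = 20,
    gene_length_codons = 180, n_marker_families = 8)
}

small_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_pangenome(small_config())
  .fixtures$sim
}

small_orth <- function() {
  if (is.null(.fixtures$orth)) .fixtures$orth <- infer_families(small_sim()$genomes)
  .fixtures$orth
}

# truth family id encoded in every simulated protein id ("genome|OGxxxx[.k]")
truth_family_of <- function(protein_ids) {
  sub("\\.\\d+$", "", sub("^.*\\|", "", protein_ids))
}

random_aa <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

translate_seq <- function(s) pancore:::translate_nt(s)
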