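# Small in-code fixtures shared across test files.

# A hand-built 4-taxon table: 1 site x 3 field replicates, 1 positive,
# 1 negative control.
tiny_table <- function() {
  counts <- rbind(
    Sebastes  = c(500, 480, 520, 0,   0),
    Embiotoca = c(100, 120,  90, 0,   0),
    Gallus    = c(  1,   0,   0, 2,   1),
    Homo      = c( 30,  25,  28, 0,  40))
  colnames(counts) <- c("S1_1", "S1_2", "S1_3", "POS_1", "NEG_1")
  meta <- data.frame(
    replicate_id = colnames(counts),
    site_id = c("S1", "S1", "S1", "POS_1", "NEG_1"),
    habitat = c(rep("kelp_forest", 3), "control", "control"),
    distance_m = c(100, 100, 100, NA, NA),
    depth_m = c(5, 5, 5, NA, NA),
    role = c("field", "field", "field", "positive", "negative"),
    stringsAsFactors = FALSE)
  taxa <- data.frame(
    taxon_id = rownames(counts),
    rank = "genus",
    lineage = c(
      "class:Actinopterygii;order:Perciformes;family:Sebastidae;genus:Sebastes",
      "class:Actinopterygii;order:Perciformes;family:Embiotocidae;genus:Embiotoca",
      "class:Aves;order:Galliformes;family:Phasianidae;genus:Gallus",
      "class:Mammalia;order:Primates;family:Hominidae;genus:Homo"),
    stringsAsFactors = FALSE)
  taxon_table(counts, meta, taxa)
}

# Toy taxonomy: two rockfish-family genera, a surfperch, a tuna, plus humans.
toy_tree <- function() {
  build_taxonomy(c(
    "class:Actinopterygii;order:Perciformes;family:Sebastidae;genus:Sebastes",
    "class:Actinopterygii;order:Perciformes;family:Sebastidae;genus:Sebastolobus",
    "class:Actinopterygii;order:Perciformes;family:Embiotocidae;genus:Embiotoca",
    "class:Actinopterygii;order:Scombriformes;family:Scombridae;genus:Thunnus",
    "class:Mammalia;order:Primates;family:Hominidae;genus:Homo"))
}

# A compact 3-habitat design used where the full 12-site transect is overkill.
small_design <- function(n_taxa = 8, n_replicates = 3) {
  taxa <- default_taxa()[seq_len(n_taxa), ]
  hab <- setdiff(names(taxa), c("taxon_id", "lineage"))
  # flatten affinities so every taxon is solidly present in every habitat
  taxa[hab] <- 1
  sites <- data.frame(site_id = c("A", "B", "C"),
                      habitat = c("seagrass", "kelp_forest", "rocky_reef"),
                      distance_m = c(50, 150, 400), depth_m = c(2, 6, 20),
                      stringsAsFactors = FALSE)
  transect_design(sites, taxa, n_replicates_per_site = n_replicates)
}

quiet_noise <- function(seed = 1, contaminants = default_contaminants()[0, ]) {
  noise_model(contaminants = contaminants, spurious_annotation_rate = 0,
              replicate_dispersion = 0, tag_jump_rate = 0, seed = seed)
}

# mock compositions restricted to taxa that exist in a reduced design
small_mocks <- function(design, n_members = 5) {
  members <- design$taxa$taxon_id[seq_len(min(n_members, nrow(design$taxa)))]
  list(mock1 = stats::setNames(rep(1 / length(members), length(members)),
                               members),
       sword1 = c(Xiphias = 1))
}
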