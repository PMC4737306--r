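#' Default transect site layout
#'
#' Twelve sites across five habitat types (seagrass, kelp forest, sandy
#' bottom, rocky reef, open water) along a 2.5 km cross-shore transect, with
#' distance from shore and depth for each site.
#'
#' @return data.frame (`site_id`, `habitat`, `distance_m`, `depth_m`).
#' @export
default_sites <- function() {
  data.frame(
    site_id = c("SGin", "SGout", "KFin", "KFmid", "KFout", "SBshallow",
                "RR1", "RR2", "SBdeep", "OW1", "OW2", "OW3"),
    habitat = c("seagrass", "seagrass", "kelp_forest", "kelp_forest",
                "kelp_forest", "sandy_bottom", "rocky_reef", "rocky_reef",
                "sandy_bottom", "open_water", "open_water", "open_water"),
    distance_m = c(44, 97, 140, 206, 262, 355, 421, 470, 596, 978, 1436, 2665),
    depth_m = c(2, 3, 5, 9, 12, 18, 21, 24, 30, 48, 55, 70),
    stringsAsFactors = FALSE)
}

#' Default transect community
#'
#' Twenty-two vertebrate genera typical of a temperate kelp-forest ecosystem
#' (rockfish, greenlings, surfperch, flatfish, anchovies, pinnipeds, sea
#' otters, cormorants, ...), each with a lineage path and a nonnegative
#' habitat-affinity weight per habitat. Within a site, expected relative
#' abundances are the habitat-normalized affinities.
#'
#' @return data.frame with `taxon_id`, `lineage` and one affinity column per
#'   habitat.
#' @export
default_taxa <- function() {
  L <- function(cls, ord, fam, gen, sub = NULL) {
    mid <- if (is.null(sub)) sprintf("order:%s", ord)
           else sprintf("order:%s;suborder:%s", ord, sub)
    sprintf("class:%s;%s;family:%s;genus:%s", cls, mid, fam, gen)
  }
  fish <- function(ord, fam, gen, sub = NULL) L("Actinopterygii", ord, fam, gen, sub)
  tx <- rbind(
    c("Sebastes",        fish("Perciformes", "Sebastidae", "Sebastes"),        0.5, 3.0, 0.5, 3.0, 0.2),
    c("Paralabrax",      fish("Perciformes", "Serranidae", "Paralabrax"),      0.5, 1.0, 0.0, 0.8, 0.0),
    c("Hexagrammos",     fish("Perciformes", "Hexagrammidae", "Hexagrammos"),  0.2, 2.0, 0.2, 2.0, 0.0),
    c("Ophiodon",        fish("Perciformes", "Hexagrammidae", "Ophiodon"),     0.0, 1.5, 0.3, 2.0, 0.0),
    c("Oxylebius",       fish("Perciformes", "Hexagrammidae", "Oxylebius"),    0.0, 1.5, 0.0, 1.5, 0.0),
    c("Scorpaenichthys", fish("Perciformes", "Cottidae", "Scorpaenichthys"),   0.3, 1.5, 0.0, 1.5, 0.0),
    c("Oxyjulis",        fish("Labriformes", "Labridae", "Oxyjulis"),          0.5, 3.0, 0.0, 1.0, 0.0),
    c("Embiotoca",       fish("Perciformes", "Embiotocidae", "Embiotoca"),     3.0, 1.0, 0.0, 0.3, 0.0),
    c("Rhacochilus",     fish("Perciformes", "Embiotocidae", "Rhacochilus"),   3.0, 1.0, 0.0, 0.3, 0.0),
    c("Cebidichthys",    fish("Perciformes", "Stichaeidae", "Cebidichthys", "Zoarcoidei"), 0.3, 0.8, 0.0, 0.8, 0.0),
    c("Apodichthys",     fish("Perciformes", "Pholidae", "Apodichthys", "Zoarcoidei"),     0.5, 1.0, 0.0, 1.0, 0.0),
    c("Gibbonsia",       fish("Blenniiformes", "Clinidae", "Gibbonsia"),       1.0, 1.5, 0.0, 0.5, 0.0),
    c("Citharichthys",   fish("Pleuronectiformes", "Paralichthyidae", "Citharichthys"), 0.2, 0.0, 3.0, 0.2, 0.0),
    c("Psettichthys",    fish("Pleuronectiformes", "Pleuronectidae", "Psettichthys"),   0.0, 0.0, 2.5, 0.0, 0.0),
    c("Atherinops",      fish("Atheriniformes", "Atherinopsidae", "Atherinops"), 1.5, 0.5, 0.2, 0.0, 0.2),
    c("Engraulis",       fish("Clupeiformes", "Engraulidae", "Engraulis"),     0.0, 0.2, 0.5, 0.2, 3.0),
    c("Oncorhynchus",    fish("Salmoniformes", "Salmonidae", "Oncorhynchus"),  0.2, 0.3, 0.2, 0.2, 1.0),
    c("Enhydra",   L("Mammalia", "Carnivora", "Mustelidae", "Enhydra"),        0.5, 2.0, 0.0, 1.0, 0.0),
    c("Phoca",     L("Mammalia", "Carnivora", "Phocidae", "Phoca"),            2.0, 0.5, 0.5, 0.3, 0.2),
    c("Zalophus",  L("Mammalia", "Carnivora", "Otariidae", "Zalophus"),        0.0, 0.2, 0.0, 0.2, 2.0),
    c("Grampus",   L("Mammalia", "Cetacea", "Delphinidae", "Grampus"),         0.0, 0.0, 0.0, 0.0, 1.5),
    c("Phalacrocorax", L("Aves", "Suliformes", "Phalacrocoracidae", "Phalacrocorax"), 2.0, 0.5, 0.2, 0.0, 0.0))
  out <- data.frame(taxon_id = tx[, 1], lineage = tx[, 2],
                    stringsAsFactors = FALSE)
  aff <- apply(tx[, 3:7], 2, as.numeric)
  colnames(aff) <- c("seagrass", "kelp_forest", "sandy_bottom", "rocky_reef",
                     "open_water")
  cbind(out, aff)
}

#' Default contaminant taxa
#'
#' Reagent-borne contamination (chicken, scope `"all"`: present in every
#' replicate including positive controls, so it is what sets the
#' low-frequency noise threshold) and handling-borne human contamination
#' (scope `"field_negative"`: field samples and blanks only).
#'
#' @return data.frame (`taxon_id`, `rate`, `scope`, `lineage`).
#' @export
default_contaminants <- function() {
  data.frame(
    taxon_id = c("Gallus", "Homo"),
    rate = c(2e-04, 0.28),
    scope = c("all", "field_negative"),
    lineage = c("class:Aves;order:Galliformes;family:Phasianidae;genus:Gallus",
                "class:Mammalia;order:Primates;family:Hominidae;genus:Homo"),
    stringsAsFactors = FALSE)
}

#' Default pool of off-community taxa for spurious annotations
#'
#' Targets of read misannotation: taxa outside the simulated community whose
#' families may or may not occur locally, exercising both branches of the
#' geographic filter (family-level reassignment vs exotic removal).
#'
#' @return data.frame (`taxon_id`, `lineage`).
#' @export
default_spurious_pool <- function() {
  data.frame(
    taxon_id = c("Epinephelus", "Etropus", "Odontesthes", "Plectobranchus",
                 "Thunnus", "Meleagris"),
    lineage = c(
      "class:Actinopterygii;order:Perciformes;family:Serranidae;genus:Epinephelus",
      "class:Actinopterygii;order:Pleuronectiformes;family:Paralichthyidae;genus:Etropus",
      "class:Actinopterygii;order:Atheriniformes;family:Atherinopsidae;genus:Odontesthes",
      "class:Actinopterygii;order:Perciformes;suborder:Zoarcoidei;family:Stichaeidae;genus:Plectobranchus",
      "class:Actinopterygii;order:Scombriformes;family:Scombridae;genus:Thunnus",
      "class:Aves;order:Galliformes;family:Phasianidae;genus:Meleagris"),
    stringsAsFactors = FALSE)
}

#' Default mock-community positive controls
#'
#' Two ten-species bony-fish mock communities (one equimolar, one with
#' linearly increasing input proportions) plus three single-species tissue
#' controls, mirroring a five-replicate positive-control block.
#'
#' @return named list: control id to named numeric vector of input DNA
#'   proportions (summing to 1).
#' @export
default_mock_compositions <- function() {
  members <- c("Sebastes", "Oncorhynchus", "Hexagrammos", "Ophiodon",
               "Embiotoca", "Engraulis", "Oxyjulis", "Citharichthys",
               "Scorpaenichthys", "Paralabrax")
  mock1 <- stats::setNames(rep(1 / 10, 10), members)
  mock2 <- stats::setNames((1:10) / sum(1:10), members)
  sword <- c(Xiphias = 1)
  list(mock1 = mock1, mock2 = mock2,
       sword1 = sword, sword2 = sword, sword3 = sword)
}

xiphias_lineage <- function() {
  c(Xiphias = "class:Actinopterygii;order:Istiophoriformes;family:Xiphiidae;genus:Xiphias")
}

#' Transect study design
#'
#' @param sites data.frame as [default_sites()].
#' @param taxa data.frame as [default_taxa()]: `taxon_id`, `lineage`, one
#'   nonnegative affinity column per habitat.
#' @param n_replicates_per_site filter replicates per site (default 3).
#' @param microhabitat_sd standard deviation of a per-site lognormal
#'   multiplier on taxon affinities, creating site-to-site (microhabitat)
#'   differences within a habitat type (default 0.5; 0 makes same-habitat
#'   sites identical in expectation). Never changes which taxa are present.
#' @return an object of class `transect_design`.
#' @export
transect_design <- function(sites = default_sites(), taxa = default_taxa(),
                            n_replicates_per_site = 3,
                            microhabitat_sd = 0.5) {
  if (nrow(taxa) == 0) stop("empty taxon list")
  if (n_replicates_per_site < 2) stop("need at least 2 replicates per site")
  if (any(sites$distance_m <= 0)) stop("distances must be strictly positive")
  if (anyDuplicated(sites$distance_m)) stop("site distances must be unique")
  habitats <- setdiff(names(taxa), c("taxon_id", "lineage"))
  if (!all(sites$habitat %in% habitats))
    stop("no affinity column for habitat(s): ",
         paste(setdiff(sites$habitat, habitats), collapse = ", "))
  aff <- as.matrix(taxa[, habitats, drop = FALSE])
  if (any(aff < 0)) stop("affinities must be nonnegative")
  if (any(rowSums(aff) == 0))
    stop("taxa with no positive affinity: ",
         paste(taxa$taxon_id[rowSums(aff) == 0], collapse = ", "))
  if (microhabitat_sd < 0) stop("microhabitat_sd must be nonnegative")
  structure(list(sites = sites, taxa = taxa, habitats = habitats,
                 n_replicates_per_site = n_replicates_per_site,
                 microhabitat_sd = microhabitat_sd),
            class = "transect_design")
}

#' Noise model for a simulated sequencing run
#'
#' @param contaminants data.frame as [default_contaminants()]: per-taxon
#'   expected relative abundance (`rate`), injection `scope` (`"all"`,
#'   `"field_negative"` or `"negative_only"`) and `lineage`.
#' @param spurious_annotation_rate probability a read is relabelled to a
#'   random off-community taxon (default 0.001).
#' @param replicate_dispersion Dirichlet-multinomial overdispersion of field
#'   replicate compositions; 0 gives a plain multinomial (default 0.005,
#'   which leaves replicate-level variance a small fraction of the total, as
#'   observed for filter replicates of a shared water sample).
#' @param tag_jump_rate probability a read is reassigned to a uniformly
#'   chosen other replicate in the run (default 5e-4).
#' @param seed integer seed driving the whole simulation.
#' @param spurious_pool data.frame as [default_spurious_pool()].
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(contaminants = default_contaminants(),
                        spurious_annotation_rate = 0.001,
                        replicate_dispersion = 0.005,
                        tag_jump_rate = 5e-4,
                        seed = 1,
                        spurious_pool = default_spurious_pool()) {
  rates <- c(spurious_annotation_rate, tag_jump_rate, contaminants$rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (replicate_dispersion < 0) stop("dispersion must be nonnegative")
  structure(list(contaminants = contaminants,
                 spurious_annotation_rate = spurious_annotation_rate,
                 replicate_dispersion = replicate_dispersion,
                 tag_jump_rate = tag_jump_rate, seed = seed,
                 spurious_pool = spurious_pool),
            class = "noise_model")
}

#' Simulate a metabarcoding study as a taxon-by-replicate count table
#'
#' Field replicates draw community reads from a (Dirichlet-)multinomial
#' around habitat-weighted expected abundances; mock-community and tissue
#' positive controls draw from their input proportions; negative controls
#' carry contamination only. Contaminant reads displace community reads, so
#' every field and positive replicate sums exactly to
#' `total_reads_per_replicate` before tag jumping; spurious-annotation
#' relabelling and tag jumping conserve the grand total.
#'
#' @param design a [transect_design()].
#' @param noise a [noise_model()].
#' @param total_reads_per_replicate sequencing depth per replicate
#'   (default 20000).
#' @param mock_compositions named list of positive-control compositions
#'   (default [default_mock_compositions()]).
#' @param n_negative_controls number of blank replicates (default 13:
#'   1 collection, 3 filtration and 9 extraction blanks).
#' @param extra_lineages named character vector of lineages for mock members
#'   outside the transect community.
#' @return list with `table` (a [taxon_table]) and `truth` (class
#'   `truth_set`: `presence` and `expected_abundance` site-by-taxon matrices,
#'   `planted_contaminants`, `spurious_pool`, `mock_compositions`).
#' @export
simulate_study <- function(design, noise = noise_model(),
                           total_reads_per_replicate = 20000,
                           mock_compositions = default_mock_compositions(),
                           n_negative_controls = 13,
                           extra_lineages = xiphias_lineage()) {
  stopifnot(inherits(design, "transect_design"), inherits(noise, "noise_model"))
  if (total_reads_per_replicate <= 0) stop("total_reads_per_replicate must be > 0")
  set.seed(noise$seed)
  total <- total_reads_per_replicate

  field_taxa <- design$taxa$taxon_id
  lineage <- c(stats::setNames(design$taxa$lineage, field_taxa),
               stats::setNames(noise$contaminants$lineage, noise$contaminants$taxon_id),
               stats::setNames(noise$spurious_pool$lineage, noise$spurious_pool$taxon_id),
               extra_lineages)
  mock_members <- unique(unlist(lapply(mock_compositions, names)))
  no_lineage <- setdiff(mock_members, names(lineage))
  if (length(no_lineage))
    stop("no lineage for mock members: ", paste(no_lineage, collapse = ", "))
  all_taxa <- unique(c(field_taxa, noise$contaminants$taxon_id,
                       noise$spurious_pool$taxon_id, mock_members))

  meta_field <- do.call(rbind, lapply(seq_len(nrow(design$sites)), function(i) {
    s <- design$sites[i, ]
    data.frame(replicate_id = paste0(s$site_id, "_", seq_len(design$n_replicates_per_site)),
               site_id = s$site_id, habitat = s$habitat,
               distance_m = s$distance_m, depth_m = s$depth_m, role = "field",
               stringsAsFactors = FALSE)
  }))
  meta_pos <- if (length(mock_compositions) > 0) {
    data.frame(replicate_id = names(mock_compositions),
               site_id = names(mock_compositions),
               habitat = "control", distance_m = NA_real_,
               depth_m = NA_real_, role = "positive",
               stringsAsFactors = FALSE)
  } else NULL
  meta_neg <- if (n_negative_controls > 0) {
    data.frame(replicate_id = sprintf("NEG_%02d", seq_len(n_negative_controls)),
               site_id = sprintf("NEG_%02d", seq_len(n_negative_controls)),
               habitat = "control", distance_m = NA_real_, depth_m = NA_real_,
               role = "negative", stringsAsFactors = FALSE)
  } else NULL
  meta <- rbind(meta_field, meta_pos, meta_neg)

  counts <- matrix(0L, nrow = length(all_taxa), ncol = nrow(meta),
                   dimnames = list(all_taxa, meta$replicate_id))

  aff <- as.matrix(design$taxa[, design$habitats, drop = FALSE])
  rownames(aff) <- field_taxa
  msd <- if (is.null(design$microhabitat_sd)) 0 else design$microhabitat_sd
  site_p <- sapply(design$sites$site_id, function(sid) {
    hab <- design$sites$habitat[design$sites$site_id == sid]
    w <- aff[, hab]
    if (sum(w) == 0) stop("zero-weight habitat at site ", sid)
    if (msd > 0)  # site-level microhabitat variation within the habitat type
      w <- w * exp(stats::rnorm(length(w), 0, msd))
    w / sum(w)
  })  # taxa x sites
  if (!is.matrix(site_p))
    site_p <- matrix(site_p, nrow = length(field_taxa),
                     dimnames = list(field_taxa, design$sites$site_id))

  draw_contaminants <- function(role) {
    cc <- noise$contaminants
    applicable <- cc$scope == "all" |
      (cc$scope == "field_negative" & role %in% c("field", "negative")) |
      (cc$scope == "negative_only" & role == "negative")
    out <- stats::setNames(integer(max(nrow(cc), 0)), cc$taxon_id)
    if (any(applicable))
      out[applicable] <- stats::rpois(sum(applicable), cc$rate[applicable] * total)
    out
  }

  for (j in seq_len(nrow(meta))) {
    role <- meta$role[j]
    contam <- draw_contaminants(role)
    n_contam <- min(sum(contam), total)
    if (role == "field") {
      p <- site_p[, meta$site_id[j]]
      if (noise$replicate_dispersion > 0) {
        w <- numeric(length(p))
        pos <- p > 0
        w[pos] <- stats::rgamma(sum(pos), shape = p[pos] / noise$replicate_dispersion)
        if (sum(w) == 0) w[pos] <- p[pos]
        p <- w / sum(w)
      }
      community <- stats::rmultinom(1, total - n_contam, p)[, 1]
      counts[field_taxa, j] <- counts[field_taxa, j] + as.integer(community)
    } else if (role == "positive") {
      comp <- mock_compositions[[meta$replicate_id[j]]]
      community <- stats::rmultinom(1, total - n_contam, comp)[, 1]
      counts[names(comp), j] <- counts[names(comp), j] + as.integer(community)
    }
    counts[names(contam), j] <- counts[names(contam), j] + as.integer(contam)
  }

  # spurious annotation: relabel reads to a uniformly chosen pool taxon
  pool <- noise$spurious_pool$taxon_id
  if (noise$spurious_annotation_rate > 0 && length(pool)) {
    for (j in seq_len(ncol(counts))) {
      tot_j <- sum(counts[, j])
      if (tot_j == 0) next
      nsp <- stats::rbinom(1, tot_j, noise$spurious_annotation_rate)
      if (nsp == 0) next
      victims <- stats::rmultinom(1, nsp, counts[, j])[, 1]
      victims <- pmin(victims, counts[, j])
      moved <- sum(victims)
      if (moved == 0) next
      dest <- stats::rmultinom(1, moved, rep(1, length(pool)))[, 1]
      counts[, j] <- counts[, j] - victims
      counts[pool, j] <- counts[pool, j] + dest
    }
  }

  # tag jumping: move reads uniformly to any other replicate in the run
  if (noise$tag_jump_rate > 0 && ncol(counts) > 1) {
    delta <- matrix(0L, nrow = nrow(counts), ncol = ncol(counts))
    for (j in seq_len(ncol(counts))) {
      tot_j <- sum(counts[, j])
      if (tot_j == 0) next
      nj <- stats::rbinom(1, tot_j, noise$tag_jump_rate)
      if (nj == 0) next
      victims <- stats::rmultinom(1, nj, counts[, j])[, 1]
      victims <- pmin(victims, counts[, j])
      delta[, j] <- delta[, j] - victims
      others <- setdiff(seq_len(ncol(counts)), j)
      for (t in which(victims > 0)) {
        dest <- stats::rmultinom(1, victims[t], rep(1, length(others)))[, 1]
        delta[t, others] <- delta[t, others] + dest
      }
    }
    counts <- counts + delta
  }

  taxa_df <- data.frame(taxon_id = all_taxa,
                        rank = lineage_rank(lineage[all_taxa]),
                        lineage = unname(lineage[all_taxa]),
                        stringsAsFactors = FALSE)
  presence <- t(site_p > 0)
  expected <- t(site_p)
  truth <- structure(list(presence = presence, expected_abundance = expected,
                          planted_contaminants = noise$contaminants$taxon_id,
                          spurious_pool = pool,
                          mock_compositions = mock_compositions),
                     class = "truth_set")
  list(table = taxon_table(counts, meta, taxa_df), truth = truth)
}

#' Bin a count into the four-level visual abundance scale
#'
#' @param n nonnegative integer count(s).
#' @return character: `"single"` (1), `"few"` (2-10), `"many"` (11-100) or
#'   `"common"` (101-1000; larger counts are capped into this class).
#' @export
abundance_category <- function(n) {
  ifelse(n <= 1, "single",
         ifelse(n <= 10, "few",
                ifelse(n <= 100, "many", "common")))
}

#' Simulate a visual dive survey from the planted truth
#'
#' Each taxon present at a site is detected with its detectability; detected
#' taxa receive an abundance category by binning a Poisson draw whose mean is
#' proportional to the taxon's expected relative abundance at the site.
#'
#' @param truth the `truth_set` from [simulate_study()].
#' @param detectability named numeric in `[0, 1]` per taxon, or a single
#'   value recycled over all taxa (default 0.9).
#' @param seed integer seed.
#' @param count_scale Poisson mean per unit relative abundance (default 150,
#'   so dominant taxa land in the `"many"` class).
#' @param sites optional site ids to survey (default all; open-water sites
#'   can be excluded as divers cannot survey them).
#' @return data.frame of class `visual_survey` (`site_id`, `taxon_id`,
#'   `category`).
#' @export
simulate_visual_survey <- function(truth, detectability = 0.9, seed = 1,
                                   count_scale = 150, sites = NULL) {
  taxa <- colnames(truth$presence)
  if (length(detectability) == 1 && is.null(names(detectability)))
    detectability <- stats::setNames(rep(detectability, length(taxa)), taxa)
  if (!all(names(detectability) %in% taxa))
    stop("detectability names must be taxa of the truth set")
  set.seed(seed)
  if (is.null(sites)) sites <- rownames(truth$presence)
  rows <- list()
  for (s in sites) for (t in taxa) {
    if (!truth$presence[s, t]) next
    if (stats::runif(1) > detectability[[t]]) next
    n <- stats::rpois(1, truth$expected_abundance[s, t] * count_scale)
    n <- min(max(n, 1), 1000)
    rows[[length(rows) + 1]] <- data.frame(site_id = s, taxon_id = t,
                                           category = abundance_category(n),
                                           stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(site_id = character(0), taxon_id = character(0),
                         category = character(0), stringsAsFactors = FALSE)
  class(out) <- c("visual_survey", "data.frame")
  out
}

#' Reference sequences for simulated taxa
#'
#' Draws one random amplicon-insert sequence per taxon (no homopolymer runs
#' over 7 bases, all pairwise far apart at the OTU radius with overwhelming
#' probability at the default length).
#'
#' @param taxon_ids character vector.
#' @param length insert length in bp (default 106).
#' @param seed integer seed.
#' @return named character vector of DNA sequences.
#' @export
taxon_reference_sequences <- function(taxon_ids, length = 106, seed = 99) {
  set.seed(seed)
  draw <- function() {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      if (max_homopolymer_run(s) <= 7) return(s)
    }
  }
  out <- character(0)
  for (t in taxon_ids) {
    repeat {
      s <- draw()
      if (!s %in% out) break
    }
    out <- c(out, s)
  }
  stats::setNames(out, taxon_ids)
}

#' Emit tagged amplicon reads for a simulated count table
#'
#' Builds one read per count: leading pad + sample tag + forward primer +
#' taxon insert + reverse-complemented reverse primer + reverse-complemented
#' tag + pad, with uniform quality. This is the noiseless read-level image of
#' a table, used to exercise the read-processing cascade end to end.
#'
#' @param table a [taxon_table].
#' @param sequences named character vector: taxon to insert sequence.
#' @param tag_table data.frame (`sample_id`, `tag`) covering every replicate.
#' @param forward_primer,reverse_primer PCR primers.
#' @param pad leading spacer (default `"NNN"`).
#' @param quality_char Phred+33 quality character for every base
#'   (default `"I"`, Q40).
#' @return read table (`read_id`, `sequence`, `quality`).
#' @export
simulate_reads <- function(table, sequences, tag_table,
                           forward_primer = "ACTGGGATTAGATACCCC",
                           reverse_primer = "TAGAACAGGCTCCTCTAG",
                           pad = "NNN", quality_char = "I") {
  stopifnot(inherits(table, "taxon_table"))
  missing_tag <- setdiff(colnames(table$counts), tag_table$sample_id)
  if (length(missing_tag))
    stop("no tag for replicates: ", paste(missing_tag, collapse = ", "))
  nonzero <- which(table$counts > 0, arr.ind = TRUE)
  tag_of <- stats::setNames(tag_table$tag, tag_table$sample_id)
  seqs <- character(0)
  ids <- character(0)
  for (k in seq_len(nrow(nonzero))) {
    taxon <- rownames(table$counts)[nonzero[k, 1]]
    rep_id <- colnames(table$counts)[nonzero[k, 2]]
    if (!taxon %in% names(sequences))
      stop("no reference sequence for taxon ", taxon)
    n <- table$counts[nonzero[k, 1], nonzero[k, 2]]
    tag <- tag_of[[rep_id]]
    read <- paste0(pad, tag, forward_primer, sequences[[taxon]],
                   reverse_complement(reverse_primer),
                   reverse_complement(tag), pad)
    seqs <- c(seqs, rep(read, n))
    ids <- c(ids, sprintf("%s|%s|%d", rep_id, taxon, seq_len(n)))
  }
  data.frame(read_id = ids, sequence = seqs,
             quality = strrep(quality_char, nchar(seqs)),
             stringsAsFactors = FALSE)
}
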