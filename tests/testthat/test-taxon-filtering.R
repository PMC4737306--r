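test_that("derive_noise_threshold is the worst spurious abundance in controls", {
  tt <- tiny_table()
  mocks <- list(POS_1 = c(Sebastes = 0.5, Embiotoca = 0.5))
  # POS_1 currently holds 2 Gallus reads out of 2 -> all spurious
  expect_equal(derive_noise_threshold(tt, mocks), 1)

  # clean controls -> 0
  clean <- tt
  clean$counts["Gallus", "POS_1"] <- 0
  clean$counts["Sebastes", "POS_1"] <- 100
  expect_equal(derive_noise_threshold(clean, mocks), 0)

  # planted spurious taxon at 0.5% -> 0.005 (direct division oracle)
  planted <- clean
  planted$counts["Sebastes", "POS_1"] <- 995
  planted$counts["Gallus", "POS_1"] <- 5
  expect_equal(derive_noise_threshold(planted, mocks), 5 / 1000)

  # zero-total control errors, naming the control
  zero <- clean
  zero$counts[, "POS_1"] <- 0
  expect_error(derive_noise_threshold(zero, mocks), "POS_1")
})

test_that("apply_noise_filter zeroes strictly-below-threshold detections", {
  tt <- tiny_table()
  tot1 <- sum(tt$counts[, "S1_1"])
  thr <- tt$counts["Gallus", "S1_1"] / tot1  # Gallus sits exactly at thr
  out <- apply_noise_filter(tt, thr)
  expect_identical(out$table$counts["Gallus", "S1_1"],
                   tt$counts["Gallus", "S1_1"])  # boundary kept (strict <)
  out2 <- apply_noise_filter(tt, thr * 1.01)
  expect_identical(unname(out2$table$counts["Gallus", "S1_1"]), 0)
  expect_identical(out2$taxa_removed, "Gallus")  # only field rep with Gallus
  expect_equal(out2$reads_removed, 1)
})

test_that("apply_noise_filter matches a per-cell oracle on random tables", {
  set.seed(12)
  for (i in 1:5) {
    counts <- matrix(rpois(60, 50), nrow = 10,
                     dimnames = list(paste0("t", 1:10), paste0("S1_", 1:6)))
    meta <- data.frame(replicate_id = colnames(counts), site_id = "S1",
                       habitat = "h", distance_m = 1, depth_m = 1,
                       role = "field", stringsAsFactors = FALSE)
    tt <- taxon_table(counts, meta)
    thr <- 0.015
    out <- apply_noise_filter(tt, thr)
    oracle <- counts
    for (j in seq_len(ncol(counts)))
      oracle[counts[, j] / sum(counts[, j]) < thr, j] <- 0
    expect_equal(unname(out$table$counts), unname(oracle))
    expect_equal(out$reads_removed, sum(counts) - sum(oracle))
  }
})

test_that("replicate rule zeroes 1-of-3 detections per site, keeps 2-of-3", {
  counts <- rbind(one_of3 = c(50, 0, 0, 9, 9, 9),
                  two_of3 = c(40, 40, 0, 0, 0, 0),
                  everywhere = c(10, 10, 10, 10, 10, 10))
  colnames(counts) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  meta <- data.frame(replicate_id = colnames(counts),
                     site_id = rep(c("A", "B"), each = 3), habitat = "h",
                     distance_m = rep(c(1, 2), each = 3), depth_m = 1,
                     role = "field", stringsAsFactors = FALSE)
  tt <- taxon_table(counts, meta)
  out <- replicate_consistency_filter(tt, 2)
  # one_of3 fails at site A (1 rep) but passes at B (3 reps)
  expect_true(all(out$table$counts["one_of3", c("A_1", "A_2", "A_3")] == 0))
  expect_true(all(out$table$counts["one_of3", c("B_1", "B_2", "B_3")] == 9))
  # two_of3 retained at its site
  expect_identical(out$table$counts["two_of3", "A_1"], 40)
  expect_identical(out$taxa_removed, character(0))
  expect_equal(out$reads_removed, 50)
  # a taxon failing everywhere is recorded as removed
  out2 <- replicate_consistency_filter(taxon_table(
    matrix(c(5, 0, 0, 7, 0, 0), 1, dimnames = list("x", colnames(counts))),
    meta), 2)
  expect_identical(out2$taxa_removed, "x")
})

test_that("replicate rule equals a per-site presence-count oracle", {
  set.seed(23)
  counts <- matrix(rbinom(90, 1, 0.5) * rpois(90, 30), nrow = 10,
                   dimnames = list(paste0("t", 1:10),
                                   paste0(rep(c("A", "B", "C"), each = 3),
                                          "_", 1:3)))
  meta <- data.frame(replicate_id = colnames(counts),
                     site_id = rep(c("A", "B", "C"), each = 3), habitat = "h",
                     distance_m = rep(1:3, each = 3), depth_m = 1,
                     role = "field", stringsAsFactors = FALSE)
  out <- replicate_consistency_filter(taxon_table(counts, meta), 2)
  oracle <- counts
  for (s in c("A", "B", "C")) {
    cols <- grep(paste0("^", s, "_"), colnames(counts))
    fail <- rowSums(counts[, cols] > 0) < 2
    oracle[fail, cols] <- 0
  }
  expect_equal(unname(out$table$counts), unname(oracle))
})

test_that("negative subtraction floors at zero and can exclude a taxon", {
  tt <- tiny_table()
  out <- subtract_negative_controls(tt)
  # Homo: negative has 40 >= every field count -> excluded entirely
  expect_true(all(out$table$counts["Homo",
                                   replicates_by_role(tt, "field")] == 0))
  expect_true("Homo" %in% out$taxa_removed)
  # Sebastes unaffected (negatives carry none)
  expect_identical(out$table$counts["Sebastes", "S1_1"],
                   tt$counts["Sebastes", "S1_1"])
  # all-zero negatives leave the table unchanged
  clean <- tt
  clean$counts[, "NEG_1"] <- 0
  out2 <- subtract_negative_controls(clean)
  expect_identical(out2$table$counts, clean$counts)
  expect_equal(out2$reads_removed, 0)
})

test_that("pooled-max subtraction equals an element-wise oracle", {
  set.seed(31)
  counts <- matrix(rpois(48, 20), nrow = 6,
                   dimnames = list(paste0("t", 1:6),
                                   c(paste0("S1_", 1:3), paste0("S2_", 1:3),
                                     "NEG_1", "NEG_2")))
  meta <- data.frame(replicate_id = colnames(counts),
                     site_id = c(rep(c("S1", "S2"), each = 3), "NEG_1", "NEG_2"),
                     habitat = "h", distance_m = c(rep(c(1, 2), each = 3), NA, NA),
                     depth_m = 1,
                     role = c(rep("field", 6), "negative", "negative"),
                     stringsAsFactors = FALSE)
  tt <- taxon_table(counts, meta)
  out <- subtract_negative_controls(tt)
  negmax <- pmax(counts[, "NEG_1"], counts[, "NEG_2"])
  for (f in paste0("S", rep(1:2, each = 3), "_", 1:3))
    expect_equal(unname(out$table$counts[, f]),
                 unname(pmax(0, counts[, f] - negmax)))
  # explicit one-to-one pairing instead of the pooled default
  pairing <- setNames(rep(c("NEG_1", "NEG_2"), each = 3),
                      colnames(counts)[1:6])
  out2 <- subtract_negative_controls(tt, pairing)
  expect_equal(unname(out2$table$counts[, "S2_2"]),
               unname(pmax(0, counts[, "S2_2"] - counts[, "NEG_2"])))
})

test_that("geographic filter keeps, reassigns or removes by occurrence evidence", {
  counts <- rbind(Sebastes = c(100, 90, 95),
                  Epinephelus = c(20, 25, 15),   # genus absent, family present
                  Thunnus = c(5, 6, 4),          # genus and family absent
                  Paralabrax = c(30, 20, 25))    # pre-existing Serranidae genus
  colnames(counts) <- paste0("S1_", 1:3)
  meta <- data.frame(replicate_id = colnames(counts), site_id = "S1",
                     habitat = "h", distance_m = 1, depth_m = 1,
                     role = "field", stringsAsFactors = FALSE)
  taxa <- data.frame(
    taxon_id = rownames(counts), rank = "genus",
    lineage = c("class:Actinopterygii;family:Sebastidae;genus:Sebastes",
                "class:Actinopterygii;family:Serranidae;genus:Epinephelus",
                "class:Actinopterygii;family:Scombridae;genus:Thunnus",
                "class:Actinopterygii;family:Serranidae;genus:Paralabrax"),
    stringsAsFactors = FALSE)
  occ <- occurrence_list(genera = c("Sebastes", "Paralabrax"),
                         families = c("Sebastidae", "Serranidae"))
  out <- geographic_filter(taxon_table(counts, meta, taxa), occ)
  expect_identical(out$classification[["Sebastes"]], "true_positive_class1")
  expect_identical(out$classification[["Epinephelus"]], "reassigned_to_family")
  expect_identical(out$classification[["Thunnus"]], "spurious_exotic")
  expect_identical(out$taxa_removed, "Thunnus")
  expect_identical(out$reassigned$family, "Serranidae")
  # Epinephelus reads now live in a family-level row; totals conserved less exotics
  expect_equal(unname(out$table$counts["Serranidae", ]), c(20, 25, 15))
  expect_equal(sum(out$table$counts), sum(counts) - sum(counts["Thunnus", ]))
  expect_equal(out$reads_removed, sum(counts["Thunnus", ]))
  # genus-present rows pass through untouched
  expect_identical(out$table$counts["Sebastes", ], counts["Sebastes", ])
})

test_that("suborder- and family-level rows are judged at their own rank", {
  counts <- rbind(Zoarcoidei = c(10, 12, 9), Embiotocidae = c(5, 5, 5))
  colnames(counts) <- paste0("S1_", 1:3)
  meta <- data.frame(replicate_id = colnames(counts), site_id = "S1",
                     habitat = "h", distance_m = 1, depth_m = 1,
                     role = "field", stringsAsFactors = FALSE)
  taxa <- data.frame(
    taxon_id = rownames(counts), rank = c("suborder", "family"),
    lineage = c("class:Actinopterygii;order:Perciformes;suborder:Zoarcoidei",
                "class:Actinopterygii;family:Embiotocidae"),
    stringsAsFactors = FALSE)
  occ <- occurrence_list(genera = "Sebastes", families = "Embiotocidae",
                         suborders = "Zoarcoidei")
  out <- geographic_filter(taxon_table(counts, meta, taxa), occ)
  expect_identical(unname(out$classification[rownames(counts)]),
                   rep("true_positive_class2", 2))
  expect_identical(out$taxa_removed, character(0))
})

test_that("the full pipeline reconciles its ledger and classifies every taxon", {
  sim <- simulate_study(transect_design(), noise_model(seed = 2), 10000)
  cfg <- filter_config(default_occurrence_list(),
                       mock_compositions = default_mock_compositions())
  res <- run_filter_pipeline(sim$table, cfg)
  rep <- res$report
  # reads in = reads out + sum of reads removed per step
  expect_equal(rep$input_reads,
               rep$output_reads + sum(rep$steps$reads_removed))
  # classifications exhaustive over removed + surviving taxa
  cls <- rep$classification
  expect_true(all(rownames(res$table$counts) %in% names(cls)))
  expect_true(all(unlist(rep$steps$taxa) %in% names(cls)))
  # no taxon classified twice with conflicting labels
  expect_identical(anyDuplicated(names(cls)), 0L)
  # every survivor is a true positive of some class
  expect_true(all(grepl("^true_positive",
                        cls[rownames(res$table$counts)])))
})

test_that("an empty table passes through with an all-zero ledger", {
  counts <- matrix(0, nrow = 0, ncol = 3,
                   dimnames = list(NULL, paste0("S1_", 1:3)))
  meta <- data.frame(replicate_id = paste0("S1_", 1:3), site_id = "S1",
                     habitat = "h", distance_m = 1, depth_m = 1,
                     role = "field", stringsAsFactors = FALSE)
  tt <- taxon_table(counts, meta,
                    taxa = data.frame(taxon_id = character(0),
                                      rank = character(0),
                                      lineage = character(0)))
  cfg <- filter_config(occurrence_list(genera = "Sebastes", families = "S"),
                       noise_threshold = 0.0002)
  res <- run_filter_pipeline(tt, cfg)
  expect_identical(nrow(res$table$counts), 0L)
  expect_true(all(res$report$steps$reads_removed == 0))
  expect_true(all(res$report$steps$taxa_removed == 0))
})

test_that("running subtraction before the replicate rule can change the outcome", {
  # taxon present 2-of-3; the negative wipes one of those two replicates
  counts <- rbind(x = c(20, 3, 0, 5), anchor = c(50, 50, 50, 0))
  colnames(counts) <- c("S1_1", "S1_2", "S1_3", "NEG_1")
  meta <- data.frame(replicate_id = colnames(counts),
                     site_id = c("S1", "S1", "S1", "NEG_1"), habitat = "h",
                     distance_m = c(1, 1, 1, NA), depth_m = 1,
                     role = c("field", "field", "field", "negative"),
                     stringsAsFactors = FALSE)
  tt <- taxon_table(counts, meta)
  # pipeline order (replicate rule first): x survives with reduced counts
  a <- subtract_negative_controls(replicate_consistency_filter(tt, 2)$table)
  expect_gt(sum(a$table$counts["x", 1:3]), 0)
  # swapped order: subtraction makes x 1-of-3, the replicate rule removes it
  b <- replicate_consistency_filter(subtract_negative_controls(tt)$table, 2)
  expect_equal(sum(b$table$counts["x", 1:3]), 0)
  expect_false(identical(a$table$counts, b$table$counts))
})

test_that("taxon tables round-trip through their TSV representation", {
  tt <- tiny_table()
  cp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_taxon_table(tt, cp, mp)
  back <- read_taxon_table(cp, mp)
  expect_equal(back$counts, tt$counts)
  expect_identical(back$meta$role, tt$meta$role)
  expect_identical(back$taxa$lineage, tt$taxa$lineage)
  # tag tables too
  ts <- design_tags(5, seed = 1)
  tp <- tempfile(fileext = ".tsv")
  df <- write_tag_table(ts, paste0("S", 1:5), tp)
  expect_identical(read_tag_table(tp), df)
})
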