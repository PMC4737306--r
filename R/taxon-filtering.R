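#' Occurrence list of taxa credibly present in the survey region
#'
#' The geographic filter's external register: genera, families and suborders
#' accepted as locally present (from regional species databases and
#' historical monitoring, in a real study).
#'
#' @param genera,families,suborders character vectors of names.
#' @return an object of class `occurrence_list`.
#' @export
occurrence_list <- function(genera, families, suborders = character(0)) {
  if (length(genera) + length(families) + length(suborders) == 0)
    stop("an occurrence list cannot be empty")
  structure(list(genera_present = unique(genera),
                 families_present = unique(families),
                 suborders_present = unique(suborders)),
            class = "occurrence_list")
}

#' Occurrence list implied by a simulated community
#'
#' @param taxa data.frame as [default_taxa()].
#' @return an [occurrence_list()] of the community's genera, families and
#'   suborders.
#' @export
default_occurrence_list <- function(taxa = default_taxa()) {
  occurrence_list(genera = taxa$taxon_id,
                  families = stats::na.omit(lineage_at_rank(taxa$lineage, "family")),
                  suborders = stats::na.omit(lineage_at_rank(taxa$lineage, "suborder")))
}

#' Configuration of the taxon-filtering pipeline
#'
#' @param occurrence_list an [occurrence_list()].
#' @param noise_threshold relative-abundance cutoff in `[0, 1)`; leave `NULL`
#'   to derive it from the positive controls (requires `mock_compositions`).
#' @param min_replicates_present minimum filter replicates a taxon must
#'   occupy at a site (default 2 of 3).
#' @param mock_compositions named list of positive-control compositions, used
#'   by the threshold derivation.
#' @param control_pairing optional named character vector mapping each field
#'   replicate to its negative-control replicate; the default `NULL` pools
#'   negatives by their element-wise maximum (most conservative).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(occurrence_list, noise_threshold = NULL,
                          min_replicates_present = 2,
                          mock_compositions = NULL, control_pairing = NULL) {
  if (!is.null(noise_threshold) &&
      (noise_threshold < 0 || noise_threshold >= 1))
    stop("noise_threshold must lie in [0, 1)")
  if (min_replicates_present < 1) stop("min_replicates_present must be >= 1")
  structure(list(occurrence_list = occurrence_list,
                 noise_threshold = noise_threshold,
                 min_replicates_present = min_replicates_present,
                 mock_compositions = mock_compositions,
                 control_pairing = control_pairing),
            class = "filter_config")
}

#' Derive the low-frequency noise threshold from positive controls
#'
#' For every positive-control replicate, computes the relative abundance of
#' each taxon outside its intended composition; the threshold is the largest
#' such spurious abundance over all controls (0 when the controls are clean).
#'
#' @param table a [taxon_table] containing positive-control replicates.
#' @param mock_compositions named list: control replicate id to named vector
#'   of intended member proportions.
#' @return numeric threshold in `[0, 1)`.
#' @export
derive_noise_threshold <- function(table, mock_compositions) {
  stopifnot(inherits(table, "taxon_table"))
  pos <- replicates_by_role(table, "positive")
  if (length(pos) == 0) stop("no positive-control replicates in table")
  worst <- 0
  for (p in pos) {
    tot <- sum(table$counts[, p])
    if (tot == 0) stop("positive control has zero total reads: ", p)
    comp <- mock_compositions[[p]]
    if (is.null(comp)) stop("no mock composition for positive control: ", p)
    spurious <- setdiff(rownames(table$counts), names(comp))
    if (length(spurious))
      worst <- max(worst, max(table$counts[spurious, p] / tot))
  }
  worst
}

field_reads <- function(table) sum(table$counts[, replicates_by_role(table, "field"), drop = FALSE])

field_taxa_present <- function(table) {
  f <- replicates_by_role(table, "field")
  rownames(table$counts)[rowSums(table$counts[, f, drop = FALSE]) > 0]
}

#' Zero out low-frequency taxon detections
#'
#' Per field replicate, any taxon whose count is a fraction of the replicate
#' total strictly below the threshold is set to zero. Denominators are the
#' replicate totals at the time the step runs.
#'
#' @param table a [taxon_table].
#' @param threshold relative-abundance cutoff in `[0, 1)`.
#' @return list with `table`, `reads_removed`, `taxa_removed` (taxa left with
#'   no field reads anywhere).
#' @export
apply_noise_filter <- function(table, threshold) {
  stopifnot(inherits(table, "taxon_table"), threshold >= 0, threshold < 1)
  before <- field_taxa_present(table)
  reads_removed <- 0
  for (f in replicates_by_role(table, "field")) {
    tot <- sum(table$counts[, f])
    if (tot == 0) next
    low <- table$counts[, f] > 0 & table$counts[, f] / tot < threshold
    reads_removed <- reads_removed + sum(table$counts[low, f])
    table$counts[low, f] <- 0
  }
  list(table = table, reads_removed = reads_removed,
       taxa_removed = setdiff(before, field_taxa_present(table)))
}

#' Enforce presence in multiple filter replicates per site
#'
#' At each site, a taxon detected in fewer than `min_replicates_present` of
#' that site's field replicates is zeroed across the whole site; a taxon
#' counts as removed only when this leaves it with no field reads at any
#' site.
#'
#' @param table a [taxon_table].
#' @param min_replicates_present default 2 (the 2-of-3 rule).
#' @return list with `table`, `reads_removed`, `taxa_removed`.
#' @export
replicate_consistency_filter <- function(table, min_replicates_present = 2) {
  stopifnot(inherits(table, "taxon_table"))
  before <- field_taxa_present(table)
  reads_removed <- 0
  meta_f <- table$meta[table$meta$role == "field", , drop = FALSE]
  for (site in unique(meta_f$site_id)) {
    reps <- meta_f$replicate_id[meta_f$site_id == site]
    if (length(reps) < min_replicates_present)
      stop("site ", site, " has fewer field replicates than min_replicates_present")
    sub <- table$counts[, reps, drop = FALSE]
    n_present <- rowSums(sub > 0)
    fail <- n_present > 0 & n_present < min_replicates_present
    reads_removed <- reads_removed + sum(sub[fail, , drop = FALSE])
    table$counts[fail, reps] <- 0
  }
  list(table = table, reads_removed = reads_removed,
       taxa_removed = setdiff(before, field_taxa_present(table)))
}

#' Subtract negative-control read counts from field samples
#'
#' Each field replicate's count for a taxon is reduced by the count of that
#' taxon in its paired negative control, floored at zero. With no explicit
#' pairing the negatives are pooled by their element-wise maximum, the most
#' conservative choice.
#'
#' @param table a [taxon_table] containing negative-control replicates.
#' @param pairing optional named character vector: field replicate id to
#'   negative-control replicate id.
#' @return list with `table`, `reads_removed`, `taxa_removed`.
#' @export
subtract_negative_controls <- function(table, pairing = NULL) {
  stopifnot(inherits(table, "taxon_table"))
  before <- field_taxa_present(table)
  negs <- replicates_by_role(table, "negative")
  fields <- replicates_by_role(table, "field")
  if (length(negs) == 0)
    return(list(table = table, reads_removed = 0, taxa_removed = character(0)))
  reads_removed <- 0
  for (f in fields) {
    neg_counts <- if (is.null(pairing)) {
      apply(table$counts[, negs, drop = FALSE], 1, max)
    } else {
      if (is.na(pairing[f]) || is.null(pairing[f]))
        stop("no negative-control pairing for field replicate ", f)
      table$counts[, pairing[[f]]]
    }
    newc <- pmax(0, table$counts[, f] - neg_counts)
    reads_removed <- reads_removed + sum(table$counts[, f] - newc)
    table$counts[, f] <- newc
  }
  list(table = table, reads_removed = reads_removed,
       taxa_removed = setdiff(before, field_taxa_present(table)))
}

truncate_lineage_at <- function(lineage, rank) {
  vapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    i <- grep(paste0("^", rank, ":"), p)
    if (!length(i)) NA_character_ else paste(p[seq_len(i[[1]])], collapse = ";")
  }, character(1))
}

#' Geographic plausibility filter with family-level rescue
#'
#' Taxa whose genus is on the occurrence list are kept; genera absent from
#' the list but whose family is present are reassigned to a family-level row
#' (merging with an existing row for that family, read counts conserved);
#' family- and suborder-level rows are kept when their name is listed.
#' Everything else is removed as exotic to the survey area.
#'
#' @param table a [taxon_table] whose taxa have ranks genus, family or
#'   suborder and `;`-delimited lineages.
#' @param occurrence an [occurrence_list()].
#' @return list with `table`, `reads_removed`, `taxa_removed` (exotic taxa),
#'   `reassigned` (data.frame `taxon_id`, `family`) and `classification`
#'   (named character over the input present taxa plus any family rows the
#'   reassignment created).
#' @export
geographic_filter <- function(table, occurrence) {
  stopifnot(inherits(table, "taxon_table"), inherits(occurrence, "occurrence_list"))
  fields <- replicates_by_role(table, "field")
  present <- field_taxa_present(table)
  classification <- character(0)
  reassigned <- data.frame(taxon_id = character(0), family = character(0),
                           stringsAsFactors = FALSE)
  exotic <- character(0)
  reads_removed <- 0
  merge_into <- character(0)  # taxon -> family row it merges into
  for (t in present) {
    i <- match(t, table$taxa$taxon_id)
    rank <- table$taxa$rank[i]
    lin <- table$taxa$lineage[i]
    if (is.na(rank) || !rank %in% c("genus", "family", "suborder"))
      stop("cannot resolve taxon for geographic filtering: ", t)
    if (rank == "genus") {
      fam <- lineage_at_rank(lin, "family")
      if (t %in% occurrence$genera_present) {
        classification[t] <- "true_positive_class1"
      } else if (!is.na(fam) && fam %in% occurrence$families_present) {
        classification[t] <- "reassigned_to_family"
        merge_into[t] <- fam
        reassigned <- rbind(reassigned,
                            data.frame(taxon_id = t, family = fam,
                                       stringsAsFactors = FALSE))
      } else {
        classification[t] <- "spurious_exotic"
        exotic <- c(exotic, t)
      }
    } else if (rank == "family") {
      if (t %in% occurrence$families_present) {
        classification[t] <- "true_positive_class2"
      } else {
        classification[t] <- "spurious_exotic"
        exotic <- c(exotic, t)
      }
    } else {  # suborder
      if (t %in% occurrence$suborders_present) {
        classification[t] <- "true_positive_class2"
      } else {
        classification[t] <- "spurious_exotic"
        exotic <- c(exotic, t)
      }
    }
  }
  # remove exotics
  reads_removed <- sum(table$counts[exotic, fields, drop = FALSE])
  table$counts[exotic, fields] <- 0
  # merge reassigned genera into family rows
  for (t in names(merge_into)) {
    fam <- merge_into[[t]]
    i <- match(t, table$taxa$taxon_id)
    fam_lineage <- truncate_lineage_at(table$taxa$lineage[i], "family")
    if (!fam %in% rownames(table$counts)) {
      table$counts <- rbind(table$counts,
                            matrix(0, 1, ncol(table$counts),
                                   dimnames = list(fam, colnames(table$counts))))
      table$taxa <- rbind(table$taxa,
                          data.frame(taxon_id = fam, rank = "family",
                                     lineage = fam_lineage,
                                     stringsAsFactors = FALSE))
      classification[fam] <- "true_positive_class3"
    }
    table$counts[fam, ] <- table$counts[fam, ] + table$counts[t, ]
    table$counts[t, ] <- 0
  }
  out <- taxon_table(table$counts, table$meta, table$taxa)
  list(table = out, reads_removed = reads_removed, taxa_removed = exotic,
       reassigned = reassigned, classification = classification)
}

#' Run the full taxon-filtering decision tree
#'
#' Applies, in order: noise-threshold derivation (from the positive controls,
#' unless a threshold is fixed in the config), the low-frequency noise
#' filter, the replicate-consistency rule, negative-control subtraction and
#' the geographic filter. Emits the filtered table (field replicates only,
#' empty taxa dropped) plus an auditable ledger of reads and taxa removed per
#' step and a final classification for every taxon.
#'
#' @param table a [taxon_table] with field, positive and negative replicates.
#' @param config a [filter_config()].
#' @return list with `table` (filtered [taxon_table]) and `report`
#'   (class `filter_report`).
#' @export
run_filter_pipeline <- function(table, config) {
  stopifnot(inherits(table, "taxon_table"), inherits(config, "filter_config"))
  input_reads <- field_reads(table)
  input_taxa <- field_taxa_present(table)

  threshold <- config$noise_threshold
  if (is.null(threshold)) {
    if (is.null(config$mock_compositions))
      stop("either fix noise_threshold or supply mock_compositions to derive it")
    threshold <- derive_noise_threshold(table, config$mock_compositions)
  }

  classification <- character(0)
  steps <- list()
  note <- function(name, res) {
    steps[[length(steps) + 1]] <<- data.frame(
      step = name, reads_removed = res$reads_removed,
      taxa_removed = length(res$taxa_removed), stringsAsFactors = FALSE)
    steps[[length(steps)]]$taxa <<- I(list(res$taxa_removed))
  }

  s1 <- apply_noise_filter(table, threshold)
  classification[s1$taxa_removed] <- "low_confidence_threshold"
  note("low_frequency_noise", s1)

  s2 <- replicate_consistency_filter(s1$table, config$min_replicates_present)
  classification[s2$taxa_removed] <- "low_confidence_replicate"
  note("replicate_consistency", s2)

  s3 <- subtract_negative_controls(s2$table, config$control_pairing)
  classification[s3$taxa_removed] <- "spurious_negative_control"
  note("negative_control_subtraction", s3)

  s4 <- geographic_filter(s3$table, config$occurrence_list)
  classification <- c(classification, s4$classification)
  note("geographic_filter", s4)

  out <- subset_taxon_table(s4$table,
                            replicates = replicates_by_role(s4$table, "field"),
                            drop_empty_taxa = TRUE)
  report <- structure(list(steps = do.call(rbind, steps),
                           classification = classification,
                           reassigned = s4$reassigned,
                           threshold = threshold,
                           input_reads = input_reads,
                           input_taxa = length(input_taxa),
                           output_reads = sum(out$counts),
                           output_taxa = nrow(out$counts)),
                      class = "filter_report")
  list(table = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Taxon-filtering report\n")
  cat(sprintf("  noise threshold: %.4g (%.4g%% of replicate reads)\n",
              x$threshold, 100 * x$threshold))
  cat(sprintf("  input:  %d reads, %d taxa (field replicates)\n",
              x$input_reads, x$input_taxa))
  for (i in seq_len(nrow(x$steps))) {
    s <- x$steps[i, ]
    taxa <- s$taxa[[1]]
    cat(sprintf("  %-28s -%7d reads, -%2d taxa%s\n", s$step, s$reads_removed,
                s$taxa_removed,
                if (length(taxa)) paste0(" (", paste(taxa, collapse = ", "), ")")
                else ""))
  }
  if (nrow(x$reassigned))
    cat("  reassigned to family:",
        paste(sprintf("%s->%s", x$reassigned$taxon_id, x$reassigned$family),
              collapse = ", "), "\n")
  cat(sprintf("  output: %d reads, %d taxa\n", x$output_reads, x$output_taxa))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  steps <- lapply(seq_len(nrow(report$steps)), function(i) {
    s <- report$steps[i, ]
    list(step = s$step, reads_removed = s$reads_removed,
         taxa_removed = s$taxa_removed, taxa = s$taxa[[1]])
  })
  jsonlite::write_json(
    list(threshold = report$threshold, input_reads = report$input_reads,
         input_taxa = report$input_taxa, output_reads = report$output_reads,
         output_taxa = report$output_taxa, steps = steps,
         classification = as.list(report$classification)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
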