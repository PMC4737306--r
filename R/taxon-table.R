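#' Taxon-by-replicate count table
#'
#' The central object of the pipeline: a matrix of read counts (taxa in rows,
#' filter replicates in columns) together with per-replicate metadata and
#' per-taxon taxonomy. Replicates carry a `role` so that field samples,
#' mock-community/tissue positive controls and blank negative controls travel
#' through the same object and can be told apart by the filtering steps.
#'
#' @param counts numeric matrix of nonnegative counts; rownames are taxon ids,
#'   colnames are replicate ids.
#' @param meta data.frame with one row per replicate and columns
#'   `replicate_id`, `site_id`, `habitat`, `distance_m`, `depth_m`,
#'   `role` (one of `"field"`, `"positive"`, `"negative"`).
#' @param taxa optional data.frame with columns `taxon_id`, `rank`, `lineage`
#'   (a `;`-delimited `rank:name` path). If omitted, a minimal frame with
#'   `NA` lineages is built from the rownames of `counts`.
#' @return An object of class `taxon_table`.
#' @export
taxon_table <- function(counts, meta, taxa = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("`counts` must have taxon rownames and replicate colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (any(counts < 0)) stop("negative counts are not allowed")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("replicate_id", "site_id", "habitat", "distance_m", "depth_m", "role")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(colnames(counts) %in% meta$replicate_id))
    stop("every count column needs a metadata row; missing: ",
         paste(setdiff(colnames(counts), meta$replicate_id), collapse = ", "))
  meta <- meta[match(colnames(counts), meta$replicate_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad_role <- setdiff(unique(meta$role), c("field", "positive", "negative"))
  if (length(bad_role)) stop("unknown replicate role: ", paste(bad_role, collapse = ", "))
  if (is.null(taxa)) {
    taxa <- data.frame(taxon_id = rownames(counts), rank = NA_character_,
                       lineage = NA_character_, stringsAsFactors = FALSE)
  }
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  if (!all(rownames(counts) %in% taxa$taxon_id))
    stop("every count row needs a taxa entry; missing: ",
         paste(setdiff(rownames(counts), taxa$taxon_id), collapse = ", "))
  taxa <- taxa[match(rownames(counts), taxa$taxon_id), , drop = FALSE]
  rownames(taxa) <- NULL
  structure(list(counts = counts, meta = meta, taxa = taxa), class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  roles <- table(factor(x$meta$role, levels = c("field", "positive", "negative")))
  cat("taxon_table:", nrow(x$counts), "taxa x", ncol(x$counts), "replicates",
      sprintf("(%d field, %d positive, %d negative)\n",
              roles[["field"]], roles[["positive"]], roles[["negative"]]))
  cat("  total reads:", sum(x$counts), "\n")
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$counts)

#' Replicate ids of a given role
#'
#' @param x a [taxon_table].
#' @param role `"field"`, `"positive"` or `"negative"`.
#' @return character vector of replicate ids.
#' @export
replicates_by_role <- function(x, role) {
  stopifnot(inherits(x, "taxon_table"))
  x$meta$replicate_id[x$meta$role == role]
}

#' Subset a taxon table by replicate ids and/or taxon ids
#'
#' @param x a [taxon_table].
#' @param replicates,taxa character vectors of ids to keep (default all).
#' @param drop_empty_taxa drop taxa whose counts are zero everywhere after
#'   subsetting.
#' @return a [taxon_table].
#' @export
subset_taxon_table <- function(x, replicates = NULL, taxa = NULL,
                               drop_empty_taxa = FALSE) {
  stopifnot(inherits(x, "taxon_table"))
  if (is.null(replicates)) replicates <- colnames(x$counts)
  if (is.null(taxa)) taxa <- rownames(x$counts)
  counts <- x$counts[taxa, replicates, drop = FALSE]
  if (drop_empty_taxa) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  taxon_table(counts, x$meta[x$meta$replicate_id %in% replicates, , drop = FALSE],
              x$taxa[x$taxa$taxon_id %in% rownames(counts), , drop = FALSE])
}

lineage_last <- function(lineage) {
  vapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    last <- p[length(p)]
    sub("^[^:]*:", "", last)
  }, character(1))
}

lineage_rank <- function(lineage) {
  vapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    last <- p[length(p)]
    sub(":.*$", "", last)
  }, character(1))
}

#' Look up a named rank inside a lineage path
#'
#' @param lineage character vector of `;`-delimited `rank:name` paths.
#' @param rank rank to extract, e.g. `"family"`.
#' @return character vector of names (`NA` where the rank is absent).
#' @export
lineage_at_rank <- function(lineage, rank) {
  vapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    hit <- grep(paste0("^", rank, ":"), p, value = TRUE)
    if (length(hit)) sub("^[^:]*:", "", hit[[1]]) else NA_character_
  }, character(1))
}

#' Write a taxon table as TSV files
#'
#' The count file has columns `taxon_id`, `lineage`, then one column per
#' replicate; the metadata file mirrors the `meta` slot.
#'
#' @param x a [taxon_table].
#' @param counts_path,meta_path output file paths.
#' @return `x`, invisibly.
#' @export
write_taxon_table <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "taxon_table"))
  df <- data.frame(taxon_id = rownames(x$counts),
                   lineage = x$taxa$lineage[match(rownames(x$counts), x$taxa$taxon_id)],
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a taxon table from TSV files written by [write_taxon_table()]
#'
#' @param counts_path,meta_path input file paths.
#' @return a [taxon_table].
#' @export
read_taxon_table <- function(counts_path, meta_path) {
  df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("taxon_id", "lineage")), drop = FALSE])
  rownames(counts) <- df$taxon_id
  taxa <- data.frame(taxon_id = df$taxon_id,
                     rank = ifelse(is.na(df$lineage), NA_character_, lineage_rank(df$lineage)),
                     lineage = df$lineage, stringsAsFactors = FALSE)
  taxon_table(counts, meta, taxa)
}
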