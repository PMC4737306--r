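#' Numeric encoding of visual-survey abundance categories
#'
#' Categories map to the medians of their inclusive integer count ranges:
#' single (1) -> 1, few (2-10) -> 6, many (11-100) -> 55.5,
#' common (101-1000) -> 550.5.
#'
#' @return named numeric vector.
#' @export
visual_category_encoding <- function() {
  c(single = 1, few = 6, many = 55.5, common = 550.5)
}

#' Encode a visual survey as a site-by-taxon count matrix
#'
#' @param survey data.frame (`site_id`, `taxon_id`, `category`), e.g. from
#'   [simulate_visual_survey()]; at most one record per (site, taxon).
#' @param sites,taxa optional row/column universes (defaults: those seen in
#'   the survey); absent pairs get 0.
#' @return numeric matrix, sites in rows and taxa in columns.
#' @export
encode_visual_counts <- function(survey, sites = NULL, taxa = NULL) {
  enc <- visual_category_encoding()
  bad <- setdiff(unique(survey$category), names(enc))
  if (length(bad)) stop("unknown abundance category: ", paste(bad, collapse = ", "))
  if (anyDuplicated(survey[c("site_id", "taxon_id")]))
    stop("more than one record per (site, taxon)")
  if (is.null(sites)) sites <- unique(survey$site_id)
  if (is.null(taxa)) taxa <- unique(survey$taxon_id)
  m <- matrix(0, length(sites), length(taxa), dimnames = list(sites, taxa))
  if (nrow(survey))
    m[cbind(survey$site_id, survey$taxon_id)] <- enc[survey$category]
  m
}

#' Compare eDNA and visual-survey taxon detections
#'
#' Matching is rank-aware through the taxonomy: a visual record (often at
#' family level) is matched by any eDNA taxon that descends from it, and vice
#' versa. The false-negative rate is the fraction of visually observed taxa
#' that eDNA missed.
#'
#' @param edna_taxa character vector of taxa detected by eDNA.
#' @param visual_taxa character vector of taxa recorded visually.
#' @param tree a [build_taxonomy()] tree resolving both sets.
#' @return list with `shared` (visual taxa matched by eDNA), `edna_only`,
#'   `visual_only` and `false_negative_rate`
#'   (`|visual_only| / |visual_taxa|`).
#' @export
detection_comparison <- function(edna_taxa, visual_taxa, tree) {
  edna_taxa <- unique(edna_taxa)
  visual_taxa <- unique(visual_taxa)
  node <- function(name) taxonomy_node(tree, name)
  related <- function(a, b) {
    na <- node(a); nb <- node(b)
    descends_from(tree, na, nb) || descends_from(tree, nb, na)
  }
  visual_matched <- vapply(visual_taxa, function(v)
    any(vapply(edna_taxa, related, logical(1), b = v)), logical(1))
  edna_matched <- vapply(edna_taxa, function(e)
    any(vapply(visual_taxa, related, logical(1), b = e)), logical(1))
  list(shared = visual_taxa[visual_matched],
       edna_only = edna_taxa[!edna_matched],
       visual_only = visual_taxa[!visual_matched],
       false_negative_rate = if (length(visual_taxa))
         sum(!visual_matched) / length(visual_taxa) else NA_real_)
}

ks_asymptotic_p <- function(d, n_eff) {
  if (d <= 0) return(1)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov comparison of two spatial count distributions
#'
#' Each count series is turned into a probability mass over
#' distance-from-shore by weighting site positions with counts; D is the
#' maximum gap between the two weighted CDFs. The asymptotic two-sample
#' p-value uses effective sample sizes equal to the count totals capped at
#' ten observations per site, since read or survey counts are not
#' independent draws.
#'
#' @param edna_counts,visual_counts named numeric vectors: site id to count.
#' @param site_positions named numeric: site id to distance from shore (m).
#' @param cap_per_site cap on effective observations per site (default 10).
#' @return list with `D`, `p_value`, `n_effective`.
#' @export
ks_spatial_test <- function(edna_counts, visual_counts, site_positions,
                            cap_per_site = 10) {
  sites <- names(site_positions)
  e <- edna_counts[sites]; e[is.na(e)] <- 0
  v <- visual_counts[sites]; v[is.na(v)] <- 0
  if (sum(e) == 0) stop("eDNA series is all zero")
  if (sum(v) == 0) stop("visual series is all zero")
  ord <- order(site_positions)
  F_e <- cumsum(e[ord]) / sum(e)
  F_v <- cumsum(v[ord]) / sum(v)
  D <- max(abs(F_e - F_v))
  cap <- length(sites) * cap_per_site
  n1 <- min(sum(e), cap)
  n2 <- min(sum(v), cap)
  n_eff <- n1 * n2 / (n1 + n2)
  list(D = unname(D), p_value = ks_asymptotic_p(D, n_eff), n_effective = n_eff)
}
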