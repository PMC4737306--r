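#' Median-of-ratios size factors for sequencing-depth normalization
#'
#' The reference profile is the per-taxon geometric mean across replicates,
#' computed over taxa observed in every replicate; each replicate's factor is
#' the median ratio of its counts to the reference. When no taxon is
#' all-positive the geometric means fall back to positive entries only, with
#' a warning.
#'
#' @param counts taxon-by-replicate count matrix.
#' @return named positive numeric vector of per-replicate size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
    f <- apply(counts[all_pos, , drop = FALSE], 2,
               function(col) stats::median(col / ref))
  } else {
    warning("no taxon observed in every replicate; ",
            "using positive-entry geometric means")
    use <- rowSums(counts > 0) > 0
    logc <- log(counts[use, , drop = FALSE])
    logc[!is.finite(logc)] <- NA
    ref <- exp(rowMeans(logc, na.rm = TRUE))
    f <- apply(counts[use, , drop = FALSE], 2, function(col) {
      r <- col / ref
      stats::median(r[col > 0])
    })
  }
  if (any(!is.finite(f) | f <= 0))
    stop("could not compute positive size factors for all replicates")
  f
}

#' Normalize counts by size factors
#'
#' @param counts taxon-by-replicate matrix.
#' @param factors per-replicate size factors (default [size_factors()]).
#' @return matrix of normalized values (`counts[, j] / factors[j]`).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  sweep(as.matrix(counts), 2, factors, "/")
}

#' Presence/absence version of a count matrix
#'
#' @param x taxon-by-replicate matrix (or [taxon_table]).
#' @return 0/1 matrix of the same shape.
#' @export
to_presence_absence <- function(x) {
  if (inherits(x, "taxon_table")) x <- x$counts
  (as.matrix(x) > 0) * 1
}

#' Bray-Curtis dissimilarity between replicates
#'
#' `d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over taxa `i`;
#' bounded in `[0, 1]`, 0 for identical profiles, 1 for disjoint supports.
#'
#' @param x taxon-by-replicate matrix (or [taxon_table]) of nonnegative
#'   values; replicates are columns.
#' @return a `dist` object over replicates.
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "taxon_table")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis needs nonnegative values")
  zero <- colSums(x) == 0
  if (any(zero))
    stop("all-zero replicate(s): ", paste(colnames(x)[zero], collapse = ", "))
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (j in seq_len(n - 1)) for (k in seq(j + 1, n)) {
    d[j, k] <- d[k, j] <-
      sum(abs(x[, j] - x[, k])) / sum(x[, j] + x[, k])
  }
  stats::as.dist(d)
}

#' PERMANOVA partition of community variance
#'
#' Permutational multivariate analysis of variance of a dissimilarity matrix
#' over sequential model terms, with free permutation of replicate labels
#' (optionally restricted within strata). A thin front end to
#' `vegan::adonis2` with the partition returned term by term.
#'
#' @param dist a `dist` object over replicates.
#' @param design data.frame of replicate covariates, rows aligned with the
#'   `dist` labels.
#' @param terms character vector of design columns, fitted sequentially.
#' @param n_permutations number of permutations (default 200).
#' @param seed integer seed for the permutations.
#' @param strata optional design column restricting permutations within
#'   groups.
#' @return an object of class `permanova_result`: data.frame `terms`
#'   (`term`, `df`, `sum_sq`, `r_squared`, `pseudo_f`, `p_value`) plus
#'   `residual_r_squared` and `n_permutations`.
#' @export
permanova <- function(dist, design, terms, n_permutations = 200, seed = NULL,
                      strata = NULL) {
  stopifnot(inherits(dist, "dist"))
  labels <- attr(dist, "Labels")
  if (!is.null(labels) && !is.null(rownames(design)) &&
      all(labels %in% rownames(design)))
    design <- design[labels, , drop = FALSE]
  for (tm in terms) {
    if (!tm %in% names(design)) stop("term not in design: ", tm)
    if (length(unique(design[[tm]])) < 2)
      stop("term has fewer than 2 groups: ", tm)
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- if (is.null(strata)) n_permutations else
    permute::how(nperm = n_permutations,
                 blocks = as.factor(design[[strata]]))
  form <- stats::as.formula(paste("dist ~", paste(terms, collapse = " + ")))
  fit <- vegan::adonis2(form, data = design, permutations = perm,
                        by = "terms")
  rows <- rownames(fit)
  term_rows <- setdiff(rows, c("Residual", "Total"))
  out <- data.frame(term = term_rows,
                    df = fit[term_rows, "Df"],
                    sum_sq = fit[term_rows, "SumOfSqs"],
                    r_squared = fit[term_rows, "R2"],
                    pseudo_f = fit[term_rows, "F"],
                    p_value = fit[term_rows, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(terms = out,
                 residual_r_squared = fit["Residual", "R2"],
                 total_sum_sq = fit["Total", "SumOfSqs"],
                 n_permutations = n_permutations),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (", x$n_permutations, "permutations )\n")
  df <- x$terms
  df$r_squared <- sprintf("%.3f", df$r_squared)
  print(df, row.names = FALSE)
  cat(sprintf("  residual R2: %.3f\n", x$residual_r_squared))
  invisible(x)
}

#' Per-taxon Kruskal-Wallis tests across groups
#'
#' Rank-based H statistic with tie correction for each taxon, with Bonferroni
#' adjustment over the taxa tested in this call. Taxa constant across all
#' groups get `H = 0`, `p = 1`.
#'
#' @param values taxon-by-replicate matrix (normalized counts).
#' @param grouping factor/character of group labels per replicate.
#' @param correction multiplicity correction passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return data.frame (`taxon_id`, `H`, `p_value`, `p_adjusted`).
#' @export
kruskal_wallis_by_taxon <- function(values, grouping,
                                    correction = "bonferroni") {
  values <- as.matrix(values)
  grouping <- as.factor(grouping)
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(table(grouping) < 2)) stop("need at least 2 observations per group")
  res <- t(apply(values, 1, function(v) {
    if (length(unique(v)) == 1) return(c(0, 1))
    k <- stats::kruskal.test(v, grouping)
    c(unname(k$statistic), k$p.value)
  }))
  data.frame(taxon_id = rownames(values), H = res[, 1], p_value = res[, 2],
             p_adjusted = stats::p.adjust(res[, 2], method = correction),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 minimization from multiple random starts via
#' `vegan::metaMDS`, returning the best-stress configuration.
#'
#' @param dist a `dist` object.
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed.
#' @return list with `coordinates` (replicate-by-`k` matrix), `stress`,
#'   `converged` and `n_restarts`.
#' @export
nmds <- function(dist, k = 2, n_restarts = 20, seed = NULL) {
  stopifnot(inherits(dist, "dist"))
  if (k >= attr(dist, "Size") - 1) stop("k must be below n - 1")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(dist, k = k, trymax = n_restarts, trace = 0)
  list(coordinates = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$converged > 0,
       n_restarts = n_restarts)
}

#' Group-average (UPGMA) hierarchical clustering
#'
#' @param dist a `dist` object.
#' @return list with `hclust` (the merge tree; heights are nondecreasing),
#'   `phylo` (an `ape` tree) and `newick` (serialized string with branch
#'   lengths).
#' @export
upgma <- function(dist) {
  stopifnot(inherits(dist, "dist"))
  hc <- stats::hclust(dist, method = "average")
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph, newick = ape::write.tree(ph))
}

#' Observed taxon richness per replicate and per site
#'
#' @param x taxon-by-replicate matrix or [taxon_table].
#' @param site_of named character mapping replicate id to site id; derived
#'   from the table metadata when `x` is a [taxon_table].
#' @return list with `per_replicate` (named integer) and `per_site`
#'   (data.frame `site_id`, `mean`, `sd`; sample SD over the site's
#'   replicates).
#' @export
richness <- function(x, site_of = NULL) {
  if (inherits(x, "taxon_table")) {
    if (is.null(site_of))
      site_of <- stats::setNames(x$meta$site_id, x$meta$replicate_id)
    x <- x$counts
  }
  x <- as.matrix(x)
  per_rep <- colSums(x > 0)
  per_site <- NULL
  if (!is.null(site_of)) {
    sites <- site_of[colnames(x)]
    per_site <- do.call(rbind, lapply(unique(sites), function(s) {
      v <- per_rep[sites == s]
      data.frame(site_id = s, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_replicate = per_rep, per_site = per_site)
}
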