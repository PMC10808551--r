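#' Between-context field correlation of one cell
#'
#' Pearson correlation of the spatial activity profiles of one cell in
#' two contexts, over bins occupied in both.
#'
#' @param map_a,map_b `spatial_map`s on identical bin edges.
#' @return Pearson r; `NA` with fewer than 4 jointly occupied bins or a
#'   zero-variance map.
#' @export
field_correlation <- function(map_a, map_b) {
  if (!isTRUE(all.equal(map_a$bin_edges, map_b$bin_edges)))
    abort("maps must share bin edges")
  ok <- map_a$occupied & map_b$occupied
  if (sum(ok) < 4) return(NA_real_)
  a <- map_a$lambda[ok]; b <- map_b$lambda[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# z-score a cell's map over space; NA if constant
zscore_map <- function(lambda) {
  s <- sd(lambda)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(lambda)))
  (lambda - mean(lambda)) / s
}

#' Population-vector correlation between two contexts
#'
#' Stacks the z-scored spatial maps of all place cells into a cells-x-bins
#' matrix per context, then correlates the across-cell population vectors
#' of the two contexts in each spatial bin. z-scoring each map over space
#' removes mean-rate differences so the measure isolates the spatial
#' pattern. Sessions with fewer than `min_cells` place cells in either
#' condition are ineligible.
#'
#' @param maps_a,maps_b Named lists of `spatial_map`s (same cells, same
#'   bin edges; typically 10-cm bins).
#' @param min_cells Eligibility threshold (default 5 place cells per
#'   condition).
#' @return Tibble: `bin`, `center`, `pv_corr`; or `NULL` (with a warning)
#'   for ineligible sessions. Cells whose map is constant in either
#'   context are dropped from the vectors.
#' @export
population_vector_correlation <- function(maps_a, maps_b, min_cells = 5) {
  common <- intersect(names(maps_a), names(maps_b))
  if (length(maps_a) < min_cells || length(maps_b) < min_cells ||
      length(common) < min_cells) {
    warn(sprintf(
      "session excluded: fewer than %d place cells in each condition",
      min_cells))
    return(NULL)
  }
  za <- sapply(common, function(id) zscore_map(maps_a[[id]]$lambda))
  zb <- sapply(common, function(id) zscore_map(maps_b[[id]]$lambda))
  keep <- colSums(is.na(za)) == 0 & colSums(is.na(zb)) == 0
  za <- za[, keep, drop = FALSE]; zb <- zb[, keep, drop = FALSE]
  if (ncol(za) < min_cells) {
    warn("session excluded: too few non-constant maps")
    return(NULL)
  }
  edges <- maps_a[[common[1]]]$bin_edges
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  pv <- vapply(seq_len(nrow(za)), function(i) {
    if (sd(za[i, ]) == 0 || sd(zb[i, ]) == 0) return(NA_real_)
    cor(za[i, ], zb[i, ])
  }, numeric(1))
  tibble::tibble(bin = seq_along(pv), center = centers, pv_corr = pv)
}

#' Contrast field-correlation distributions between two conditions
#'
#' Unpaired two-sided Wilcoxon rank-sum comparison of per-cell field
#' correlations, e.g. baseline vs chemogenetic suppression. Undefined
#' correlations are excluded (exclusion counts reported).
#'
#' @param r_a,r_b Numeric vectors of per-cell field correlations.
#' @return Tibble: `n_a`, `n_b`, `excluded_a`, `excluded_b`, `statistic`,
#'   `p_value`, `median_a`, `median_b`, `direction`.
#' @export
condition_contrast <- function(r_a, r_b) {
  a <- r_a[!is.na(r_a)]; b <- r_b[!is.na(r_b)]
  if (length(a) < 2 || length(b) < 2)
    abort("each condition needs at least 2 defined correlations")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
  tibble::tibble(
    n_a = length(a), n_b = length(b),
    excluded_a = length(r_a) - length(a),
    excluded_b = length(r_b) - length(b),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    median_a = median(a), median_b = median(b),
    direction = dplyr::case_when(
      median(a) > median(b) ~ "a > b",
      median(a) < median(b) ~ "a < b",
      TRUE ~ "none")
  )
}
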