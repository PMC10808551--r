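# Vectorized spatial metrics over circularly shifted alignments. The Rcpp
# kernel returns per-bin sums/counts for every shift; metric formulas are
# then applied column-wise.

# activity/position are already restricted to the analysis (masked)
# sequence of length M; `sel` selects a subsequence (e.g. one half) whose
# activity is binned against the circularly shifted position sequence.
shifted_maps <- function(activity, position, sel, shifts, bin_width,
                         track_length) {
  nb <- ceiling(track_length / bin_width)
  bins <- bin_index(position, bin_width, track_length)
  st <- shifted_bin_stats(activity[sel], bins, sel, as.integer(shifts), nb)
  counts <- st$counts
  lam <- st$sums / ifelse(counts > 0, counts, NA)
  p <- sweep(counts, 2, colSums(counts), "/")
  list(lambda = lam, p = p, counts = counts, n_bins = nb)
}

si_by_column <- function(sm) {
  lam <- pmax(sm$lambda, 0)
  lam[sm$counts == 0] <- NA
  lbar <- colSums(sm$p * lam, na.rm = TRUE)
  ratio <- sweep(lam, 2, lbar, "/")
  terms <- lam * log2(ratio) * sm$p
  terms[!is.finite(terms)] <- 0  # 0*log(0) and unoccupied bins
  out <- colSums(terms)
  out[lbar <= 0] <- NA
  out
}

coherence_by_column <- function(sm, circular) {
  nb <- sm$n_bins
  lam <- sm$lambda
  if (circular) {
    left <- lam[c(nb, seq_len(nb - 1)), , drop = FALSE]
    right <- lam[c(seq_len(nb - 1) + 1, 1), , drop = FALSE]
  } else {
    left <- rbind(NA, lam[seq_len(nb - 1), , drop = FALSE])
    right <- rbind(lam[seq_len(nb - 1) + 1, , drop = FALSE], NA)
  }
  neigh <- (left + right) / 2
  vapply(seq_len(ncol(lam)), function(j) {
    ok <- !is.na(lam[, j]) & !is.na(neigh[, j])
    if (sum(ok) < 4 || sd(lam[ok, j]) == 0 || sd(neigh[ok, j]) == 0)
      return(NA_real_)
    cor(lam[ok, j], neigh[ok, j])
  }, numeric(1))
}

vector_length_by_column <- function(sm, track_length, bin_width) {
  lam <- pmax(sm$lambda, 0)
  lam[is.na(lam)] <- 0
  centers <- (seq_len(sm$n_bins) - 0.5) * bin_width
  theta <- 2 * pi * centers / (sm$n_bins * bin_width)
  tot <- colSums(lam)
  vl <- sqrt(colSums(lam * cos(theta))^2 + colSums(lam * sin(theta))^2) / tot
  vl[tot <= 0] <- NA
  vl
}

stability_by_column <- function(sm1, sm2) {
  vapply(seq_len(ncol(sm1$lambda)), function(j) {
    ok <- sm1$counts[, j] > 0 & sm2$counts[, j] > 0
    if (sum(ok) < 4) return(NA_real_)
    a <- sm1$lambda[ok, j]; b <- sm2$lambda[ok, j]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
}

#' Circular-shuffle null distributions for spatial-tuning metrics
#'
#' The masked (analysis) samples of position and activity are
#' concatenated in recording order and the position sequence is
#' circularly shifted against the activity sequence by `n_shuffles`
#' uniformly drawn forward intervals (samples that fall off the end wrap
#' to the beginning); spatial information, coherence, tuning-vector
#' length, and split-half stability are recomputed for each shift.
#' Shifts are drawn with replacement from `[min_shift, M - min_shift]`
#' frames of masked time, excluding near-zero and near-full-length shifts
#' that would replicate the true alignment. A metric's tuning is
#' significant when its true value exceeds strictly more than 95% of the
#' null values.
#'
#' @param activity Activity vector over the (per-condition concatenated)
#'   frames.
#' @param position Position vector, same frames.
#' @param mask Logical frame mask (typically the movement mask).
#' @param fs Sampling rate, Hz.
#' @param n_shuffles Number of shifts (default 1000).
#' @param min_shift_s Minimum shift in seconds (default 10).
#' @param bin_width,track_length,circular Map geometry.
#' @param metrics Subset of
#'   `c("si", "coherence", "vector_length", "stability")`.
#' @param halves Optional list of `half1`/`half2` masks (see
#'   [split_halves()]); required for the stability null.
#' @param sig_quantile Exceedance fraction defining significance
#'   (default 0.95).
#' @return Tibble, one row per metric: `metric`, `n_shuffles`,
#'   `true_value`, `percentile_of_true`, `significant`, and the
#'   `null_values` list-column.
#' @export
circular_shuffle_null <- function(activity, position, mask, fs,
                                  n_shuffles = 1000, min_shift_s = 10,
                                  bin_width = 5, track_length = 400,
                                  circular = TRUE,
                                  metrics = c("si", "coherence",
                                              "vector_length", "stability"),
                                  halves = NULL, sig_quantile = 0.95) {
  keep <- which(mask & !is.na(activity))
  a <- activity[keep]
  pos <- position[keep]
  M <- length(keep)
  min_shift <- round(min_shift_s * fs)
  if (M <= 2 * min_shift)
    abort("masked trace shorter than twice the minimum shift")
  if ("stability" %in% metrics && is.null(halves))
    metrics <- setdiff(metrics, "stability")
  shifts <- sample(seq(min_shift, M - min_shift), n_shuffles, replace = TRUE)
  all_shifts <- c(0L, shifts)

  res <- list()
  needs_full <- any(c("si", "coherence", "vector_length") %in% metrics)
  if (needs_full) {
    sm <- shifted_maps(a, pos, seq_len(M), all_shifts, bin_width,
                       track_length)
    if ("si" %in% metrics) res$si <- si_by_column(sm)
    if ("coherence" %in% metrics)
      res$coherence <- coherence_by_column(sm, circular)
    if ("vector_length" %in% metrics)
      res$vector_length <- vector_length_by_column(sm, track_length, bin_width)
  }
  if ("stability" %in% metrics) {
    sm1 <- shifted_maps(a, pos, which(halves$half1[keep]), all_shifts,
                        bin_width, track_length)
    sm2 <- shifted_maps(a, pos, which(halves$half2[keep]), all_shifts,
                        bin_width, track_length)
    res$stability <- stability_by_column(sm1, sm2)
  }

  purrr::map_dfr(names(res), function(m) {
    v <- res[[m]]
    true <- v[1]
    null <- v[-1]
    n_ok <- sum(!is.na(null))
    pct <- if (is.na(true) || n_ok == 0) NA_real_ else
      100 * sum(null < true, na.rm = TRUE) / n_ok
    tibble::tibble(
      metric = m, n_shuffles = n_ok, true_value = true,
      percentile_of_true = pct,
      significant = !is.na(pct) && pct > 100 * sig_quantile,
      null_values = list(null)
    )
  })
}

#' Population-level bootstrap comparison of tuning values
#'
#' Selects one null value per cell at random and compares the resulting
#' distribution against the true per-cell values with a paired two-sided
#' Wilcoxon signed-rank test.
#'
#' @param true_values Numeric vector, one true metric value per cell.
#' @param null_values List of numeric null vectors, one per cell.
#' @return Tibble: `statistic`, `p_value`, `n`.
#' @export
population_bootstrap_compare <- function(true_values, null_values) {
  if (length(true_values) != length(null_values))
    abort("true_values and null_values must have one entry per cell")
  ok <- !is.na(true_values) & lengths(null_values) > 0
  if (sum(ok) < 5) abort("need at least 5 cells with nulls")
  sel <- vapply(null_values[ok], function(v) v[sample.int(length(v), 1)],
                numeric(1))
  wt <- suppressWarnings(
    wilcox.test(true_values[ok], sel, paired = TRUE, exact = FALSE))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = sum(ok))
}

#' Classify place cells
#'
#' A cell is a place cell in a context when its spatial information is
#' shuffle-significant and its movement transient rate is at least
#' `min_rate` transients/min.
#'
#' @param records Tibble with columns `cell_id`, `context`,
#'   `si_significant` (logical), `transient_rate` (transients/min).
#' @param min_rate Activity threshold, transients/min (default 1).
#' @return `records` with `is_place_cell` added; cells with missing rates
#'   are dropped (count reported via the `n_excluded` attribute).
#' @export
classify_place_cells <- function(records, min_rate = 1) {
  need <- c("cell_id", "context", "si_significant", "transient_rate")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0)
    abort(paste0("records is missing: ", paste(missing, collapse = ", ")))
  n0 <- nrow(records)
  out <- dplyr::filter(records, !is.na(.data$transient_rate)) |>
    dplyr::mutate(is_place_cell = .data$si_significant &
                    .data$transient_rate >= min_rate)
  attr(out, "n_excluded") <- n0 - nrow(out)
  out
}
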