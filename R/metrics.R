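#' Running-speed tuning of one cell
#'
#' Mean dF/F as a function of running speed in 1 cm/s bins; a linear fit
#' (with offset) of the binned means against each bin's mean speed gives
#' the slope as the sign and magnitude of speed modulation. Significance comes from the Pearson
#' correlation between the sample-level dF/F and speed values under the
#' mask; the modulation class combines the slope sign with that p value.
#'
#' @param dff dF/F vector of one cell.
#' @param speed Speed vector, cm/s.
#' @param mask Logical frame mask (default: all frames with finite data).
#' @param bin_width Speed-bin width, cm/s (default 1).
#' @param min_bin_time Minimum occupancy (s) for a bin to enter the fit.
#' @param fs Sampling rate, Hz.
#' @param alpha Significance level for the modulation class.
#' @return A `speed_tuning` object; see [tidy.speed_tuning()] and
#'   [glance.speed_tuning()].
#' @export
speed_tuning <- function(dff, speed, mask = NULL, bin_width = 1,
                         min_bin_time = 1, fs = 10, alpha = 0.05) {
  if (is.null(mask)) mask <- rep(TRUE, length(dff))
  ok <- mask & !is.na(dff) & !is.na(speed)
  x <- speed[ok]; y <- dff[ok]
  bins <- tibble::tibble(bin = floor(x / bin_width), x = x, y = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_dff = mean(.data$y), mean_speed = mean(.data$x),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(center = (.data$bin + 0.5) * bin_width,
                  occupancy_s = .data$n / fs) |>
    dplyr::filter(.data$occupancy_s >= min_bin_time)
  if (nrow(bins) < 2) {
    return(structure(list(bins = bins, slope = NA_real_,
                          intercept = NA_real_, pearson_r = NA_real_,
                          p_value = NA_real_, modulation_class = NA_character_,
                          n_samples = length(y)),
                     class = "speed_tuning"))
  }
  fit <- lm(mean_dff ~ mean_speed, data = bins)
  ct <- suppressWarnings(cor.test(x, y))
  slope <- unname(coef(fit)[2])
  cls <- if (is.na(ct$p.value) || ct$p.value >= alpha) "none"
         else if (slope > 0) "positive" else "negative"
  structure(
    list(bins = bins, slope = slope, intercept = unname(coef(fit)[1]),
         pearson_r = unname(ct$estimate), p_value = ct$p.value,
         modulation_class = cls, n_samples = length(y)),
    class = "speed_tuning"
  )
}

#' @export
print.speed_tuning <- function(x, ...) {
  cat(sprintf(
    "<speed_tuning> slope %.4g dF/F per cm/s, r = %.3f, p = %.3g (%s)\n",
    x$slope, x$pearson_r, x$p_value, x$modulation_class))
  invisible(x)
}

#' Tidy the binned speed-tuning curve
#' @param x A `speed_tuning` object.
#' @param ... Unused.
#' @return Tibble with `center`, `mean_dff`, `occupancy_s`.
#' @export
tidy.speed_tuning <- function(x, ...) {
  dplyr::select(x$bins, "center", "mean_dff", "occupancy_s")
}

#' One-row summary of a speed-tuning fit
#' @param x A `speed_tuning` object.
#' @param ... Unused.
#' @export
glance.speed_tuning <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, p_value = x$p_value,
                 modulation_class = x$modulation_class,
                 n_samples = x$n_samples)
}

#' Moving / immobile activity ratio
#'
#' Mean activity during movement divided by mean activity during
#' immobility and very slow movement. Ratios below 1 indicate
#' immobility-preferring cells.
#'
#' @param activity Activity vector.
#' @param moving,immobile Logical masks (see [movement_mask()],
#'   [immobility_mask()]).
#' @return Ratio; `NA` when either mask is empty or the immobile mean is
#'   not positive.
#' @export
move_immobile_ratio <- function(activity, moving, immobile) {
  if (sum(moving) == 0 || sum(immobile) == 0) return(NA_real_)
  m <- mean(activity[moving], na.rm = TRUE)
  i <- mean(activity[immobile], na.rm = TRUE)
  if (!is.finite(i) || i <= 0) return(NA_real_)
  m / i
}

#' Skaggs spatial information of a map
#'
#' `SI = sum_i lambda_i * log2(lambda_i / lambda_bar) * p_i` over occupied
#' bins, with `0 * log(0) := 0`. Negative bin means (possible for dF/F)
#' are clamped to zero before the logarithm; `lambda_bar` is recomputed
#' from the clamped map so the formula stays internally consistent.
#' The normalized variant divides by the cell's mean activity (mean dF/F
#' over masked time), giving bits per unit activity.
#'
#' @param map A `spatial_map`.
#' @return List: `si` (bits), `si_norm`, `lambda_bar`,
#'   `clamped_fraction` (share of occupied bins clamped at zero).
#' @export
spatial_information <- function(map) {
  lam <- map$lambda[map$occupied]
  p <- map$p[map$occupied]
  clamped <- lam < 0
  lam[clamped] <- 0
  lbar <- sum(p * lam)
  if (!is.finite(lbar) || lbar <= 0) {
    return(list(si = NA_real_, si_norm = NA_real_, lambda_bar = lbar,
                clamped_fraction = mean(clamped)))
  }
  terms <- ifelse(lam > 0, lam * log2(lam / lbar) * p, 0)
  si <- sum(terms)
  si_norm <- if (is.finite(map$mean_activity) && map$mean_activity > 0)
    si / map$mean_activity else NA_real_
  list(si = si, si_norm = si_norm, lambda_bar = lbar,
       clamped_fraction = mean(clamped))
}

#' Spatial coherence of a map
#'
#' Pearson correlation between each occupied bin's activity and the mean
#' of its two nearest neighbors (wrapping around the track seam when the
#' map is circular); a measure of local smoothness of the tuning curve.
#'
#' @param map A `spatial_map`.
#' @return Pearson r, or `NA` when fewer than 4 bins contribute or
#'   either vector is constant.
#' @export
spatial_coherence <- function(map) {
  lam <- map$lambda
  nb <- map$n_bins
  if (map$circular) {
    left <- lam[c(nb, seq_len(nb - 1))]
    right <- lam[c(seq_len(nb - 1) + 1, 1)]
  } else {
    left <- c(NA, lam[seq_len(nb - 1)])
    right <- c(lam[seq_len(nb - 1) + 1], NA)
  }
  neigh <- rowMeans(cbind(left, right))
  ok <- map$occupied & !is.na(lam) & !is.na(neigh)
  if (sum(ok) < 4) return(NA_real_)
  if (sd(lam[ok]) == 0 || sd(neigh[ok]) == 0) return(NA_real_)
  cor(lam[ok], neigh[ok])
}

#' Circular vector tuning of a map
#'
#' Places each bin's mean activity at its track angle and computes the
#' activity-weighted circular mean. The resultant length (0–1) measures
#' spatial concentration; the angle is the preferred position.
#'
#' @param map A `spatial_map` on a circular track.
#' @return List: `vector_length`, `vector_angle` (radians in `[0, 2*pi)`).
#' @export
vector_tuning <- function(map) {
  lam <- map$lambda
  lam[!map$occupied | is.na(lam)] <- 0
  lam <- pmax(lam, 0)
  tot <- sum(lam)
  if (tot <= 0) return(list(vector_length = NA_real_, vector_angle = NA_real_))
  centers <- (map$bin_edges[-1] + map$bin_edges[-length(map$bin_edges)]) / 2
  theta <- 2 * pi * centers / max(map$bin_edges)
  cx <- sum(lam * cos(theta)) / tot
  cy <- sum(lam * sin(theta)) / tot
  list(vector_length = sqrt(cx^2 + cy^2),
       vector_angle = atan2(cy, cx) %% (2 * pi))
}

#' Split-half stability of a spatial map
#'
#' Zero-lag Pearson correlation between the first- and second-half maps
#' over bins occupied in both halves.
#'
#' @param map_h1,map_h2 `spatial_map`s with identical bin edges.
#' @return Pearson r, or `NA` with < 4 jointly occupied bins or zero
#'   variance.
#' @export
within_session_stability <- function(map_h1, map_h2) {
  if (!isTRUE(all.equal(map_h1$bin_edges, map_h2$bin_edges)))
    abort("maps must share bin edges")
  ok <- map_h1$occupied & map_h2$occupied
  if (sum(ok) < 4) return(NA_real_)
  a <- map_h1$lambda[ok]; b <- map_h2$lambda[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}
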