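#' Sliding-percentile dF/F (principal-cell variant)
#'
#' Corrects slow drift by subtracting the 8th-percentile fluorescence in
#' a window of about 8 s around each time point, then divides by an
#' initial baseline estimate — the mean of all raw samples not exceeding
#' 3 SD of the total signal (samples above that likely belong to
#' transients). Recording-gap frames are excluded from the window
#' statistics and set to `NA` in the output.
#'
#' @param raw_f Numeric vector, raw fluorescence of one cell.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 8).
#' @param pct Percentile used for the running baseline (default 8).
#' @param gap Optional logical vector of recording-gap frames.
#' @return dF/F vector, same length as `raw_f`.
#' @export
dff_sliding_percentile <- function(raw_f, fs, window_s = 8, pct = 8,
                                   gap = NULL) {
  if (all(is.na(raw_f))) abort("raw_f is all-NA")
  n <- length(raw_f)
  half <- floor(window_s * fs / 2)
  if (2 * half + 1 < 3) abort("window must span at least 3 samples")
  if (2 * half + 1 > n) abort("window longer than trace")
  x <- raw_f
  if (!is.null(gap)) x[gap] <- NA
  base_run <- running_percentile(x, half, pct / 100)
  corrected <- raw_f - base_run
  ok <- !is.na(x)
  mu <- mean(x[ok]); s <- sd(x[ok])
  keep <- ok & x <= mu + 3 * s
  f0 <- mean(x[keep])
  if (!is.finite(f0) || f0 <= 0)
    abort("baseline estimate is not positive; raw units look invalid")
  dff <- corrected / f0
  if (!is.null(gap)) dff[gap] <- NA
  dff
}

# Truncated-window running percentile (no padding at the edges).
running_percentile <- function(x, half, p) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w) == 0) NA_real_ else
      quantile(w, p, names = FALSE, type = 7)
  }, numeric(1))
}

#' Per-segment percentile dF/F (interneuron variant)
#'
#' Divides each recording segment's trace by the 8th percentile of its own
#' fluorescence-value distribution, yielding a dimensionless
#' baseline-normalized trace. Used for interneurons, whose high firing
#' rates preclude discrete transient detection; their continuous dF/F is
#' analyzed directly as a rate proxy.
#'
#' @param raw_f Numeric vector, raw fluorescence of one cell.
#' @param segment_id Vector assigning each frame to a segment; `NA` frames
#'   (e.g. recording gaps) are normalized with their nearest segment but
#'   excluded from the percentile. Default: one segment.
#' @param pct Percentile (default 8).
#' @return Normalized trace (baseline near 1).
#' @export
dff_segment_percentile <- function(raw_f, segment_id = NULL, pct = 8) {
  n <- length(raw_f)
  if (is.null(segment_id)) segment_id <- rep(1L, n)
  if (length(segment_id) != n) abort("segment_id length mismatch")
  seg <- dplyr::if_else(is.na(segment_id),
                        vctrs_fill_locf(segment_id), segment_id)
  out <- numeric(n)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    vals <- raw_f[idx][!is.na(segment_id[idx])]
    p8 <- quantile(vals, pct / 100, names = FALSE)
    if (!is.finite(p8) || p8 <= 0)
      abort("segment percentile is not positive; raw units look invalid")
    out[idx] <- raw_f[idx] / p8
  }
  out
}

# forward-fill then backward-fill segment labels across NA runs
vctrs_fill_locf <- function(x) {
  filled <- x
  last <- NA
  for (i in seq_along(x)) {
    if (!is.na(x[i])) last <- x[i] else filled[i] <- last
  }
  nxt <- NA
  for (i in rev(seq_along(filled))) {
    if (!is.na(filled[i])) nxt <- filled[i] else filled[i] <- nxt
  }
  filled
}

# ---- transient detection ----------------------------------------------

# Run-length event finder used for both polarities. Events start where the
# trace exceeds baseline + thr*sd for at least min_dur seconds and end when
# it falls back below baseline + offset_frac*thr*sd.
find_events <- function(dff, fs, baseline, sdev, threshold, min_dur,
                        offset_frac) {
  hi <- baseline + threshold * sdev
  lo <- baseline + offset_frac * threshold * sdev
  above <- !is.na(dff) & dff > hi
  if (!any(above)) {
    return(tibble::tibble(onset_frame = integer(0), offset_frame = integer(0),
                          peak_dff = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= max(1L, round(min_dur * fs)))
  if (length(runs) == 0) {
    return(tibble::tibble(onset_frame = integer(0), offset_frame = integer(0),
                          peak_dff = numeric(0)))
  }
  n <- length(dff)
  onset <- integer(0); offset <- integer(0)
  last_end <- 0L
  for (k in runs) {
    s <- starts[k]
    if (s <= last_end) next  # swallowed by the previous event's decay
    e <- ends[k]
    while (e < n && !is.na(dff[e + 1]) && dff[e + 1] > lo) e <- e + 1L
    onset <- c(onset, s); offset <- c(offset, e)
    last_end <- e
  }
  tibble::tibble(
    onset_frame = onset, offset_frame = offset,
    peak_dff = vapply(seq_along(onset),
                      function(i) max(dff[onset[i]:offset[i]]), numeric(1))
  )
}

# Baseline and SD from transient-free samples only.
transient_free_stats <- function(dff, events) {
  mask <- rep(TRUE, length(dff))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events)))
      mask[events$onset_frame[i]:events$offset_frame[i]] <- FALSE
  }
  mask[is.na(dff)] <- FALSE
  list(baseline = mean(dff[mask]), sd = sd(dff[mask]))
}

detect_transients_once <- function(dff, fs, threshold, min_dur, offset_frac) {
  ok <- !is.na(dff)
  mu0 <- mean(dff[ok]); s0 <- sd(dff[ok])
  init_keep <- ok & dff <= mu0 + 3 * s0
  base <- mean(dff[init_keep]); sdev <- sd(dff[init_keep])
  ev <- find_events(dff, fs, base, sdev, threshold, min_dur, offset_frac)
  # definitive baseline/SD from transient-free samples, then re-detect
  st <- transient_free_stats(dff, ev)
  ev <- find_events(dff, fs, st$baseline, st$sd, threshold, min_dur,
                    offset_frac)
  list(events = ev, baseline = st$baseline, sd = st$sd)
}

#' Calibrate transient-detection parameters to a false-positive ceiling
#'
#' Searches a grid of (onset threshold, minimum duration) pairs from
#' permissive to stringent and returns the least stringent pair whose
#' false-positive rate — the ratio of negative-going to positive-going
#' transients, with negatives detected by the same detector on the
#' sign-inverted, baseline-centered trace — is below `fpr_max`.
#'
#' @param dff dF/F vector of one cell.
#' @param fs Sampling rate, Hz.
#' @param thresholds Candidate onset thresholds, multiples of baseline SD.
#' @param durations Candidate minimum durations, seconds.
#' @param offset_frac Event-termination level, fraction of the onset
#'   threshold (default 0.5).
#' @param fpr_max False-positive ceiling (default 0.05).
#' @return A list of class `transient_params`: `onset_threshold`,
#'   `min_duration`, `offset_fraction`, `achieved_fpr`, `n_pos`, `n_neg`.
#' @export
calibrate_transient_params <- function(dff, fs,
                                       thresholds = c(2, 2.5, 3, 3.5, 4),
                                       durations = c(0.2, 0.3, 0.5, 1.0),
                                       offset_frac = 0.5, fpr_max = 0.05) {
  if (length(thresholds) == 0 || length(durations) == 0)
    abort("calibration grid is empty")
  grid <- tidyr::expand_grid(threshold = sort(thresholds),
                             min_dur = sort(durations))
  best_ratio <- Inf
  for (i in seq_len(nrow(grid))) {
    thr <- grid$threshold[i]; md <- grid$min_dur[i]
    det <- detect_transients_once(dff, fs, thr, md, offset_frac)
    n_pos <- nrow(det$events)
    inv <- 2 * det$baseline - dff
    n_neg <- nrow(find_events(inv, fs, det$baseline, det$sd, thr, md,
                              offset_frac))
    ratio <- if (n_pos == 0) {
      if (n_neg == 0) 0 else Inf
    } else n_neg / n_pos
    best_ratio <- min(best_ratio, ratio)
    if (ratio < fpr_max) {
      return(structure(
        list(onset_threshold = thr, min_duration = md,
             offset_fraction = offset_frac, achieved_fpr = ratio,
             n_pos = n_pos, n_neg = n_neg),
        class = "transient_params"))
    }
  }
  abort(sprintf(
    "no grid point achieves FPR < %.3g; best achieved ratio %.3g",
    fpr_max, best_ratio))
}

#' @export
print.transient_params <- function(x, ...) {
  cat(sprintf(
    "<transient_params> %.1f sd onset, %.2g s min duration, FPR %.3g (%d+/%d-)\n",
    x$onset_threshold, x$min_duration, x$achieved_fpr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Detect significant calcium transients
#'
#' Extracts positive excursions crossing `onset_threshold` baseline SDs
#' for at least `min_duration` seconds, each ending when the trace decays
#' to `offset_fraction` of the onset level. The definitive baseline and
#' SD are recomputed from transient-free samples. All dF/F values outside
#' detected transients are masked to zero in `masked_dff`.
#'
#' @param dff dF/F vector of one cell.
#' @param fs Sampling rate, Hz.
#' @param params `transient_params` from [calibrate_transient_params()].
#' @return List of class `transient_events`: `events` tibble
#'   (`onset_frame`, `offset_frame`, `peak_dff`), `baseline`, `sd`,
#'   `transient_mask` (logical), `masked_dff`.
#' @export
detect_transients <- function(dff, fs, params) {
  det <- detect_transients_once(dff, fs, params$onset_threshold,
                                params$min_duration, params$offset_fraction)
  ev <- det$events
  mask <- rep(FALSE, length(dff))
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev)))
      mask[ev$onset_frame[i]:ev$offset_frame[i]] <- TRUE
  }
  mask[is.na(dff)] <- FALSE
  masked <- ifelse(mask, dff, 0)
  masked[is.na(dff)] <- NA
  structure(list(events = ev, baseline = det$baseline, sd = det$sd,
                 transient_mask = mask, masked_dff = masked),
            class = "transient_events")
}

#' @export
print.transient_events <- function(x, ...) {
  cat("<transient_events> ", nrow(x$events), " events, baseline ",
      signif(x$baseline, 3), ", sd ", signif(x$sd, 3), "\n", sep = "")
  invisible(x)
}

#' Transient rate during movement
#'
#' Counts event onsets falling inside the movement mask and divides by
#' the total moving time in minutes.
#'
#' @param events `transient_events` (or its `events` tibble).
#' @param mask Logical movement mask, one entry per frame.
#' @param fs Sampling rate, Hz.
#' @return Rate in transients/min; `NA` when there is no moving time.
#' @export
transient_rate <- function(events, mask, fs) {
  ev <- if (inherits(events, "transient_events")) events$events else events
  minutes <- sum(mask) / fs / 60
  if (minutes == 0) return(NA_real_)
  sum(mask[ev$onset_frame]) / minutes
}
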