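test_that("sliding-percentile dF/F flattens constant traces and slow ramps", {
  fs <- 10
  flat <- rep(200, 600)
  d <- dff_sliding_percentile(flat, fs)
  expect_true(all(abs(d) < 1e-12))
  # slow linear ramp with no events: residual dF/F stays small
  ramp <- 200 + seq(0, 10, length.out = 1200)
  d2 <- dff_sliding_percentile(ramp, fs)
  expect_lt(max(abs(d2)), 0.05)
})

test_that("boxcar event amplitude is recovered as amplitude / baseline", {
  fs <- 10
  b <- 120
  x <- boxcar_trace(1200, baseline = b, events = list(501:510), amp = 30)
  d <- dff_sliding_percentile(x, fs)
  expect_equal(max(d), 30 / b, tolerance = 0.05)
})

test_that("window preconditions are enforced", {
  expect_error(dff_sliding_percentile(rep(NA_real_, 100), 10), "all-NA")
  expect_error(dff_sliding_percentile(rep(1, 10), 10, window_s = 8),
               "window longer")
})

test_that("segment-percentile normalization is per segment", {
  # segment with 8th percentile 2.0: every value halved
  x <- rep(2, 100); x[50] <- 4
  d <- dff_segment_percentile(x)
  expect_equal(d[1], 1)
  expect_equal(d[50], 2)
  # two segments with different baselines normalized independently
  seg <- rep(c(1L, 2L), each = 100)
  y <- c(rep(10, 100), rep(20, 100))
  d2 <- dff_segment_percentile(y, seg)
  expect_equal(unique(d2), 1)
  # single segment equals global normalization
  expect_equal(dff_segment_percentile(y),
               y / quantile(y, 0.08, names = FALSE))
  expect_error(dff_segment_percentile(c(-1, 0, 0), rep(1L, 3)), "percentile")
})

test_that("transient detector finds boxcar events with correct extent", {
  fs <- 10
  set.seed(71)
  d <- rnorm(3000, 0, 0.02)
  d[1001:1010] <- d[1001:1010] + 0.5  # 1-s, ~25-sigma boxcar
  params <- calibrate_transient_params(d, fs)
  det <- detect_transients(d, fs, params)
  expect_equal(nrow(det$events), 1)
  expect_lte(abs(det$events$onset_frame - 1001), 1)
  # two events separated by a sub-threshold return -> 2 events
  d[2001:2010] <- d[2001:2010] + 0.5
  det2 <- detect_transients(d, fs, params)
  expect_equal(nrow(det2$events), 2)
  # event shorter than min_duration at a strict grid point -> rejected
  short <- rnorm(3000, 0, 0.02)
  short[1500] <- 0.5  # single frame
  p_strict <- list(onset_threshold = 3, min_duration = 0.5,
                   offset_fraction = 0.5)
  det3 <- detect_transients(short, fs, p_strict)
  expect_equal(nrow(det3$events), 0)
})

test_that("calibration walks past permissive grid points on pure noise", {
  set.seed(5)
  d <- rnorm(6000, 0, 0.05)  # symmetric noise: permissive points have FPR ~ 1
  expect_error(
    calibrate_transient_params(d, 10, thresholds = 2, durations = 0.2),
    "best achieved")
  # with the full grid a stringent point is found or an error raised;
  # on success the guarantee holds
  res <- tryCatch(calibrate_transient_params(d, 10), error = identity)
  if (!inherits(res, "error")) {
    expect_lt(res$achieved_fpr, 0.05)
    expect_true(res$onset_threshold > 2 || res$min_duration > 0.2)
  }
})

test_that("calibrated detection recovers large events with no negatives", {
  fs <- 10
  set.seed(42)
  d <- rnorm(6000, 0, 0.02)
  onsets <- seq(100, 5800, length.out = 20)
  for (o in onsets) d[o:(o + 9)] <- d[o:(o + 9)] + 0.4
  params <- calibrate_transient_params(d, fs)
  expect_lt(params$achieved_fpr, 0.05)
  det <- detect_transients(d, fs, params)
  expect_gte(nrow(det$events), 19)
  # empty grid errors
  expect_error(calibrate_transient_params(d, fs, thresholds = numeric(0)),
               "empty")
})

test_that("detector is equivariant to positive rescaling of raw_f", {
  fs <- 10
  set.seed(9)
  raw <- boxcar_trace(2000, baseline = 100,
                      events = list(501:510, 1401:1412), amp = 25,
                      noise_sd = 1)
  d1 <- dff_sliding_percentile(raw, fs)
  d2 <- dff_sliding_percentile(raw * 7.3, fs)
  expect_equal(d1, d2, tolerance = 1e-10)
  p1 <- calibrate_transient_params(d1, fs)
  ev1 <- detect_transients(d1, fs, p1)
  ev2 <- detect_transients(d2, fs, p1)
  expect_equal(ev1$events$onset_frame, ev2$events$onset_frame)
})

test_that("masked dF/F is exactly zero outside detected events", {
  fs <- 10
  set.seed(3)
  d <- rnorm(3000, 0, 0.02)
  d[1001:1010] <- d[1001:1010] + 0.5
  det <- detect_transients(d, fs, calibrate_transient_params(d, fs))
  expect_true(all(det$masked_dff[!det$transient_mask] == 0))
  expect_true(all(det$masked_dff[det$transient_mask] ==
                    d[det$transient_mask]))
})

test_that("transient rate is onsets per moving minute", {
  ev <- tibble::tibble(onset_frame = c(10, 50, 80), offset_frame = c(12, 55, 83),
                       peak_dff = 1)
  mask <- rep(TRUE, 900)  # 90 s at 10 Hz
  expect_equal(transient_rate(ev, mask, 10), 2)
  # onsets only during immobility -> 0
  mask2 <- rep(TRUE, 900); mask2[c(10, 50, 80)] <- FALSE
  expect_equal(transient_rate(ev, mask2, 10), 0)
  expect_true(is.na(transient_rate(ev, rep(FALSE, 900), 10)))
})

test_that("movement transient-rate estimate covers the true Poisson rate", {
  # true 4/min over 10 min: estimate within [2.8, 5.2] w.p. > 0.95
  set.seed(12)
  n <- 6000  # 10 min at 10 Hz
  onsets <- which(rbinom(n, 1, 4 / 60 / 10) == 1)
  ev <- tibble::tibble(onset_frame = onsets, offset_frame = onsets + 2,
                       peak_dff = 1)
  r <- transient_rate(ev, rep(TRUE, n), 10)
  expect_gte(r, 2.8); expect_lte(r, 5.2)
})
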