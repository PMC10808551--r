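test_that("behavior simulation is deterministic and obeys its config", {
  cfg <- load_config(overrides = list(n_blocks = 4))
  set.seed(21); a <- simulate_behavior(cfg)
  set.seed(21); b <- simulate_behavior(cfg)
  expect_identical(a, b)
  expect_true(all(a$position >= 0 & a$position < cfg$track_length))
  expect_true(all(a$speed >= 0))
  # alternating context blocks present
  expect_setequal(unique(a$context_id[!a$recording_gap]),
                  c("familiar", "novel"))
  # gap frames separate blocks
  expect_gt(sum(a$recording_gap), 0)
})

test_that("zero pause probability keeps speed positive at non-gap samples", {
  cfg <- load_config(overrides = list(pause_rate = 0, n_blocks = 2))
  set.seed(2)
  beh <- simulate_behavior(cfg)
  expect_true(all(beh$speed[!beh$recording_gap] > 0))
})

test_that("a full lap occupies every 5-cm bin within each context", {
  cfg <- load_config(overrides = list(block_mode = "laps", n_blocks = 2,
                                      laps_per_block = 2, pause_rate = 0))
  set.seed(13)
  beh <- simulate_behavior(cfg)
  for (idx in segment_contexts(beh)) {
    occ <- compute_occupancy(beh$position[idx],
                             rep(TRUE, length(idx)), 5, 400)
    expect_true(all(occ > 0))
  }
})

test_that("population mixture fractions are recovered within binomial CI", {
  cfg <- load_config(overrides = list(n_cells = 500, frac_speed_pos = 0.5,
                                      frac_speed_neg = 0.25))
  set.seed(31)
  gt <- sample_population(cfg)
  ci <- qbinom(c(0.025, 0.975), 500, 0.25) / 500
  obs <- mean(gt$speed_class == "negative")
  expect_gte(obs, ci[1]); expect_lte(obs, ci[2])
  expect_true(all(gt$speed_slope[gt$speed_class == "negative"] < 0))
  expect_true(all(gt$speed_slope[gt$speed_class == "none"] == 0))
})

test_that("degenerate mixtures behave as specified", {
  cfg1 <- load_config(overrides = list(n_cells = 50, frac_speed_pos = 1,
                                       frac_speed_neg = 0))
  set.seed(1)
  expect_true(all(sample_population(cfg1)$speed_slope > 0))
  cfg2 <- load_config(overrides = list(n_cells = 50, frac_place = 0))
  expect_true(all(sample_population(cfg2)$field_gain == 0))
  expect_error(sample_population(
    load_config(overrides = list(frac_speed_pos = 0.8, frac_speed_neg = 0.4))),
    "fractions")
})

test_that("spike generation matches Poisson statistics", {
  # constant rate 5/s for 100 s: count within [400, 600] w.p. > 0.99
  cfg <- load_config(overrides = list(n_blocks = 1, block_s = 100,
                                      pause_rate = 0))
  set.seed(8)
  beh <- simulate_behavior(cfg)
  gt <- tibble::tibble(cell_id = "c1", speed_class = "none",
                       baseline_rate = 5, speed_slope = 0,
                       field_center = 0, field_width = 50, field_gain = 0,
                       context_gain = 1, spike_times = list(NULL))
  gt <- simulate_spikes(beh, gt, cfg)
  n <- length(gt$spike_times[[1]])
  expect_gte(n, 400); expect_lte(n, 600)
  # all-zero rate -> no spikes
  gt0 <- gt; gt0$baseline_rate <- 0; gt0$field_gain <- 0
  gt0 <- simulate_spikes(beh, gt0, cfg)
  expect_length(gt0$spike_times[[1]], 0)
})

test_that("context gain 0 silences the novel context", {
  cfg <- load_config(overrides = list(n_blocks = 4))
  set.seed(4)
  beh <- simulate_behavior(cfg)
  gt <- tibble::tibble(cell_id = "c1", speed_class = "none",
                       baseline_rate = 5, speed_slope = 0,
                       field_center = 0, field_width = 50, field_gain = 0,
                       context_gain = 0, spike_times = list(NULL))
  gt <- simulate_spikes(beh, gt, cfg)
  st <- gt$spike_times[[1]]
  novel_t <- beh$t[beh$context_id == "novel" & !beh$recording_gap]
  dt <- 1 / cfg$fs
  in_novel <- vapply(st, function(s)
    any(abs(novel_t - s) < dt), logical(1))
  expect_false(any(in_novel))
  expect_gt(length(st), 0)
})

test_that("fluorescence rendering matches the closed-form kernel", {
  cfg <- load_config(overrides = list(shot_noise_sd = 0, drift_amplitude = 0,
                                      spike_amp = 0.5))
  # no spikes: constant photon baseline
  f0 <- render_fluorescence(list(numeric(0)), 50, cfg)
  expect_equal(unname(f0[, 1]), rep(cfg$photon_baseline, 50))
  # one spike on a frame boundary: peak amplitude = baseline * amp * k(peak)
  st <- list(10.0)  # seconds; frame grid at 0.1 s
  f1 <- render_fluorescence(st, 300, cfg)
  expected_peak <- cfg$photon_baseline *
    (1 + cfg$spike_amp * max(calcium_kernel(seq(0, 5, by = 0.1))))
  expect_equal(max(f1[, 1]), expected_peak, tolerance = 1e-10)
  tpk_frames <- which.max(f1[, 1]) -
    which(f1[, 1] > cfg$photon_baseline + 1e-6)[1]
  # peak a couple of frames after onset (rise 0.1 s, decay 0.7 s)
  expect_lte(tpk_frames, 4)
})

test_that("same seed gives bit-identical sessions", {
  a <- simulate_session(list(n_cells = 3, n_blocks = 2), seed = 99)
  b <- simulate_session(list(n_cells = 3, n_blocks = 2), seed = 99)
  expect_identical(a$session$traces$raw_f, b$session$traces$raw_f)
  expect_identical(a$session$behavior, b$session$behavior)
  expect_identical(a$truth$spike_times, b$truth$spike_times)
})

test_that("doubling session length halves the empirical rate error", {
  # rate estimated from generated spikes; SD over cells scales as 1/sqrt(T)
  est_sd <- function(block_s, n_cells) {
    cfg <- load_config(overrides = list(n_blocks = 1, block_s = block_s,
                                        pause_rate = 0))
    beh <- simulate_behavior(cfg)
    gt <- tibble::tibble(cell_id = paste0("c", seq_len(n_cells)),
                         speed_class = "none", baseline_rate = 5,
                         speed_slope = 0, field_center = 0, field_width = 50,
                         field_gain = 0, context_gain = 1,
                         spike_times = vector("list", n_cells))
    gt <- simulate_spikes(beh, gt, cfg)
    sd(lengths(gt$spike_times) / max(beh$t))
  }
  set.seed(5)
  ratio <- est_sd(120, 300) / est_sd(30, 300)
  expect_equal(ratio, 0.5, tolerance = 0.15)
})
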