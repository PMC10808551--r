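test_that("movement mask applies the 2 cm/s threshold inclusively", {
  expect_equal(movement_mask(c(0, 1.9, 2.0, 5)), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sum(movement_mask(rep(0, 10))), 0)
  # gap samples always excluded regardless of speed
  expect_equal(movement_mask(c(5, 5), gap = c(FALSE, TRUE)), c(TRUE, FALSE))
  expect_equal(immobility_mask(c(0, 1.9, 2.0, 5)),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("occupancy is uniform under constant-speed circular running", {
  beh <- constant_run(speed = 20, laps = 5)
  occ <- compute_occupancy(beh$position, rep(TRUE, nrow(beh)))
  expect_equal(sum(occ), 1)
  expect_true(all(abs(occ - 1 / 80) < 0.25 / 80))
  # confinement to one bin
  occ1 <- compute_occupancy(rep(12, 50), rep(TRUE, 50))
  expect_equal(occ1[3], 1)
  expect_error(compute_occupancy(rep(12, 50), rep(FALSE, 50)), "mask")
})

test_that("spatial maps average activity per bin and keep the identity", {
  beh <- constant_run(speed = 20, laps = 4)
  n <- nrow(beh)
  # constant activity
  m <- spatial_map(rep(3, n), beh$position, rep(TRUE, n))
  expect_true(all(abs(m$lambda[m$occupied] - 3) < 1e-12))
  # indicator of one bin
  act <- as.numeric(beh$position >= 35 & beh$position < 40)
  m2 <- spatial_map(act, beh$position, rep(TRUE, n))
  expect_gt(m2$lambda[8], 0)
  expect_true(all(m2$lambda[-8][m2$occupied[-8]] == 0))
  # lambda_bar identity on random maps
  set.seed(2)
  for (i in 1:20) {
    a <- rexp(n)
    mm <- spatial_map(a, beh$position, rep(TRUE, n))
    expect_lt(abs(mm$lambda_bar -
                    sum(mm$p[mm$occupied] * mm$lambda[mm$occupied])), 1e-12)
  }
})

test_that("maps are invariant to frame order and equivariant to rotation", {
  beh <- constant_run(speed = 20, laps = 4)
  n <- nrow(beh)
  set.seed(3)
  a <- rexp(n)
  m <- spatial_map(a, beh$position, rep(TRUE, n))
  perm <- sample(n)
  mp <- spatial_map(a[perm], beh$position[perm], rep(TRUE, n))
  expect_equal(m$lambda, mp$lambda)
  # rotating the position trace by k bins rotates the map by k bins
  k <- 7
  pos_rot <- (beh$position + k * 5) %% 400
  mr <- spatial_map(a, pos_rot, rep(TRUE, n))
  expect_equal(mr$lambda, m$lambda[((seq_len(80) - 1 - k) %% 80) + 1])
})

test_that("simulated place-field map peaks at the true field center", {
  sim <- simulate_session(list(
    n_cells = 1, block_mode = "laps", n_blocks = 1, laps_per_block = 10,
    frac_place = 1, field_gain = c(5, 5), frac_speed_pos = 0,
    frac_speed_neg = 0, shot_noise_sd = 0.005, drift_amplitude = 0,
    contexts = "familiar"), seed = 17)
  ses <- preprocess(sim$session, "interneuron")
  beh <- ses$behavior
  mv <- movement_mask(beh$speed, gap = beh$recording_gap)
  m <- spatial_map(ses$traces$dff[, 1], beh$position, mv)
  centers <- (seq_len(80) - 0.5) * 5
  peak <- centers[which.max(m$lambda)]
  d <- abs(peak - sim$truth$field_center[1])
  expect_lte(min(d, 400 - d), 10)  # within +/- 1 bin of truth
})

test_that("split_halves cuts at the median trial per context", {
  beh <- tibble::tibble(
    t = seq_len(100) / 10, position = rep(1, 100), speed = 5,
    context_id = "familiar", trial_index = rep(0:9, each = 10),
    recording_gap = FALSE)
  h <- split_halves(beh)
  expect_equal(sort(unique(beh$trial_index[h$half1])), 0:4)
  expect_equal(sort(unique(beh$trial_index[h$half2])), 5:9)
  # odd count: first half larger
  beh7 <- dplyr::filter(beh, trial_index < 7)
  h7 <- split_halves(beh7)
  expect_equal(sort(unique(beh7$trial_index[h7$half1])), 0:3)
  expect_equal(sort(unique(beh7$trial_index[h7$half2])), 4:6)
  # single-trial context errors
  beh1 <- dplyr::filter(beh, trial_index == 0)
  expect_error(split_halves(beh1), "fewer than 2 trials")
})

test_that("context segmentation preserves order and excludes gaps", {
  cfg <- load_config(overrides = list(n_blocks = 4))
  set.seed(2)
  beh <- simulate_behavior(cfg)
  segs <- segment_contexts(beh)
  expect_named(segs, c("familiar", "novel"))
  expect_false(any(beh$recording_gap[unlist(segs)]))
  expect_true(all(diff(segs$familiar) > 0))
  # familiar duration equals the sum of familiar blocks
  expect_equal(length(segs$familiar),
               sum(beh$context_id == "familiar" & !beh$recording_gap))
  expect_error(segment_contexts(beh, "unknown_ctx"), "unknown context")
  # single-context session yields one segment
  one <- dplyr::filter(beh, context_id == "familiar")
  expect_length(segment_contexts(one), 1)
})
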