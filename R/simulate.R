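#' Simulate lap-based running behavior on a virtual track
#'
#' Generates a behavior trace emulating a head-fixed mouse running on a
#' 4-m circular (or linear) track with alternating context blocks. The
#' speed process is a bounded mean-reverting random walk with a two-state
#' run/pause switch; position is the integral of speed, wrapped at the
#' track length. Context blocks are separated by blanked teleport
#' intervals flagged `recording_gap`, during which no behavior is
#' captured by downstream analyses.
#'
#' Two block structures are supported: fixed-duration blocks
#' (`block_mode = "time"`, default 60 s) and fixed-lap blocks
#' (`block_mode = "laps"`, default 15 laps), matching the two kinds of
#' session design the pipeline handles. In time mode `trial_index`
#' counts context blocks; in lap mode it counts laps.
#'
#' Uses the current RNG state; seed upstream (e.g. [simulate_session()])
#' for reproducibility.
#'
#' @param cfg A `hippo_config` (see [default_config()]).
#' @return A behavior tibble (`t`, `position`, `speed`, `context_id`,
#'   `trial_index`, `recording_gap`).
#' @export
simulate_behavior <- function(cfg = default_config()) {
  if (cfg$block_mode == "time" && cfg$block_s <= 0)
    abort("block_s must be positive")
  if (cfg$n_blocks < 1) abort("n_blocks must be >= 1")
  dt <- 1 / cfg$fs
  L <- cfg$track_length
  ctxs <- rep(cfg$contexts, length.out = cfg$n_blocks)

  blocks <- vector("list", cfg$n_blocks)
  gap_n <- round(cfg$gap_s * cfg$fs)
  trial_counter <- 0L
  for (b in seq_len(cfg$n_blocks)) {
    if (cfg$block_mode == "time") {
      speed <- sim_speed_walk(round(cfg$block_s * cfg$fs), cfg)
      pos_unwrapped <- cumsum(speed * dt)
      trial <- rep(trial_counter, length(speed))
      trial_counter <- trial_counter + 1L
    } else if (cfg$block_mode == "laps") {
      target <- cfg$laps_per_block * L
      speed <- numeric(0)
      # grow in 30-s chunks until the block's distance target is reached
      while (sum(speed) * dt < target) {
        speed <- c(speed, sim_speed_walk(30 * cfg$fs, cfg))
      }
      pos_unwrapped <- cumsum(speed * dt)
      keep <- pos_unwrapped < target
      speed <- speed[keep]
      pos_unwrapped <- pos_unwrapped[keep]
      trial <- trial_counter + as.integer(pos_unwrapped %/% L)
      trial_counter <- max(trial) + 1L
    } else {
      abort("block_mode must be 'time' or 'laps'")
    }
    blk <- tibble::tibble(
      position = pos_unwrapped %% L,
      speed = speed,
      context_id = ctxs[b],
      trial_index = as.integer(trial),
      recording_gap = FALSE
    )
    if (b < cfg$n_blocks && gap_n > 0) {
      blk <- dplyr::bind_rows(blk, tibble::tibble(
        position = 0, speed = 0, context_id = ctxs[b + 1],
        trial_index = trial_counter, recording_gap = TRUE
      )[rep(1, gap_n), ])
    }
    blocks[[b]] <- blk
  }
  beh <- dplyr::bind_rows(blocks)
  beh$t <- seq_len(nrow(beh)) * dt
  dplyr::select(beh, "t", "position", "speed", "context_id", "trial_index",
                "recording_gap")
}

# Mean-reverting speed walk with run/pause switching. Run-state speed has a
# small positive floor; pause-state speed is sub-threshold jitter emulating
# head-motion artifacts while the animal sits still.
sim_speed_walk <- function(n, cfg) {
  dt <- 1 / cfg$fs
  a <- exp(-dt / cfg$speed_tau)
  innov_sd <- cfg$speed_sd * sqrt(1 - a^2)
  v <- numeric(n)
  running <- TRUE
  cur <- cfg$mean_speed
  for (i in seq_len(n)) {
    if (running) {
      if (runif(1) < cfg$pause_rate * dt) running <- FALSE
    } else {
      if (runif(1) < cfg$unpause_rate * dt) running <- TRUE
    }
    if (running) {
      cur <- cfg$mean_speed + a * (cur - cfg$mean_speed) + innov_sd * rnorm(1)
      cur <- max(cur, cfg$min_run_speed)
      v[i] <- cur
    } else {
      v[i] <- abs(rnorm(1, 0, 0.4))
      cur <- cfg$mean_speed / 2  # resume below cruising speed
    }
  }
  v
}

#' Draw a synthetic cell population with known tuning parameters
#'
#' Cells are assigned a speed-modulation class (positive / negative /
#' unmodulated slope) and independently a place-coding flag; parameters
#' are drawn from the ranges in the config. `context_gain` is a
#' log-normal multiplier applied to the firing rate in the novel context.
#'
#' @param cfg A `hippo_config`; mixture fractions `frac_speed_pos`,
#'   `frac_speed_neg` (their complement is unmodulated) and `frac_place`.
#' @return A ground-truth tibble, one row per cell, with an empty
#'   `spike_times` list-column to be filled by [simulate_spikes()].
#' @export
sample_population <- function(cfg = default_config()) {
  fpos <- cfg$frac_speed_pos; fneg <- cfg$frac_speed_neg
  if (fpos < 0 || fneg < 0 || fpos + fneg > 1 + 1e-12)
    abort("speed-class fractions must be nonnegative and sum to at most 1")
  if (cfg$frac_place < 0 || cfg$frac_place > 1)
    abort("frac_place must lie in [0, 1]")
  n <- cfg$n_cells
  cls <- sample(c("positive", "negative", "none"), n, replace = TRUE,
                prob = c(fpos, fneg, 1 - fpos - fneg))
  base <- runif(n, cfg$baseline_rate[1], cfg$baseline_rate[2])
  slope_abs <- base * runif(n, cfg$speed_slope_rel[1], cfg$speed_slope_rel[2])
  slope <- ifelse(cls == "positive", slope_abs,
                  ifelse(cls == "negative", -slope_abs, 0))
  is_place <- runif(n) < cfg$frac_place
  center <- runif(n, 0, cfg$track_length)
  center_novel <- if (identical(cfg$remap_mode, "global"))
    runif(n, 0, cfg$track_length) else center
  tibble::tibble(
    cell_id = paste0("cell", seq_len(n)),
    speed_class = cls,
    baseline_rate = base,
    speed_slope = slope,
    field_center = center,
    field_center_novel = center_novel,
    field_width = runif(n, cfg$field_width[1], cfg$field_width[2]),
    field_gain = ifelse(is_place,
                        runif(n, cfg$field_gain[1], cfg$field_gain[2]), 0),
    context_gain = rlnorm(n, 0, cfg$context_gain_sdlog),
    spike_times = vector("list", n)
  )
}

# Unit-peak von Mises spatial field on the track; width given as FWHM in cm.
von_mises_field <- function(position, center, fwhm, L) {
  kappa <- log(2) / (1 - cos(pi * fwhm / L))
  theta <- 2 * pi * (position - center) / L
  exp(kappa * (cos(theta) - 1))
}

# Instantaneous event rate (events/s) of one cell given behavior.
cell_rate <- function(beh, cell, L) {
  r <- pmax(0, cell$baseline_rate + cell$speed_slope * beh$speed)
  if (cell$field_gain > 0) {
    novel <- beh$context_id == "novel"
    center <- ifelse(novel, cell$field_center_novel %||% cell$field_center,
                     cell$field_center)
    r <- r * (1 + cell$field_gain *
                von_mises_field(beh$position, center, cell$field_width, L))
  }
  r <- r * ifelse(beh$context_id == "novel", cell$context_gain, 1)
  r[beh$recording_gap] <- 0
  r
}

#' Generate spikes from behavior and ground-truth tuning
#'
#' The per-cell instantaneous rate is
#' `max(0, baseline + slope * speed) * (1 + gain * vonMises(position)) *
#' context_gain(context)`, zero during recording gaps. Spikes are drawn
#' from the resulting inhomogeneous Poisson process by thinning against
#' the peak rate, with the rate held piecewise constant over frames.
#'
#' @param behavior Behavior tibble from [simulate_behavior()].
#' @param truth Ground-truth tibble from [sample_population()].
#' @param cfg A `hippo_config`.
#' @return `truth` with the `spike_times` list-column filled (seconds on
#'   the session clock).
#' @export
simulate_spikes <- function(behavior, truth, cfg = default_config()) {
  dt <- 1 / cfg$fs
  t_end <- max(behavior$t)
  truth$spike_times <- purrr::map(seq_len(nrow(truth)), function(i) {
    r <- cell_rate(behavior, truth[i, ], cfg$track_length)
    rmax <- max(r)
    if (rmax <= 0) return(numeric(0))
    n_cand <- rpois(1, rmax * t_end)
    cand <- sort(runif(n_cand, 0, t_end))
    frame <- pmin(pmax(ceiling(cand / dt), 1L), length(r))
    cand[runif(n_cand) < r[frame] / rmax]
  })
  truth
}

#' Difference-of-exponentials calcium impulse response
#'
#' `k(t) = exp(-t/decay) - exp(-t/rise)` for `t >= 0`, normalized to unit
#' peak. Defaults approximate a GCaMP6f-like indicator.
#'
#' @param t Time since the event, seconds (vectorized).
#' @param rise,decay Time constants in seconds; `decay > rise`.
#' @return Kernel values, unit peak.
#' @export
calcium_kernel <- function(t, rise = 0.1, decay = 0.7) {
  if (decay <= rise) abort("decay must exceed rise")
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  k <- ifelse(t >= 0, exp(-t / decay) - exp(-t / rise), 0)
  k / peak
}

#' Render raw fluorescence from spike trains
#'
#' Forward model: each spike adds a unit-peak calcium kernel scaled by
#' `spike_amp` (dF/F per event); the summed event signal multiplies a
#' slowly drifting photon baseline, and white shot noise is added:
#' `raw = B * (1 + drift) * (1 + amp * sum kernels) + noise`.
#'
#' @param spike_times List of numeric vectors, spike times (s) per cell.
#' @param n_frames Number of frames to render.
#' @param cfg A `hippo_config` carrying the noise-model fields.
#' @return Numeric matrix, frames x cells.
#' @export
render_fluorescence <- function(spike_times, n_frames,
                                cfg = default_config()) {
  if (cfg$fs <= 0) abort("fs must be positive")
  if (cfg$drift_amplitude < 0 || cfg$shot_noise_sd < 0 ||
      cfg$photon_baseline <= 0)
    abort("noise-model parameters must be nonnegative (baseline positive)")
  dt <- 1 / cfg$fs
  klen <- ceiling(8 * cfg$kernel_decay / dt)
  kern <- calcium_kernel((seq_len(klen) - 1) * dt,
                         cfg$kernel_rise, cfg$kernel_decay)
  out <- matrix(0, n_frames, length(spike_times))
  for (j in seq_along(spike_times)) {
    st <- spike_times[[j]]
    counts <- if (length(st) == 0) numeric(n_frames) else
      tabulate(pmin(pmax(ceiling(st / dt), 1L), n_frames), n_frames)
    sig <- convolve_causal(counts, kern)
    drift <- if (cfg$drift_amplitude > 0)
      smooth_drift(n_frames, cfg$drift_timescale, cfg$fs) *
        cfg$drift_amplitude else 0
    noise <- if (cfg$shot_noise_sd > 0)
      rnorm(n_frames, 0, cfg$photon_baseline * cfg$shot_noise_sd) else 0
    out[, j] <- cfg$photon_baseline * (1 + drift) *
      (1 + cfg$spike_amp * sig) + noise
  }
  out
}

convolve_causal <- function(x, k) {
  n <- length(x)
  full <- stats::convolve(x, rev(k), type = "open")
  full[seq_len(n)]
}

# Unit-SD smooth drift: AR(1)-filtered white noise at the drift timescale.
smooth_drift <- function(n, timescale, fs) {
  a <- exp(-1 / (timescale * fs))
  d <- as.numeric(stats::filter(rnorm(n), a, method = "recursive"))
  s <- sd(d)
  if (s > 0) d / s else d
}

#' Simulate a full session with ground truth
#'
#' Runs behavior, population, spike, and fluorescence generation under a
#' single seed and packages the result as a `hippo_session` plus the
#' ground-truth table.
#'
#' @param config Named list of config overrides (see [default_config()]).
#' @param seed Integer seed controlling every random draw.
#' @param meta Optional cell metadata tibble.
#' @return A list of class `hippo_sim` with elements `session` (a
#'   `hippo_session`), `truth` (ground-truth tibble) and `config`.
#' @export
#' @examples
#' sim <- simulate_session(list(n_cells = 4, n_blocks = 2), seed = 1)
#' sim$session
simulate_session <- function(config = list(), seed = 1, meta = NULL) {
  cfg <- load_config(overrides = config)
  set.seed(seed)
  beh <- simulate_behavior(cfg)
  truth <- sample_population(cfg)
  truth <- simulate_spikes(beh, truth, cfg)
  raw_f <- render_fluorescence(truth$spike_times, nrow(beh), cfg)
  colnames(raw_f) <- truth$cell_id
  if (!is.null(meta)) meta$cell_id <- truth$cell_id
  ses <- hippo_session(
    behavior = beh, raw_f = raw_f, meta = meta, fs = cfg$fs,
    track_length = cfg$track_length, circular = cfg$circular,
    provenance = list(seed = seed, config_hash = config_hash(cfg))
  )
  structure(list(session = ses, truth = truth, config = cfg),
            class = "hippo_sim")
}

#' @export
print.hippo_sim <- function(x, ...) {
  cat("<hippo_sim> seed-controlled synthetic session\n")
  print(x$session)
  cat("  ground truth: ", nrow(x$truth), " cells (",
      sum(x$truth$field_gain > 0), " place-coding)\n", sep = "")
  invisible(x)
}
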