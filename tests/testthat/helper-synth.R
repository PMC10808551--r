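# Small fixture builders shared across test files.

# Behavior with constant speed on a circular track: n laps, no gaps.
constant_run <- function(speed = 20, track_length = 400, laps = 2, fs = 10) {
  dt <- 1 / fs
  n <- ceiling(laps * track_length / speed * fs)
  pos <- (seq_len(n) * speed * dt) %% track_length
  tibble::tibble(
    t = seq_len(n) * dt, position = pos, speed = speed,
    context_id = "familiar",
    trial_index = as.integer((seq_len(n) * speed * dt) %/% track_length),
    recording_gap = FALSE
  )
}

# A spatial_map built directly from per-bin values (all bins occupied).
map_from_values <- function(lambda, p = NULL, bin_width = 5,
                            circular = TRUE, mean_activity = NULL) {
  nb <- length(lambda)
  if (is.null(p)) p <- rep(1 / nb, nb)
  structure(
    list(lambda = lambda, p = p, counts = pmax(1L, round(p * 1000)),
         occupied = rep(TRUE, nb),
         lambda_bar = sum(p * pmax(lambda, 0)),
         bin_edges = seq(0, nb * bin_width, by = bin_width),
         n_bins = nb, circular = circular,
         mean_activity = mean_activity %||% sum(p * lambda)),
    class = "spatial_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent literal transcription of the weighted-information formula,
# used as the oracle against the pipeline implementation.
si_oracle <- function(lambda, p) {
  lambda <- pmax(lambda, 0)
  lbar <- sum(p * lambda)
  s <- 0
  for (i in seq_along(lambda)) {
    if (lambda[i] > 0) s <- s + lambda[i] * log2(lambda[i] / lbar) * p[i]
  }
  s
}

# Flat-baseline trace with boxcar events at known frames.
boxcar_trace <- function(n, baseline = 100, events = list(), amp = 20,
                         noise_sd = 0) {
  x <- rep(baseline, n) + rnorm(n, 0, noise_sd)
  for (ev in events) x[ev] <- x[ev] + amp
  x
}
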