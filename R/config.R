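#' Default analysis and simulation configuration
#'
#' Returns the full set of pipeline parameters with their default values.
#' Every entry can be overridden from a YAML config file via [load_config()]
#' or by passing a named list to the simulation and pipeline functions.
#'
#' Key analysis defaults: movement threshold 2 cm/s, 5-cm spatial bins
#' (10-cm bins for population vectors), 1 cm/s speed bins, 1000 circular
#' shuffles with a minimum shift of 10 s, transient false-positive-rate
#' ceiling of 0.05, place-cell rate threshold of 1 transient/min, and a
#' minimum of 5 place cells per condition for population-vector analysis.
#'
#' @return A named list of class `hippo_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$speed_threshold
default_config <- function() {
  cfg <- list(
    # track / acquisition
    track_length   = 400,    # cm
    circular       = TRUE,
    fs             = 10,     # Hz, effective per-plane sampling rate

    # behavior simulation
    block_mode     = "time", # "time": fixed-duration context blocks; "laps"
    block_s        = 60,     # s per context block in time mode
    n_blocks       = 20,     # alternating familiar/novel blocks (~20 min)
    laps_per_block = 15,     # laps per context block in lap mode
    gap_s          = 5,      # blanked teleport interval between blocks
    contexts       = c("familiar", "novel"),
    mean_speed     = 15,     # cm/s target moving speed
    speed_sd       = 5,      # cm/s stationary SD of the speed walk
    speed_tau      = 2,      # s relaxation time of the speed walk
    min_run_speed  = 0.5,    # cm/s floor while in the run state
    pause_rate     = 0.02,   # 1/s hazard of entering a pause
    unpause_rate   = 0.5,    # 1/s hazard of leaving a pause

    # population simulation
    n_cells          = 20,
    frac_speed_pos   = 0.5,
    frac_speed_neg   = 0.2,
    frac_place       = 0.5,
    baseline_rate    = c(2, 6),     # events/s, uniform range
    speed_slope_rel  = c(0.005, 0.03), # |slope| as fraction of baseline per
                                    # cm/s; keeps negatively modulated cells
                                    # above zero at typical running speeds
    field_width      = c(40, 80),   # cm FWHM, uniform range
    field_gain       = c(1, 4),     # dimensionless, uniform range
    context_gain_sdlog = 0.4,       # log-normal multiplier in the novel context
    remap_mode       = "stable",    # "stable": same field centers in both
                                    # contexts; "global": independent centers

    # fluorescence forward model
    kernel_rise     = 0.1,   # s
    kernel_decay    = 0.7,   # s
    spike_amp       = 0.1,   # dF/F peak per event
    drift_amplitude = 0.05,  # fraction of baseline
    drift_timescale = 600,   # s, bleaching-like slow drift
    shot_noise_sd   = 0.02,  # dF/F units
    photon_baseline = 100,   # arbitrary units

    # dF/F
    dff_window_s   = 8,
    dff_percentile = 8,

    # transient detection
    transient_thresholds = c(2, 2.5, 3, 3.5, 4),  # multiples of baseline SD
    transient_durations  = c(0.2, 0.3, 0.5, 1.0), # s
    offset_fraction      = 0.5,  # of onset threshold, event termination
    fpr_max              = 0.05,

    # masks and maps
    speed_threshold   = 2,   # cm/s
    bin_width         = 5,   # cm, tuning metrics
    pv_bin_width      = 10,  # cm, population vectors
    speed_bin_width   = 1,   # cm/s
    min_speed_bin_time = 1,  # s occupancy for a speed bin to enter the fit

    # significance
    n_shuffles    = 1000,
    min_shift_s   = 10,
    alpha         = 0.05,
    place_min_rate = 1,      # transients/min
    min_place_cells = 5,

    # statistics hygiene
    outlier_iqr_k = 3
  )
  class(cfg) <- c("hippo_config", "list")
  cfg
}

#' Load a configuration file
#'
#' Reads a YAML key-value file and merges it over [default_config()].
#' Unknown keys raise an error listing the valid ones.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file.
#' @return A `hippo_config` list with all parameters resolved.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  if (!is.null(overrides)) user <- utils::modifyList(user, as.list(overrides))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown config key(s): ", paste(unknown, collapse = ", "),
      ". Valid keys: ", paste(names(cfg), collapse = ", ")
    ))
  }
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$bin_width <= 0) abort("bin_width must be positive")
  if (cfg$pv_bin_width <= 0) abort("pv_bin_width must be positive")
  if (cfg$track_length <= 0) abort("track_length must be positive")
  if (cfg$fs <= 0) abort("fs must be positive")
  if (cfg$speed_threshold < 0) abort("speed_threshold must be nonnegative")
  if (cfg$n_shuffles < 1) abort("n_shuffles must be >= 1")
  if (cfg$kernel_decay <= cfg$kernel_rise)
    abort("kernel_decay must exceed kernel_rise")
  invisible(cfg)
}

#' @export
print.hippo_config <- function(x, ...) {
  cat("<hippo_config> ", length(x), " parameters\n", sep = "")
  for (k in names(x)) {
    cat("  ", format(k, width = 20), ": ",
        paste(format(x[[k]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Stable hash of a resolved configuration, recorded in session provenance.
config_hash <- function(cfg) {
  rlang::hash(cfg[order(names(cfg))])
}
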