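# Session-level wrappers: preprocess a session, then derive tidy per-cell
# result tables. Every output table carries the session's provenance seed
# and config hash.

# Trial-based halves, or NULL when some context has a single trial (then
# split-half stability is undefined and reported NA).
halves_or_null <- function(beh) {
  tryCatch(split_halves(beh), error = function(e) NULL)
}

add_provenance <- function(df, ses) {
  df$provenance_seed <- ses$provenance$seed
  df$provenance_hash <- ses$provenance$config_hash
  df
}

# Segment id per frame for interneuron normalization: each consecutive
# pair of context blocks (one familiar + one novel run) forms a recording
# segment; gap frames take NA and inherit their neighbors' scaling.
segment_ids <- function(behavior) {
  gap <- behavior$recording_gap
  block <- cumsum(c(TRUE, diff(gap) == -1))  # increments at each block start
  block[gap] <- NA
  (block - 1L) %/% 2L
}

#' Preprocess a session into dF/F (and transients for principal cells)
#'
#' Interneuron mode normalizes each recording segment by its 8th
#' fluorescence percentile and analyzes the continuous trace. Principal
#' mode computes sliding-percentile dF/F, calibrates transient detection
#' per cell to a false-positive ratio below 5%, and masks all
#' non-transient samples to zero.
#'
#' @param ses A `hippo_session`.
#' @param mode `"interneuron"` or `"principal"`.
#' @param cfg A `hippo_config`.
#' @return The session with `traces$dff` (and for principal mode
#'   `traces$masked_dff`, `traces$transient_mask`, `events`,
#'   `transient_params`) filled; `mode` is recorded on the session.
#' @export
preprocess <- function(ses, mode = c("interneuron", "principal"),
                       cfg = default_config()) {
  mode <- match.arg(mode)
  raw <- ses$traces$raw_f
  n <- nrow(raw); nc <- ncol(raw)
  gap <- ses$behavior$recording_gap
  if (mode == "interneuron") {
    seg <- segment_ids(ses$behavior)
    dff <- apply(raw, 2, dff_segment_percentile, segment_id = seg,
                 pct = cfg$dff_percentile)
    dff[gap, ] <- NA
    ses$traces$dff <- dff
  } else {
    dff <- matrix(NA_real_, n, nc, dimnames = dimnames(raw))
    masked <- dff
    tmask <- matrix(FALSE, n, nc, dimnames = dimnames(raw))
    events <- vector("list", nc)
    params <- vector("list", nc)
    for (j in seq_len(nc)) {
      d <- dff_sliding_percentile(raw[, j], ses$traces$fs,
                                  window_s = cfg$dff_window_s,
                                  pct = cfg$dff_percentile, gap = gap)
      p <- calibrate_transient_params(
        d, ses$traces$fs, thresholds = cfg$transient_thresholds,
        durations = cfg$transient_durations,
        offset_frac = cfg$offset_fraction, fpr_max = cfg$fpr_max)
      det <- detect_transients(d, ses$traces$fs, p)
      dff[, j] <- d
      masked[, j] <- det$masked_dff
      tmask[, j] <- det$transient_mask
      ev <- det$events
      if (nrow(ev) > 0) ev$cell_id <- ses$meta$cell_id[j]
      events[[j]] <- ev
      params[[j]] <- p
    }
    ses$traces$dff <- dff
    ses$traces$masked_dff <- masked
    ses$traces$transient_mask <- tmask
    ses$events <- dplyr::bind_rows(events)
    ses$transient_params <- setNames(params, ses$meta$cell_id)
  }
  ses$mode <- mode
  ses
}

# Activity matrix used for spatial analyses: continuous dF/F for INs,
# transient-masked dF/F for principal cells.
analysis_activity <- function(ses) {
  if (is.null(ses$traces$dff))
    abort("run preprocess() before analysis")
  if (identical(ses$mode, "principal")) ses$traces$masked_dff else
    ses$traces$dff
}

#' Per-cell context spatial maps
#'
#' @param ses A preprocessed `hippo_session`.
#' @param bin_width Bin width, cm.
#' @param cfg A `hippo_config`.
#' @return Nested list `maps[[context]][[cell_id]]` of `spatial_map`s.
#' @export
context_maps <- function(ses, bin_width = 5, cfg = default_config()) {
  act <- analysis_activity(ses)
  segs <- segment_contexts(ses$behavior)
  purrr::map(segs, function(idx) {
    mv <- movement_mask(ses$behavior$speed[idx], cfg$speed_threshold)
    setNames(purrr::map(seq_len(ncol(act)), function(j)
      spatial_map(act[idx, j], ses$behavior$position[idx], mv,
                  bin_width = bin_width, track_length = ses$track_length,
                  circular = ses$circular)),
      ses$meta$cell_id)
  })
}

#' Per-cell speed-modulation and spatial-tuning table
#'
#' Computes, for every cell and context: the speed-tuning fit (slope,
#' Pearson r, p, modulation class), the moving/immobile activity ratio,
#' spatial information (raw and activity-normalized), spatial coherence,
#' circular vector tuning, and split-half stability. For principal-mode
#' sessions the movement transient rate is included.
#'
#' @param ses A preprocessed `hippo_session`.
#' @param cfg A `hippo_config`.
#' @return Tibble, one row per cell x context, with provenance columns.
#' @export
tuning_table <- function(ses, cfg = default_config()) {
  act <- analysis_activity(ses)
  beh <- ses$behavior
  segs <- segment_contexts(beh)
  halves <- halves_or_null(beh)
  fs <- ses$traces$fs
  rows <- purrr::imap_dfr(segs, function(idx, ctx) {
    sp <- beh$speed[idx]
    mv <- movement_mask(sp, cfg$speed_threshold)
    im <- immobility_mask(sp, cfg$speed_threshold)
    h1 <- if (is.null(halves)) NULL else halves$half1[idx]
    h2 <- if (is.null(halves)) NULL else halves$half2[idx]
    purrr::map_dfr(seq_len(ncol(act)), function(j) {
      a <- act[idx, j]
      st <- speed_tuning(ses$traces$dff[idx, j], sp,
                         bin_width = cfg$speed_bin_width,
                         min_bin_time = cfg$min_speed_bin_time,
                         fs = fs, alpha = cfg$alpha)
      map5 <- spatial_map(a, beh$position[idx], mv, cfg$bin_width,
                          ses$track_length, ses$circular)
      sinfo <- spatial_information(map5)
      vt <- vector_tuning(map5)
      m1 <- if (is.null(h1)) NULL else
        try_map(a, beh$position[idx], mv & h1, cfg, ses)
      m2 <- if (is.null(h2)) NULL else
        try_map(a, beh$position[idx], mv & h2, cfg, ses)
      stab <- if (is.null(m1) || is.null(m2)) NA_real_ else
        within_session_stability(m1, m2)
      tr <- if (identical(ses$mode, "principal")) {
        ev <- dplyr::filter(ses$events, .data$cell_id ==
                              ses$meta$cell_id[j])
        full_mv <- rep(FALSE, nrow(beh)); full_mv[idx[mv]] <- TRUE
        transient_rate(ev, full_mv, fs)
      } else NA_real_
      tibble::tibble(
        cell_id = ses$meta$cell_id[j], context = ctx,
        slope = st$slope, pearson_r = st$pearson_r, p_value = st$p_value,
        modulation_class = st$modulation_class,
        move_immobile_ratio = move_immobile_ratio(ses$traces$dff[idx, j],
                                                  mv, im),
        si = sinfo$si, si_norm = sinfo$si_norm,
        coherence = spatial_coherence(map5),
        vector_length = vt$vector_length, vector_angle = vt$vector_angle,
        stability = stab, transient_rate = tr
      )
    })
  })
  add_provenance(rows, ses)
}

try_map <- function(a, pos, mask, cfg, ses) {
  if (sum(mask) == 0) return(NULL)
  spatial_map(a, pos, mask, cfg$bin_width, ses$track_length, ses$circular)
}

#' Per-cell circular-shuffle significance table
#'
#' Runs [circular_shuffle_null()] for every cell and context and returns
#' the long table of metrics with their null percentiles. Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param ses A preprocessed `hippo_session`.
#' @param cfg A `hippo_config` (`n_shuffles`, `min_shift_s`).
#' @param metrics Metric subset passed through.
#' @param keep_null Keep the `null_values` list-column (default `FALSE`).
#' @return Tibble: cell x context x metric rows with `true_value`,
#'   `percentile_of_true`, `significant`, provenance columns.
#' @export
significance_table <- function(ses, cfg = default_config(),
                               metrics = c("si", "coherence",
                                           "vector_length", "stability"),
                               keep_null = FALSE) {
  act <- analysis_activity(ses)
  beh <- ses$behavior
  segs <- segment_contexts(beh)
  halves <- halves_or_null(beh)
  rows <- purrr::imap_dfr(segs, function(idx, ctx) {
    mv <- movement_mask(beh$speed[idx], cfg$speed_threshold)
    hv <- if (is.null(halves)) NULL else
      list(half1 = halves$half1[idx], half2 = halves$half2[idx])
    purrr::map_dfr(seq_len(ncol(act)), function(j) {
      out <- circular_shuffle_null(
        act[idx, j], beh$position[idx], mv, ses$traces$fs,
        n_shuffles = cfg$n_shuffles, min_shift_s = cfg$min_shift_s,
        bin_width = cfg$bin_width, track_length = ses$track_length,
        circular = ses$circular, metrics = metrics, halves = hv)
      out$cell_id <- ses$meta$cell_id[j]
      out$context <- ctx
      out
    })
  })
  if (!keep_null) rows$null_values <- NULL
  add_provenance(
    dplyr::relocate(rows, "cell_id", "context"), ses)
}

#' Place-cell table for a principal-cell session
#'
#' Combines shuffle-significant spatial information with the movement
#' transient-rate threshold (default 1 transient/min).
#'
#' @param ses A preprocessed principal-mode session.
#' @param sig Significance table from [significance_table()].
#' @param tun Tuning table from [tuning_table()] (provides rates).
#' @param cfg A `hippo_config`.
#' @return Tibble per cell x context with `is_place_cell`, plus the
#'   per-session fractions as attributes `fraction_place`.
#' @export
place_cell_table <- function(ses, sig, tun, cfg = default_config()) {
  si_sig <- sig |>
    dplyr::filter(.data$metric == "si") |>
    dplyr::select("cell_id", "context", si_significant = "significant")
  rates <- dplyr::select(tun, "cell_id", "context", "transient_rate")
  rec <- dplyr::left_join(si_sig, rates, by = c("cell_id", "context"))
  out <- classify_place_cells(rec, min_rate = cfg$place_min_rate)
  attr(out, "fraction_place") <-
    dplyr::summarise(dplyr::group_by(out, .data$context),
                     fraction = mean(.data$is_place_cell))
  add_provenance(out, ses)
}

#' Between-context remapping table for one session
#'
#' Per-cell familiar-vs-novel field correlations on 5-cm maps (cells that
#' are place cells in at least one context when a place table is given),
#' and the per-bin population-vector correlation on 10-cm z-scored maps.
#' The population-vector analysis requires at least 5 place cells in each
#' condition; ineligible sessions yield `pv = NULL` with a warning.
#'
#' @param ses A preprocessed `hippo_session` with two contexts.
#' @param place Optional place-cell table restricting the cell set.
#' @param cfg A `hippo_config`.
#' @return List: `field` (per-cell tibble), `pv` (per-bin tibble or
#'   `NULL` when the session is ineligible).
#' @export
remap_table <- function(ses, place = NULL, cfg = default_config()) {
  ctxs <- names(segment_contexts(ses$behavior))
  if (length(ctxs) < 2) abort("remapping needs two contexts")
  ca <- ctxs[1]; cb <- ctxs[2]
  maps5 <- context_maps(ses, cfg$bin_width, cfg)
  cells <- ses$meta$cell_id
  if (!is.null(place)) {
    keep <- place |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(any_place = any(.data$is_place_cell)) |>
      dplyr::filter(.data$any_place)
    cells <- intersect(cells, keep$cell_id)
  }
  field <- tibble::tibble(
    cell_id = cells,
    field_corr = vapply(cells, function(id)
      field_correlation(maps5[[ca]][[id]], maps5[[cb]][[id]]), numeric(1))
  )
  # eligibility: at least min_place_cells place cells in each condition
  eligible <- TRUE
  if (!is.null(place)) {
    counts <- place |>
      dplyr::group_by(.data$context) |>
      dplyr::summarise(n_place = sum(.data$is_place_cell))
    eligible <- nrow(counts) >= 2 &&
      all(counts$n_place >= cfg$min_place_cells)
  }
  pv <- if (!eligible) {
    warn(sprintf(
      "session excluded from population vectors: fewer than %d place cells in each condition",
      cfg$min_place_cells))
    NULL
  } else {
    maps10 <- context_maps(ses, cfg$pv_bin_width, cfg)
    population_vector_correlation(maps10[[ca]][cells], maps10[[cb]][cells],
                                  min_cells = cfg$min_place_cells)
  }
  list(field = add_provenance(field, ses), pv = pv)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a session, preprocesses it, and writes every result table
#' (and the session container plus resolved config) under `out_dir`.
#' Identical `config` and `seed` produce bit-identical output files.
#'
#' @param config Named list of config overrides.
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory (created).
#' @param mode `"interneuron"` or `"principal"`.
#' @return Invisibly, a list with the session, truth, and result tables.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir,
                         mode = "interneuron") {
  cfg <- load_config(overrides = config)
  sim <- simulate_session(config, seed = seed)
  ses <- preprocess(sim$session, mode = mode, cfg = cfg)
  tun <- tuning_table(ses, cfg)
  set.seed(seed + 1L)
  sig <- significance_table(ses, cfg)
  place <- if (mode == "principal") place_cell_table(ses, sig, tun, cfg)
           else NULL
  remap <- remap_table(ses, place, cfg)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_session(ses, file.path(out_dir, "session"), overwrite = TRUE)
  readr::write_csv(dplyr::select(sim$truth, -"spike_times"),
                   file.path(out_dir, "truth.csv"))
  readr::write_csv(tun, file.path(out_dir, "tuning.csv"))
  readr::write_csv(sig, file.path(out_dir, "significance.csv"))
  if (!is.null(place))
    readr::write_csv(place, file.path(out_dir, "place_cells.csv"))
  readr::write_csv(remap$field, file.path(out_dir, "remap_field.csv"))
  if (!is.null(remap$pv))
    readr::write_csv(remap$pv, file.path(out_dir, "remap_pv.csv"))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(list(session = ses, truth = sim$truth, tuning = tun,
                 significance = sig, place = place, remap = remap))
}
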