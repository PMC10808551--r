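#' Construct a recording session
#'
#' Bundles time-aligned behavior, the fluorescence trace matrix, and cell
#' metadata for one imaging session. Behavior and traces must share the
#' frame count and timebase; positions live on `[0, track_length)`.
#'
#' @param behavior Tibble with columns `t` (s), `position` (cm),
#'   `speed` (cm/s), `context_id` (character), `trial_index` (integer),
#'   `recording_gap` (logical). One row per frame.
#' @param raw_f Numeric matrix, frames x cells, raw fluorescence.
#' @param meta Tibble with one row per cell: `cell_id`, `animal_id`,
#'   `session_id`, `region`, `cell_class`. Defaults are filled if `NULL`.
#' @param fs Sampling rate in Hz (default 10, the per-plane rate).
#' @param track_length Track length in cm (default 400).
#' @param circular Whether the track wraps (default `TRUE`).
#' @param provenance List with at least `seed` and `config_hash`; carried
#'   into every result table derived from the session.
#' @return An object of class `hippo_session`.
#' @export
hippo_session <- function(behavior, raw_f, meta = NULL, fs = 10,
                          track_length = 400, circular = TRUE,
                          provenance = list(seed = NA_real_,
                                            config_hash = NA_character_)) {
  behavior <- tibble::as_tibble(behavior)
  raw_f <- as.matrix(raw_f)
  if (is.null(meta)) {
    meta <- tibble::tibble(
      cell_id = paste0("cell", seq_len(ncol(raw_f))),
      animal_id = "animal1", session_id = "session1",
      region = "CA1", cell_class = "PV"
    )
  }
  meta <- tibble::as_tibble(meta)
  ses <- structure(
    list(behavior = behavior,
         traces = list(raw_f = raw_f, dff = NULL, masked_dff = NULL,
                       transient_mask = NULL, fs = fs),
         meta = meta,
         track_length = track_length,
         circular = circular,
         provenance = provenance),
    class = "hippo_session"
  )
  validate_session(ses)
  ses
}

#' Validate a session's invariants
#'
#' Checks field presence, equal lengths, frame-count agreement between
#' behavior and traces, position range, nonnegative speed, and absence of
#' NaN in position/speed outside recording gaps.
#'
#' @param ses A `hippo_session`.
#' @return The session, invisibly; errors describe the first violation.
#' @export
validate_session <- function(ses) {
  b <- ses$behavior
  need <- c("t", "position", "speed", "context_id", "trial_index",
            "recording_gap")
  missing <- setdiff(need, names(b))
  if (length(missing) > 0)
    abort(paste0("behavior is missing field(s): ",
                 paste(missing, collapse = ", ")))
  n <- nrow(b)
  if (nrow(ses$traces$raw_f) != n)
    abort(sprintf("frame count mismatch: behavior has %d frames, traces %d",
                  n, nrow(ses$traces$raw_f)))
  if (ncol(ses$traces$raw_f) != nrow(ses$meta))
    abort("meta rows must match trace columns")
  if (anyDuplicated(ses$meta$cell_id) > 0)
    abort("cell_id values must be unique within a session")
  ok <- !b$recording_gap
  if (any(!is.finite(b$position[ok])) || any(!is.finite(b$speed[ok])))
    abort("NaN/Inf in position or speed outside recording gaps")
  if (any(b$speed[ok] < 0)) abort("speed must be nonnegative")
  if (any(b$position[ok] < 0 | b$position[ok] >= ses$track_length))
    abort("position must lie in [0, track_length)")
  if (any(diff(b$t) <= 0)) abort("t must be strictly increasing")
  if (!all(is.finite(ses$traces$raw_f))) abort("raw_f must be finite")
  invisible(ses)
}

#' @export
print.hippo_session <- function(x, ...) {
  b <- x$behavior
  cat("<hippo_session> ", nrow(b), " frames @ ", x$traces$fs, " Hz, ",
      ncol(x$traces$raw_f), " cells\n", sep = "")
  cat("  contexts: ",
      paste(unique(b$context_id[!b$recording_gap]), collapse = ", "), "\n",
      sep = "")
  cat("  track: ", x$track_length, " cm",
      if (x$circular) " (circular)" else " (linear)", "\n", sep = "")
  cat("  dF/F computed: ", !is.null(x$traces$dff), "\n", sep = "")
  invisible(x)
}

n_frames <- function(ses) nrow(ses$behavior)

# 17 significant digits: lossless round-trip for IEEE doubles through text
fmt_double <- function(x) sprintf("%.17g", x)

# ---- container I/O -----------------------------------------------------
# Plain-text directory container: behavior.csv, traces.csv, meta.csv and a
# JSON header with fs/track geometry/provenance. readr serializes doubles
# with the shortest representation that round-trips, so floats survive a
# write/read cycle bitwise.

#' Write a session to a directory container
#'
#' @param ses A valid `hippo_session`.
#' @param path Directory to create. With `overwrite = FALSE` (default) an
#'   existing directory is an error.
#' @param overwrite Replace an existing container.
#' @return `path`, invisibly.
#' @export
write_session <- function(ses, path, overwrite = FALSE) {
  validate_session(ses)
  if (dir.exists(path) && !overwrite)
    abort(paste0("'", path, "' exists; pass overwrite = TRUE to replace it"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  beh <- dplyr::mutate(ses$behavior,
                       dplyr::across(dplyr::where(is.double), fmt_double))
  readr::write_csv(beh, file.path(path, "behavior.csv"))
  traces <- tibble::as_tibble(apply(ses$traces$raw_f, 2, fmt_double),
                              .name_repair = "minimal")
  names(traces) <- ses$meta$cell_id
  readr::write_csv(traces, file.path(path, "traces.csv"))
  readr::write_csv(ses$meta, file.path(path, "meta.csv"))
  header <- list(fs = ses$traces$fs, track_length = ses$track_length,
                 circular = ses$circular, provenance = ses$provenance)
  jsonlite::write_json(header, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session from a directory container
#'
#' @param path Directory written by [write_session()].
#' @return A `hippo_session` whose invariants all hold.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) abort(paste0("no session container at '", path, "'"))
  files <- c("behavior.csv", "traces.csv", "meta.csv", "session.json")
  for (f in files) {
    if (!file.exists(file.path(path, f)))
      abort(paste0("session container is missing '", f, "'"))
  }
  # base R parsing: strtod is correctly rounded, so %.17g text round-trips
  # doubles bit-exactly
  behavior <- tibble::as_tibble(utils::read.csv(
    file.path(path, "behavior.csv"),
    colClasses = c(t = "numeric", position = "numeric", speed = "numeric",
                   context_id = "character", trial_index = "integer",
                   recording_gap = "logical")))
  traces <- tibble::as_tibble(utils::read.csv(
    file.path(path, "traces.csv"), colClasses = "numeric",
    check.names = FALSE))
  meta <- tibble::as_tibble(utils::read.csv(
    file.path(path, "meta.csv"), colClasses = "character"))
  header <- jsonlite::read_json(file.path(path, "session.json"),
                                simplifyVector = TRUE)
  raw_f <- as.matrix(traces)
  colnames(raw_f) <- names(traces)
  prov <- as.list(header$provenance)
  if (!is.null(prov$seed)) prov$seed <- as.numeric(prov$seed)
  hippo_session(
    behavior = behavior, raw_f = raw_f, meta = meta,
    fs = as.numeric(header$fs), track_length = as.numeric(header$track_length),
    circular = header$circular,
    provenance = prov
  )
}
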