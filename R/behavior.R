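#' Movement mask
#'
#' Frames where the animal runs at or above the speed threshold and no
#' recording gap is flagged. The complement (below threshold, non-gap)
#' is the immobility / very-slow-movement mask.
#'
#' @param speed Speed vector, cm/s.
#' @param threshold Minimum speed, cm/s (default 2).
#' @param gap Optional logical recording-gap vector.
#' @return Logical vector, `TRUE` for moving frames.
#' @export
movement_mask <- function(speed, threshold = 2, gap = NULL) {
  m <- speed >= threshold
  m[is.na(m)] <- FALSE
  if (!is.null(gap)) m <- m & !gap
  m
}

#' Immobility mask (complement of movement, excluding gaps)
#' @inheritParams movement_mask
#' @return Logical vector.
#' @export
immobility_mask <- function(speed, threshold = 2, gap = NULL) {
  m <- speed < threshold
  m[is.na(m)] <- FALSE
  if (!is.null(gap)) m <- m & !gap
  m
}

bin_index <- function(position, bin_width, track_length) {
  nb <- ceiling(track_length / bin_width)
  b <- floor(position / bin_width) + 1L
  pmin(pmax(as.integer(b), 1L), nb)  # last bin closes at track_length
}

bin_centers <- function(bin_width, track_length) {
  nb <- ceiling(track_length / bin_width)
  (seq_len(nb) - 0.5) * bin_width
}

#' Occupancy fraction per spatial bin
#'
#' Fraction of masked time spent in each half-open bin `[k*w, (k+1)*w)`;
#' sums to 1 over occupied bins.
#'
#' @param position Position vector, cm in `[0, track_length)`.
#' @param mask Logical frame mask (e.g. [movement_mask()]).
#' @param bin_width Bin width, cm (default 5).
#' @param track_length Track length, cm (default 400).
#' @return Numeric vector of occupancy fractions, one per bin.
#' @export
compute_occupancy <- function(position, mask, bin_width = 5,
                              track_length = 400) {
  if (sum(mask) == 0) abort("mask selects no frames")
  nb <- ceiling(track_length / bin_width)
  counts <- tabulate(bin_index(position[mask], bin_width, track_length), nb)
  counts / sum(counts)
}

#' Spatial activity map
#'
#' Mean activity per spatial bin under a frame mask, with occupancy.
#' The map identity `lambda_bar = sum(p_i * lambda_i)` holds exactly by
#' construction; unoccupied bins are flagged and excluded from metrics
#' that consume the map.
#'
#' @param activity Activity vector aligned to frames (continuous dF/F for
#'   interneurons, transient-masked dF/F for principal cells).
#' @param position Position vector, cm.
#' @param mask Logical frame mask.
#' @param bin_width Bin width, cm (default 5).
#' @param track_length Track length, cm (default 400).
#' @param circular Whether the track wraps (default `TRUE`).
#' @return A `spatial_map`: list with `lambda` (per-bin means), `p`
#'   (occupancy fractions), `counts`, `occupied`, `lambda_bar`,
#'   `bin_edges`, `n_bins`, `circular`, `mean_activity`.
#' @export
spatial_map <- function(activity, position, mask, bin_width = 5,
                        track_length = 400, circular = TRUE) {
  if (sum(mask) == 0) abort("mask selects no frames")
  nb <- ceiling(track_length / bin_width)
  idx <- which(mask & !is.na(activity))
  b <- bin_index(position[idx], bin_width, track_length)
  counts <- tabulate(b, nb)
  sums <- numeric(nb)
  agg <- rowsum(activity[idx], b)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  occupied <- counts > 0
  lambda <- ifelse(occupied, sums / pmax(counts, 1), NA_real_)
  p <- counts / sum(counts)
  structure(
    list(lambda = lambda, p = p, counts = counts, occupied = occupied,
         lambda_bar = sum(p[occupied] * lambda[occupied]),
         bin_edges = seq(0, nb * bin_width, by = bin_width),
         n_bins = nb, circular = circular,
         mean_activity = mean(activity[idx])),
    class = "spatial_map"
  )
}

#' @export
print.spatial_map <- function(x, ...) {
  cat("<spatial_map> ", x$n_bins, " bins (",
      sum(x$occupied), " occupied), mean activity ",
      signif(x$lambda_bar, 3), if (x$circular) ", circular" else "", "\n",
      sep = "")
  invisible(x)
}

#' @rdname spatial_map
#' @param x A `spatial_map`.
#' @param ... Unused.
#' @export
tidy.spatial_map <- function(x, ...) {
  tibble::tibble(
    bin = seq_len(x$n_bins),
    center = (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2,
    lambda = x$lambda, p = x$p, occupied = x$occupied
  )
}

#' Split a session's frames into first and second half by trials
#'
#' Splits per context at the median trial boundary; with an odd trial
#' count the first half gets the extra trial. Gap frames belong to
#' neither half.
#'
#' @param behavior Behavior tibble.
#' @return Logical matrix-like list: `half1`, `half2` frame masks.
#' @export
split_halves <- function(behavior) {
  half1 <- rep(FALSE, nrow(behavior))
  half2 <- rep(FALSE, nrow(behavior))
  for (ctx in unique(behavior$context_id[!behavior$recording_gap])) {
    in_ctx <- behavior$context_id == ctx & !behavior$recording_gap
    trials <- sort(unique(behavior$trial_index[in_ctx]))
    if (length(trials) < 2)
      abort(paste0("context '", ctx, "' has fewer than 2 trials"))
    cut <- ceiling(length(trials) / 2)
    half1 <- half1 | (in_ctx & behavior$trial_index %in% trials[seq_len(cut)])
    half2 <- half2 | (in_ctx & behavior$trial_index %in%
                        trials[(cut + 1):length(trials)])
  }
  list(half1 = half1, half2 = half2)
}

#' Per-context frame segmentation
#'
#' Returns, for each context label, the non-gap frame indices in
#' recording order. All per-context metrics run on these concatenated
#' frames.
#'
#' @param behavior Behavior tibble.
#' @param contexts Optional subset of labels; unknown labels error.
#' @return Named list of integer frame-index vectors.
#' @export
segment_contexts <- function(behavior, contexts = NULL) {
  present <- unique(behavior$context_id[!behavior$recording_gap])
  if (is.null(contexts)) contexts <- present
  unknown <- setdiff(contexts, present)
  if (length(unknown) > 0)
    abort(paste0("unknown context label(s): ", paste(unknown, collapse = ", ")))
  setNames(
    lapply(contexts, function(ctx)
      which(behavior$context_id == ctx & !behavior$recording_gap)),
    contexts
  )
}
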