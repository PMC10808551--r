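#' Plot a spatial activity map
#'
#' Tuning curve of mean activity over track position; unoccupied bins are
#' left blank.
#'
#' @param object A `spatial_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spatial_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, .data$occupied),
                  ggplot2::aes(x = .data$center, y = .data$lambda)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Position (cm)", y = "Mean activity (dF/F)") +
    ggplot2::theme_minimal()
}

#' Plot a speed-tuning curve with its linear fit
#'
#' @param object A `speed_tuning` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.speed_tuning <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$center,
                                        y = .data$mean_dff)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Running speed (cm/s)", y = "Mean dF/F") +
    ggplot2::theme_minimal()
  if (!is.na(object$slope)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  linetype = "dashed", colour = "blue")
  }
  p
}

#' Plot per-bin population-vector correlations
#'
#' @param pv Tibble from [population_vector_correlation()].
#' @return A ggplot.
#' @export
plot_pv_correlation <- function(pv) {
  ggplot2::ggplot(pv, ggplot2::aes(x = .data$center, y = .data$pv_corr)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Position (cm)", y = "Population-vector correlation") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
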