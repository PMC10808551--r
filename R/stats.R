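#' Remove extreme outliers by the 3-IQR rule
#'
#' Drops values deviating from their empirical distribution by more than
#' `k` interquartile ranges (`x > Q3 + k*IQR` or `x < Q1 - k*IQR`). NaN
#' values are dropped first and never counted in `n`. Fences come from
#' the original sample (single pass): with `IQR = 0` the fences collapse
#' to the quartile points and equal values are never removed.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 3).
#' @return List: `values` (kept), `n_before`, `n_after`, `n_removed`.
#' @export
remove_extreme_outliers <- function(values, k = 3) {
  x <- values[!is.na(values)]
  if (length(x) == 0) abort("all values are missing")
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- x >= q[1] - k * iqr & x <= q[2] + k * iqr
  list(values = x[keep], n_before = length(x), n_after = sum(keep),
       n_removed = sum(!keep))
}

# KS normality gate against a Gaussian with the sample's mean and SD.
ks_normal_p <- function(x) {
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
}

#' Normality-gated test selection
#'
#' Applies the Kolmogorov–Smirnov normality test (alpha 0.05, reference
#' Gaussian parameterized by each sample's mean and SD) to every group;
#' when all groups pass, a parametric test is used (paired/unpaired t
#' test for 2 groups, one-way ANOVA for more), otherwise the rank-based
#' counterpart (Wilcoxon signed-rank / rank-sum, Kruskal–Wallis). All
#' tests are two-sided.
#'
#' @param groups List of numeric vectors (NaN dropped per group).
#' @param paired Paired design (2 groups of equal length only).
#' @param alpha Normality gate level (default 0.05).
#' @param remove_outliers Apply [remove_extreme_outliers()] per group
#'   first (default `TRUE`; skipped for paired designs, which operate on
#'   matched values).
#' @param k Outlier fence multiplier.
#' @return One-row tibble: `n_groups`, `n_total`, `n_removed`,
#'   `min_normality_p`, `test_used`, `statistic`, `p_value`.
#' @export
choose_and_run_test <- function(groups, paired = FALSE, alpha = 0.05,
                                remove_outliers = TRUE, k = 3) {
  if (length(groups) < 2) abort("need at least 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, integer(1)) < 3))
    abort("every group needs at least 3 values")
  n_removed <- 0L
  if (remove_outliers && !paired) {
    filt <- lapply(groups, remove_extreme_outliers, k = k)
    n_removed <- sum(vapply(filt, `[[`, integer(1), "n_removed"))
    groups <- lapply(filt, `[[`, "values")
  }
  normal_p <- vapply(groups, ks_normal_p, numeric(1))
  normal <- all(normal_p >= alpha)
  if (paired && length(groups) == 2 &&
      length(groups[[1]]) != length(groups[[2]]))
    abort("paired groups must have equal length")
  if (normal) {
    if (length(groups) == 2) {
      ht <- t.test(groups[[1]], groups[[2]], paired = paired)
      used <- if (paired) "paired t-test" else "t-test"
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      df <- tibble::tibble(
        y = unlist(groups),
        g = factor(rep(seq_along(groups), lengths(groups))))
      fit <- aov(y ~ g, data = df)
      s <- summary(fit)[[1]]
      used <- "one-way ANOVA"
      stat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
    }
  } else {
    if (length(groups) == 2) {
      ht <- suppressWarnings(
        wilcox.test(groups[[1]], groups[[2]], paired = paired, exact = FALSE))
      used <- if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum"
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- kruskal.test(groups)
      used <- "Kruskal-Wallis"
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  }
  tibble::tibble(
    n_groups = length(groups), n_total = sum(lengths(groups)),
    n_removed = n_removed, min_normality_p = min(normal_p),
    test_used = used, statistic = stat, p_value = p
  )
}

#' Aggregate per-cell values to session or animal level
#'
#' Averages a per-cell variable within sessions or animals so that
#' groups, not cells, become the unit of downstream tests.
#'
#' @param df Tibble with a value column plus linkage columns.
#' @param value Name of the value column.
#' @param level `"cell"`, `"session"`, or `"animal"`.
#' @param session_col,animal_col Linkage column names.
#' @return Tibble with one row per unit: the grouping key, `value`
#'   (group mean), `n_cells`.
#' @export
aggregate_by <- function(df, value, level = c("cell", "session", "animal"),
                         session_col = "session_id",
                         animal_col = "animal_id") {
  level <- match.arg(level)
  if (!value %in% names(df)) abort(paste0("no column '", value, "'"))
  if (level == "cell") {
    return(dplyr::transmute(df, unit = .data$cell_id,
                            value = .data[[value]], n_cells = 1L))
  }
  key <- if (level == "session") session_col else animal_col
  if (!key %in% names(df))
    abort(paste0("missing linkage column '", key, "'"))
  df |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(unit = .data[[key]]) |>
    dplyr::summarise(value = mean(.data[[value]]), n_cells = dplyr::n(),
                     .groups = "drop")
}
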