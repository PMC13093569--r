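#' Two-group comparison with Student's t test and box summaries
#'
#' Compares one feature between two groups with an unpaired two-tailed
#' Student's t test (pooled variance by default, matching the classical
#' "Student's" naming; set `var_equal = FALSE` for the Welch variant, which
#' is the safer default when group variances may differ). Alongside the test
#' it reports the reporting conventions of contractility studies: mean and
#' SEM per group, and the box summary (median, 25th/75th percentiles,
#' minimum, maximum).
#'
#' Degenerate input — zero variance in both groups with equal means — yields
#' `t = 0`, `p = 1` by convention, flagged in the result.
#'
#' @param data Data frame with one row per sample (ROI or tissue).
#' @param value Column holding the feature values (unquoted name).
#' @param group Column holding the group labels (unquoted name); must have
#'   exactly two levels, each with n >= 2.
#' @param var_equal Pooled-variance Student's t (`TRUE`, default) or Welch.
#' @param conf_level Confidence level of the difference CI.
#' @return An object of class `group_comparison`; see [tidy.group_comparison()]
#'   and [glance.group_comparison()] for tabular views.
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 11, 12, 13))
#' glance(compare_groups(d, y, g))
#' @export
compare_groups <- function(data, value, group, var_equal = TRUE,
                           conf_level = 0.95) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  g <- as.character(rlang::eval_tidy(group, data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  lv <- unique(g)
  if (length(lv) != 2) abort("`group` must have exactly two levels")
  a <- v[g == lv[1]]; b <- v[g == lv[2]]
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2")

  box <- function(x, label) tibble::tibble(
    group = label, n = length(x), mean = mean(x), sd = sd(x),
    sem = sd(x) / sqrt(length(x)), median = median(x),
    q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75)),
    min = min(x), max = max(x))
  groups <- dplyr::bind_rows(box(a, lv[1]), box(b, lv[2]))

  degenerate <- var(a) == 0 && var(b) == 0
  if (degenerate && mean(a) == mean(b)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(v) - 2),
               p.value = 1, conf.int = c(0, 0), estimate = c(0, 0))
  } else if (degenerate) {
    tt <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
               parameter = c(df = length(v) - 2), p.value = 0,
               conf.int = rep(mean(a) - mean(b), 2),
               estimate = c(mean(a), mean(b)))
  } else {
    tt <- t.test(a, b, var.equal = var_equal, conf.level = conf_level)
  }
  structure(
    list(
      groups = groups,
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      estimate = mean(a) - mean(b),
      conf_int = as.numeric(tt$conf.int),
      conf_level = conf_level,
      method = if (var_equal) "Student (pooled)" else "Welch",
      degenerate = degenerate,
      data = tibble::tibble(group = g, value = v)
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s t test\n", x$method))
  for (i in 1:2) {
    gr <- x$groups[i, ]
    cat(sprintf("  %-10s n = %d, mean %.4g +/- %.3g (SEM)\n",
                gr$group, gr$n, gr$mean, gr$sem))
  }
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g %s%s\n",
              x$t_statistic, x$df, x$p_value, significance_stars(x$p_value),
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Tabular views of a two-group comparison
#'
#' `tidy()` returns the per-group summary (one row per group: n, mean, SEM,
#' and the box summary); `glance()` returns the one-row test result.
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  x$groups
}

#' @rdname tidy.group_comparison
#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    t_statistic = x$t_statistic,
    df = x$df,
    p_value = x$p_value,
    conf_low = x$conf_int[1],
    conf_high = x$conf_int[2],
    method = x$method,
    degenerate = x$degenerate
  )
}

#' Compare several features between two groups
#'
#' Runs [compare_groups()] for each feature column and returns the glance
#' rows, optionally with multiplicity-adjusted p values (`p_adjust`,
#' default `"none"` — per-feature tests are reported unadjusted by
#' convention; `"holm"` is available).
#'
#' @param data Data frame.
#' @param features Character vector of feature column names.
#' @param group Group column name (string).
#' @param p_adjust Method passed to [stats::p.adjust()].
#' @inheritParams compare_groups
#' @return Tibble with one row per feature.
#' @export
compare_features <- function(data, features, group, var_equal = TRUE,
                             p_adjust = "none") {
  stopifnot(is.character(features), length(features) >= 1)
  rows <- purrr::map(features, function(f) {
    cmp <- compare_groups(data, !!rlang::sym(f), !!rlang::sym(group),
                          var_equal = var_equal)
    dplyr::mutate(glance(cmp), feature = f, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Per-group summary of a tidy feature table
#'
#' Mean +/- SEM and box summaries (median, quartiles, min, max) for every
#' feature, per group — the plot-ready table behind box-and-whisker panels.
#'
#' @param data Data frame with a grouping column and feature columns.
#' @param features Character vector of feature columns; defaults to all
#'   numeric columns except the grouping column.
#' @param group Grouping column name (string).
#' @return Tibble with one row per feature x group. Empty or all-NA feature
#'   columns are omitted with a warning.
#' @export
summarize_groups <- function(data, features = NULL, group = "group") {
  if (!group %in% names(data)) {
    abort(sprintf("unknown grouping column `%s`", group))
  }
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], group)
  }
  ok <- vapply(features, function(f) any(is.finite(data[[f]])), TRUE)
  if (any(!ok)) {
    warn(sprintf("feature(s) with no finite values omitted: %s",
                 paste(features[!ok], collapse = ", ")))
    features <- features[ok]
  }
  rows <- purrr::map(features, function(f) {
    data %>%
      dplyr::group_by(.data[[group]]) %>%
      dplyr::summarise(
        n = sum(is.finite(.data[[f]])),
        mean = mean(.data[[f]], na.rm = TRUE),
        sem = sd(.data[[f]], na.rm = TRUE) / sqrt(sum(is.finite(.data[[f]]))),
        median = median(.data[[f]], na.rm = TRUE),
        q25 = quantile(.data[[f]], 0.25, na.rm = TRUE),
        q75 = quantile(.data[[f]], 0.75, na.rm = TRUE),
        min = min(.data[[f]], na.rm = TRUE),
        max = max(.data[[f]], na.rm = TRUE),
        .groups = "drop"
      ) %>%
      dplyr::mutate(feature = f, .before = 1) %>%
      dplyr::rename(group = !!rlang::sym(group))
  })
  dplyr::bind_rows(rows)
}

# cosmetic significance stars (numeric p values are always reported)
significance_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
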