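#' Group summaries: n, mean, SEM
#'
#' Summarises one metric of a per-slice table into mean +/- SEM per group,
#' the form used for bar plots. Invalid measurements (`NA` markers from
#' the validity thresholds) are excluded listwise and counted.
#'
#' @param data Per-slice data frame (e.g. an efficacy table).
#' @param metric Column to summarise (tidy-eval).
#' @param ... Grouping columns (tidy-eval), e.g. `group, frequency_hz`.
#' @return Tibble with grouping columns, `n` (valid rows), `n_invalid`,
#'   `mean` and `sem` (`sd/sqrt(n)`; 0 when n = 1 by convention).
#' @export
#' @examples
#' df <- tibble::tibble(g = c("a", "a", "a"), v = c(1, 2, 3))
#' summarize_groups(df, v, g)  # mean 2, sem 0.577
summarize_groups <- function(data, metric, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = sum(is.finite({{ metric }})),
      n_invalid = sum(!is.finite({{ metric }})),
      mean = mean({{ metric }}[is.finite({{ metric }})]),
      sem = {
        v <- {{ metric }}[is.finite({{ metric }})]
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
      },
      .groups = "drop"
    )
}

#' One-way fixed-effects ANOVA
#'
#' Classical between/within mean-square F test across k groups, the
#' omnibus test applied before any pairwise comparison.
#'
#' @param data Data frame with a value column and a group column.
#' @param value Value column (tidy-eval).
#' @param group Group column (tidy-eval).
#' @return Object of class `anova_1way` with `f`, `df_between` (k - 1),
#'   `df_within` (N - k) and `p`. With zero within-group variance and
#'   unequal means the p value underflows to 0 (documented limit).
#' @export
one_way_anova <- function(data, value, group) {
  df <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = factor(dplyr::pull(data, {{ group }}))
  )
  df <- df[is.finite(df$value), ]
  sizes <- table(df$group)
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L)) stop("every group needs at least two values", call. = FALSE)
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  structure(
    list(
      f = s[["F value"]][1],
      df_between = s[["Df"]][1],
      df_within = s[["Df"]][2],
      p = s[["Pr(>F)"]][1],
      fit = fit
    ),
    class = "anova_1way"
  )
}

#' @export
print.anova_1way <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g %s\n",
              x$df_between, x$df_within, x$f, x$p, stars(x$p)))
  invisible(x)
}

#' @rdname one_way_anova
#' @param x An `anova_1way` object.
#' @param ... Unused.
#' @export
glance.anova_1way <- function(x, ...) {
  tibble::tibble(f = x$f, df_between = x$df_between,
                 df_within = x$df_within, p = x$p, stars = stars(x$p))
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons using the studentized-range distribution
#' with the pooled within-group variance; unequal group sizes use the
#' Tukey-Kramer form.
#'
#' @inheritParams one_way_anova
#' @return Tibble with `pair`, `diff` (mean difference), `lwr`, `upr`
#'   (95% family-wise interval), `p_adj` and `stars`.
#' @export
tukey_hsd <- function(data, value, group) {
  a <- one_way_anova(data, {{ value }}, {{ group }})
  tk <- stats::TukeyHSD(a$fit)$group
  tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    stars = stars(tk[, "p adj"])
  )
}

#' Significance stars
#'
#' Inclusive threshold mapping at the four conventional levels:
#' `p <= 0.0001` four stars, `<= 0.001` three, `<= 0.01` two, `<= 0.05`
#' one, otherwise `"n.s."`.
#'
#' @param p Probability (vectorised), each in `[0, 1]`.
#' @return Character vector of star strings.
#' @export
#' @examples
#' stars(c(0.004, 0.3, 0.0001))  # "**" "n.s." "****"
stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  dplyr::case_when(
    p <= 0.0001 ~ "****",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Group-average trace with SEM band
#'
#' Pointwise mean and SEM across stimulus-aligned traces — the
#' group-average waveform display where a coloured trace carries the mean
#' and its thickness the standard error.
#'
#' @param traces List of aligned [gevi_trace()] of equal length and
#'   sampling interval.
#' @return Tibble with `time_ms`, `mean`, `sem`, `n`.
#' @export
group_average_trace <- function(traces) {
  if (!length(traces)) stop("no traces", call. = FALSE)
  lens <- vapply(traces, length, 0L)
  dts <- vapply(traces, function(tr) tr$sampling_interval_ms, 0)
  if (length(unique(lens)) != 1L || length(unique(dts)) != 1L) {
    stop("traces must share length and sampling interval", call. = FALSE)
  }
  m <- vapply(traces, function(tr) tr$samples, numeric(lens[1]))
  n <- length(traces)
  mu <- rowMeans(m)
  sem <- if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else rep(0, lens[1])
  tibble::tibble(
    time_ms = (seq_len(lens[1]) - 1) * dts[1],
    mean = mu, sem = sem, n = n
  )
}

#' Plot group mean +/- SEM bars
#'
#' @param summary A [summarize_groups()] tibble.
#' @param x Column for the x axis (tidy-eval).
#' @param fill Optional column mapped to fill (tidy-eval).
#' @return A ggplot object.
#' @export
plot_group_bars <- function(summary, x, fill = NULL) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes({{ x }}, .data$mean, fill = {{ fill }})) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::labs(y = "Mean ± SEM") +
    ggplot2::theme_minimal()
  p
}

#' AD-vs-CTRL comparisons of one metric, per frequency family
#'
#' For each stimulation frequency, runs the omnibus one-way ANOVA over
#' the group x frequency cells of one metric and extracts the Tukey HSD
#' comparison between the two condition labels within that frequency.
#'
#' @param table Per-slice table with columns `group`, `frequency_hz` and
#'   the metric.
#' @param metric Metric column (tidy-eval).
#' @param family `"per_direction"` (one 6-cell ANOVA per metric across
#'   all group x frequency cells, the per-panel family of the propagation
#'   figures) or `"per_frequency"` (one 2-group ANOVA per frequency).
#' @return Tibble with one row per frequency: ANOVA F/p for the family
#'   plus the within-frequency AD-vs-CTRL Tukey-adjusted p and stars.
#' @export
compare_conditions <- function(table, metric,
                               family = c("per_direction", "per_frequency")) {
  family <- match.arg(family)
  df <- tibble::tibble(
    value = dplyr::pull(table, {{ metric }}),
    group = as.character(table[["group"]]),
    frequency_hz = table[["frequency_hz"]]
  )
  df <- df[is.finite(df$value), ]
  freqs <- sort(unique(df$frequency_hz))
  if (family == "per_direction") {
    df$cell <- paste0(df$group, "@", df$frequency_hz)
    a <- one_way_anova(df, value, cell)
    tk <- tukey_hsd(df, value, cell)
    purrr::map_dfr(freqs, function(f) {
      labs <- paste0(sort(unique(df$group)), "@", f)
      want <- paste(labs[2], labs[1], sep = "-")
      hit <- tk[tk$pair %in% c(want, paste(labs[1], labs[2], sep = "-")), ]
      tibble::tibble(
        frequency_hz = f, anova_f = a$f, anova_p = a$p,
        pair = hit$pair[1], diff = hit$diff[1],
        p_adj = hit$p_adj[1], stars = hit$stars[1]
      )
    })
  } else {
    purrr::map_dfr(freqs, function(f) {
      sub <- df[df$frequency_hz == f, ]
      a <- one_way_anova(sub, value, group)
      tk <- tukey_hsd(sub, value, group)
      tibble::tibble(
        frequency_hz = f, anova_f = a$f, anova_p = a$p,
        pair = tk$pair[1], diff = tk$diff[1],
        p_adj = tk$p_adj[1], stars = tk$stars[1]
      )
    })
  }
}
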