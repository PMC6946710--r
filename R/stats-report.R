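#' Group summaries (mean +/- sem)
#'
#' @param values Numeric vector of per-cell measurements.
#' @param groups Factor or character vector of group labels.
#' @return A data frame with one row per group: `label`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(label = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference `|mean_a - mean_b| / s_p`, where `s_p` is the
#' pooled standard deviation
#' `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' `denominator = "variance"` divides by the pooled variance `s_p^2` instead
#' of `s_p`; this non-standard form is provided for compatibility with
#' analyses that normalized by the variance.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param denominator `"sd"` (standard, default) or `"variance"`.
#' @return Cohen's d (non-negative).
#' @export
cohens_d <- function(group_a, group_b, denominator = c("sd", "variance")) {
  denominator <- match.arg(denominator)
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0)
    stop("undefined effect size: zero pooled variance", call. = FALSE)
  num <- abs(mean(group_a) - mean(group_b))
  num / if (denominator == "sd") sqrt(sp2) else sp2
}

#' Welch two-sample t-test (two-tailed, unequal variances)
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param label_a,label_b Group labels for the report row.
#' @return A one-row data frame: `test`, `group_a`, `group_b`, `statistic`,
#'   `df`, `p_value`, `effect_size_d`.
#' @export
welch_t <- function(group_a, group_b, label_a = "a", label_b = "b") {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(data.frame(test = "welch_t", group_a = label_a,
                        group_b = label_b, statistic = 0, df = NA_real_,
                        p_value = 1,
                        effect_size_d = NA_real_))
    }
    stop("degenerate variances in both groups", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  data.frame(test = "welch_t", group_a = label_a, group_b = label_b,
             statistic = unname(ht$statistic), df = unname(ht$parameter),
             p_value = ht$p.value,
             effect_size_d = cohens_d(group_a, group_b))
}

#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' One-way ANOVA across three or more groups; when groups differ, pairwise
#' Tukey honest significant differences with the Tukey-Kramer unequal-n
#' correction identify which. Studentized-range quantiles are computed
#' numerically (`ptukey`), not read from tables.
#'
#' @param values Numeric vector of measurements.
#' @param groups Factor or character vector of group labels (>= 3 levels,
#'   each with n >= 2).
#' @param alpha Significance level for flagging pairs (default 0.05).
#' @return A list with `anova` (one row: `f`, `df1`, `df2`, `p_value`) and
#'   `tukey` (one row per pair: `pair`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 3L)
    stop("fewer than 3 groups; use welch_t() for a two-group comparison",
         call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha)
  rownames(tukey) <- NULL
  list(anova = data.frame(f = an[1L, "F value"], df1 = an[1L, "Df"],
                          df2 = an[2L, "Df"],
                          p_value = an[1L, "Pr(>F)"]),
       tukey = tukey)
}

#' Plot an anisotropy trace with its fitted line
#'
#' Anisotropy against the fraction of fluorophore photoswitched, with the
#' retained points, the fitted line, and the extrapolated `r_et1` / `r_et0`
#' endpoints annotated.
#'
#' @param result A `psafret_result` from [analyze_trace()].
#' @return A ggplot object.
#' @export
plot_switching_trace <- function(result) {
  stopifnot(inherits(result, "psafret_result"))
  a <- result$aniso
  line_df <- data.frame(fraction_switched = c(0, 1),
                        r = c(result$r_et1, result$r_et0))
  ggplot2::ggplot(a, ggplot2::aes(x = fraction_switched, y = r)) +
    ggplot2::geom_point(ggplot2::aes(shape = used), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "used in fit") +
    ggplot2::geom_line(data = line_df, linetype = 2, colour = "grey40") +
    ggplot2::annotate("point", x = c(0, 1),
                      y = c(result$r_et1, result$r_et0), colour = "red") +
    ggplot2::annotate("text", x = c(0, 1),
                      y = c(result$r_et1, result$r_et0),
                      label = c(sprintf("r[et1]==%.3f", result$r_et1),
                                sprintf("r[et0]==%.3f", result$r_et0)),
                      parse = TRUE, hjust = c(-0.1, 1.1), vjust = -1) +
    ggplot2::labs(x = "fraction photoswitched F(t)", y = "anisotropy r",
                  title = sprintf("delta r = %.4f, drFRET = %.4f",
                                  result$delta_r, result$drfret)) +
    ggplot2::theme_classic()
}

#' Bar chart of delta r / drFRET by group with per-cell points
#'
#' @param results Data frame of per-cell results (rows from
#'   [as.data.frame.psafret_result()]) with a `group` column.
#' @param value Which column to plot (`"drfret"` or `"delta_r"`).
#' @return A ggplot object.
#' @export
plot_group_effects <- function(results, value = c("drfret", "delta_r")) {
  value <- match.arg(value)
  if (nrow(results) == 0L) stop("empty report: no results", call. = FALSE)
  stopifnot("group" %in% names(results))
  summ <- group_summary(results[[value]], results$group)
  ggplot2::ggplot(summ, ggplot2::aes(x = label, y = mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                        ymax = mean + sem),
                           width = 0.2) +
    ggplot2::geom_jitter(data = data.frame(label = results$group,
                                           y = results[[value]]),
                         ggplot2::aes(x = label, y = y),
                         width = 0.1, shape = 1, inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = value,
                  title = "mean ± sem with individual cells") +
    ggplot2::theme_classic()
}

#' Write a mean +/- sem summary table and figures for a set of results
#'
#' @param results Data frame of per-cell results with a `group` column.
#' @param dir Output directory.
#' @param basename Stem for output files.
#' @return Invisibly, the list of written paths.
#' @export
report_results <- function(results, dir, basename = "psafret_report") {
  if (nrow(results) == 0L) stop("empty report: no results", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(summary = file.path(dir, paste0(basename, "_summary.csv")),
                drfret = file.path(dir, paste0(basename, "_drfret.png")),
                delta_r = file.path(dir, paste0(basename, "_delta_r.png")))
  summ <- rbind(cbind(metric = "delta_r",
                      group_summary(results$delta_r, results$group)),
                cbind(metric = "drfret",
                      group_summary(results$drfret, results$group)))
  utils::write.csv(summ, paths$summary, row.names = FALSE)
  ggplot2::ggsave(paths$drfret, plot_group_effects(results, "drfret"),
                  width = 5, height = 4, dpi = 150)
  ggplot2::ggsave(paths$delta_r, plot_group_effects(results, "delta_r"),
                  width = 5, height = 4, dpi = 150)
  invisible(paths)
}
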