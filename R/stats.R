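# Inferential statistics reproducing the validation analyses: a one-way
# ANOVA with Tukey HSD across the E1/E2/E3 epoch groups, and a Welch
# two-sample t test plus variance-ratio F test for the W1/W2 second groups.
# Model fitting goes through stats::aov / TukeyHSD / t.test / var.test.

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fits `value ~ group` by one-way ANOVA and computes Tukey honest
#' significant difference adjusted pairwise comparisons. Used for the
#' epoch-based analysis across groups E1/E2/E3 (epochs with 0, 1, >= 2
#' phasic events).
#'
#' @param data A data frame; rows with missing values are dropped.
#' @param value Numeric outcome column (tidy-eval).
#' @param group Grouping column (tidy-eval); at least two groups, each with
#'   at least two observations.
#' @return An object of class `hflf_anova` with [tidy()] (pairwise table)
#'   and [glance()] (omnibus F, degrees of freedom, p) methods.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 10), v = rnorm(30))
#' fit <- anova_tukey(df, v, g)
#' glance(fit)
#' tidy(fit)
anova_tukey <- function(data, value, group) {
  df <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = factor(dplyr::pull(data, {{ group }}))
  )
  df <- df[!is.na(df$value) & !is.na(df$group), , drop = FALSE]
  df$group <- droplevels(df$group)
  sizes <- table(df$group)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    abort("ANOVA needs >= 2 groups with >= 2 observations each.",
          class = "hflf_error_bad_groups")
  }
  fit <- aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  structure(
    list(
      f_statistic = tab[["F value"]][1],
      df_between = tab[["Df"]][1],
      df_within = tab[["Df"]][2],
      p_value = tab[["Pr(>F)"]][1],
      pairwise = tibble::tibble(
        group_i = vapply(pairs, `[`, character(1), 1L),
        group_j = vapply(pairs, `[`, character(1), 2L),
        mean_diff = unname(tk[, "diff"]),
        conf_low = unname(tk[, "lwr"]),
        conf_high = unname(tk[, "upr"]),
        adjusted_p = unname(tk[, "p adj"])
      ),
      group_sizes = as.list(sizes),
      fit = fit
    ),
    class = "hflf_anova"
  )
}

#' @export
print.hflf_anova <- function(x, ...) {
  cat(sprintf("<hflf_anova> F(%.0f, %.0f) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @rdname anova_tukey
#' @param x An `hflf_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hflf_anova <- function(x, ...) x$pairwise

#' @rdname anova_tukey
#' @exportS3Method generics::glance
glance.hflf_anova <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value)
}

#' Welch t test and variance-ratio F test for two sample groups
#'
#' Runs the window-based comparison between the event group (numerator,
#' e.g. W2) and the baseline group (denominator, e.g. W1): a two-tailed
#' unpaired Welch t test (unequal variances, Welch-Satterthwaite degrees of
#' freedom; a pooled-variance test is available via `var_equal = TRUE`) and
#' an F test of equality of variances with
#' `F = var(numerator) / var(denominator)`, `dfn = n_num - 1`,
#' `dfd = n_den - 1`.
#'
#' @param data A data frame; rows with missing values are dropped.
#' @param value Numeric outcome column (tidy-eval).
#' @param group Grouping column with exactly two levels (tidy-eval).
#' @param numerator Level to place in the numerator of the F ratio and as
#'   the first t-test sample; defaults to the last factor level (so the
#'   default `W1`/`W2` ordering puts the event group W2 on top).
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return An object of class `hflf_two_sample` with [tidy()] and
#'   [glance()] methods.
#' @export
two_sample_tests <- function(data, value, group, numerator = NULL,
                             var_equal = FALSE) {
  df <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = factor(dplyr::pull(data, {{ group }}))
  )
  df <- df[!is.na(df$value) & !is.na(df$group), , drop = FALSE]
  df$group <- droplevels(df$group)
  lv <- levels(df$group)
  if (length(lv) != 2L) {
    abort("`group` must have exactly two levels with data.",
          class = "hflf_error_bad_groups")
  }
  numerator <- numerator %||% lv[length(lv)]
  if (!numerator %in% lv) {
    abort(paste0("Unknown numerator level: ", numerator),
          class = "hflf_error_bad_groups")
  }
  a <- df$value[df$group == numerator]
  b <- df$value[df$group != numerator]
  if (length(a) < 2L || length(b) < 2L) {
    abort("Both groups need at least two observations.",
          class = "hflf_error_bad_groups")
  }
  tt <- t.test(a, b, var.equal = var_equal)
  ft <- var.test(a, b)
  structure(
    list(
      group_a = numerator, group_b = setdiff(lv, numerator),
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      t_statistic = unname(tt$statistic),
      t_df = unname(tt$parameter),
      t_p = tt$p.value,
      f_variance_ratio = unname(ft$statistic),
      f_dfn = unname(ft$parameter["num df"]),
      f_dfd = unname(ft$parameter["denom df"]),
      f_p = ft$p.value,
      var_equal = var_equal
    ),
    class = "hflf_two_sample"
  )
}

#' @export
print.hflf_two_sample <- function(x, ...) {
  cat(sprintf(
    "<hflf_two_sample> %s vs %s\n  %s t = %.4g, df = %.1f, p = %.3g\n  variance F = %.4g (dfn %.0f, dfd %.0f), p = %.3g\n",
    x$group_a, x$group_b, if (x$var_equal) "pooled" else "Welch",
    x$t_statistic, x$t_df, x$t_p, x$f_variance_ratio, x$f_dfn, x$f_dfd,
    x$f_p))
  invisible(x)
}

#' @rdname two_sample_tests
#' @param x An `hflf_two_sample` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hflf_two_sample <- function(x, ...) {
  tibble::tibble(
    test = c(if (x$var_equal) "pooled t" else "Welch t", "variance F"),
    statistic = c(x$t_statistic, x$f_variance_ratio),
    df1 = c(x$t_df, x$f_dfn),
    df2 = c(NA_real_, x$f_dfd),
    p_value = c(x$t_p, x$f_p)
  )
}

#' @rdname two_sample_tests
#' @exportS3Method generics::glance
glance.hflf_two_sample <- function(x, ...) {
  tibble::tibble(
    n_a = x$n_a, n_b = x$n_b, mean_a = x$mean_a, mean_b = x$mean_b,
    t_statistic = x$t_statistic, t_df = x$t_df, t_p = x$t_p,
    f_variance_ratio = x$f_variance_ratio, f_dfn = x$f_dfn,
    f_dfd = x$f_dfd, f_p = x$f_p
  )
}
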