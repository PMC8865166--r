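# broom-style tidy()/glance() methods for the fitted statistics objects

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return One row per effect with sums of squares, F, uncorrected and
#'   Greenhouse-Geisser-corrected p values, Mauchly statistics and partial
#'   eta squared.
#' @export
tidy.rm_anova <- function(x, ...) {
  x$table
}

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  inter <- x$table[x$table$effect == "interaction", ]
  tibble(n = x$n, k = x$k, alpha = x$alpha,
         interaction_F = inter$statistic,
         interaction_p = inter$p_reported,
         interaction_eta_sq = inter$partial_eta_sq)
}

#' Tidy polynomial trend contrasts
#'
#' @param x A `trend_contrast` object.
#' @param ... Unused.
#' @return One row per polynomial order with the mean contrast score, t,
#'   df and p value.
#' @export
tidy.trend_contrast <- function(x, ...) {
  x$table
}

#' @rdname tidy.trend_contrast
#' @export
glance.trend_contrast <- function(x, ...) {
  quad <- x$table[x$table$order == "quadratic", ]
  tibble(n = x$n, k = x$k,
         quadratic_t = if (nrow(quad)) quad$statistic else NA_real_,
         quadratic_p = if (nrow(quad)) quad$p_value else NA_real_)
}

#' Tidy a paired AUC comparison
#'
#' @param x A `paired_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble with the paired-test summary.
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble(n = x$n, mean_exp = x$mean_exp, sd_exp = x$sd_exp,
         mean_ctrl = x$mean_ctrl, sd_ctrl = x$sd_ctrl,
         mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         statistic = x$statistic, df = x$df,
         p_value = x$p_value, cohens_d = x$cohens_d)
}

#' @rdname tidy.paired_comparison
#' @export
glance.paired_comparison <- function(x, ...) {
  tibble(n = x$n, statistic = x$statistic, p_value = x$p_value,
         cohens_d = x$cohens_d)
}
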