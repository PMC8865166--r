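# Within-subject inferential machinery: 2 x k repeated-measures ANOVA with
# Mauchly sphericity test and Greenhouse-Geisser correction, Bonferroni
# post hocs, orthogonal polynomial trend contrasts, and paired comparisons
# with Cohen's d. All implemented from first principles; independent
# oracles (explicit-sum decompositions, aov(), mauchly.test()) back them in
# the test suite.

# orthonormal basis of contrasts (columns orthogonal to the unit vector)
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

# Greenhouse-Geisser epsilon and Mauchly's test from the n x k matrix of
# per-subject scores for one within-subject effect
sphericity_stats <- function(D) {
  n <- nrow(D)
  k <- ncol(D)
  if (k < 2) return(list(epsilon = 1, W = NA_real_, p = NA_real_))
  if (k == 2) return(list(epsilon = 1, W = 1, p = NA_real_))
  M <- orthonormal_contrasts(k)
  S <- cov(D)
  SM <- t(M) %*% S %*% M
  p <- k - 1
  tr <- sum(diag(SM))
  eps <- tr^2 / (p * sum(SM^2))
  eps <- clamp(eps, 1 / p, 1)
  detSM <- det(SM)
  if (!is.finite(detSM) || detSM <= 0 || n - 1 < p) {
    return(list(epsilon = eps, W = NA_real_, p = NA_real_))
  }
  W <- detSM / (tr / p)^p
  # Box's chi-square approximation with the second-order correction term
  nd <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nd)
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p + 2) /
    (288 * (nd * p * rho)^2)
  chi2 <- -nd * rho * log(W)
  df <- p * (p + 1) / 2 - 1
  pr1 <- stats::pchisq(chi2, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(chi2, df + 4, lower.tail = FALSE)
  list(epsilon = eps, W = W, p = pr1 + w2 * (pr2 - pr1))
}

#' Two-way (2 x k) repeated-measures ANOVA
#'
#' Full within-subject decomposition for two crossed within-subject
#' factors: condition type (experimental vs control, 2 levels) and time
#' point (k levels), each effect tested against its own subject-interaction
#' error term (F_A = MS_A / MS_AxS, and so on). Mauchly's test of
#' sphericity is run for the time and interaction effects, and
#' Greenhouse-Geisser epsilon (from the covariance of the within-subject
#' scores) multiplies both degrees of freedom for the corrected p value.
#' Both corrected and uncorrected p values are always stored; `p_reported`
#' follows the convention of applying the correction only when Mauchly's
#' test signals a violation (p < alpha). Effect size is partial eta
#' squared, SS_effect / (SS_effect + SS_error).
#'
#' @param matrix_exp,matrix_ctrl Numeric n x k matrices of change values
#'   (rows are participants, aligned across the two matrices; columns the
#'   post-baseline time points).
#' @param alpha Significance level used for the sphericity gate.
#' @return An object of class `rm_anova` with a per-effect results table
#'   (see [tidy.rm_anova()]).
#' @export
rm_anova_2x_k <- function(matrix_exp, matrix_ctrl, alpha = 0.05) {
  matrix_exp <- as.matrix(matrix_exp)
  matrix_ctrl <- as.matrix(matrix_ctrl)
  if (!all(dim(matrix_exp) == dim(matrix_ctrl))) {
    abort("experimental and control matrices must have identical dimensions")
  }
  n <- nrow(matrix_exp)
  k <- ncol(matrix_exp)
  if (n < 3) abort("need at least 3 participants")
  if (k < 2) abort("need at least 2 time points")

  Y <- array(c(matrix_exp, matrix_ctrl), dim = c(n, k, 2)) # subject x time x type
  grand <- mean(Y)
  m_s <- apply(Y, 1, mean)          # subject means
  m_b <- apply(Y, 2, mean)          # time means
  m_a <- apply(Y, 3, mean)          # type means
  m_sb <- apply(Y, c(1, 2), mean)   # subject x time
  m_sa <- apply(Y, c(1, 3), mean)   # subject x type
  m_ba <- apply(Y, c(2, 3), mean)   # time x type

  ss_s <- 2 * k * sum((m_s - grand)^2)
  ss_a <- n * k * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_as <- k * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + grand)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, rep(1, k)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_ab <- n * sum((m_ba - outer(m_b, rep(1, 2)) -
                      outer(rep(1, k), m_a) + grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_abs <- ss_tot - ss_s - ss_a - ss_b - ss_as - ss_bs - ss_ab

  df <- c(type = 1, time = k - 1, interaction = k - 1)
  df_err <- c(type = n - 1, time = (n - 1) * (k - 1),
              interaction = (n - 1) * (k - 1))
  ss_eff <- c(type = ss_a, time = ss_b, interaction = ss_ab)
  ss_err <- c(type = ss_as, time = ss_bs, interaction = ss_abs)

  # sphericity inputs: per-subject scores collapsing the other factor
  sph <- list(
    type = list(epsilon = 1, W = NA_real_, p = NA_real_), # df 1: trivially spherical
    time = sphericity_stats((matrix_exp + matrix_ctrl) / 2),
    interaction = sphericity_stats(matrix_exp - matrix_ctrl)
  )

  effects <- names(df)
  tabs <- lapply(effects, function(e) {
    df1 <- df[[e]]
    df2 <- df_err[[e]]
    ms_e <- ss_eff[[e]] / df1
    ms_r <- ss_err[[e]] / df2
    if (ms_r <= 1e-300) {
      if (ss_eff[[e]] <= 1e-300) {
        f <- 0; p_unc <- 1
      } else {
        abort(sprintf("zero error variance for the %s term", e))
      }
    } else {
      f <- ms_e / ms_r
      p_unc <- pf(f, df1, df2, lower.tail = FALSE)
    }
    eps <- sph[[e]]$epsilon
    p_gg <- if (df1 == 1) p_unc else pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
    denom <- ss_eff[[e]] + ss_err[[e]]
    eta <- if (denom <= 1e-300) 0 else ss_eff[[e]] / denom
    mauchly_p <- sph[[e]]$p
    use_gg <- df1 > 1 && is.finite(mauchly_p) && mauchly_p < alpha
    tibble(effect = e, ss = ss_eff[[e]], df = df1,
           ms = ms_e, ss_error = ss_err[[e]], df_error = df2,
           ms_error = ms_r, statistic = f, p_uncorrected = p_unc,
           mauchly_w = sph[[e]]$W, mauchly_p = mauchly_p,
           gg_epsilon = eps, df_gg = df1 * eps,
           df_error_gg = df2 * eps, p_gg = p_gg,
           p_reported = if (use_gg) p_gg else p_unc,
           sphericity_corrected = use_gg,
           partial_eta_sq = eta)
  })

  structure(
    list(table = dplyr::bind_rows(tabs), n = n, k = k, alpha = alpha,
         ss_subject = ss_s, ss_total = ss_tot),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (2 x %d within-subject, n = %d)\n",
              x$k, x$n))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    corr <- if (tab$sphericity_corrected[i]) " (GG-corrected)" else ""
    cat(sprintf("  %-12s F(%.2f, %.2f) = %6.3f, p = %.4g%s, eta_p^2 = %.3f\n",
                tab$effect[i],
                if (tab$sphericity_corrected[i]) tab$df_gg[i] else tab$df[i],
                if (tab$sphericity_corrected[i]) tab$df_error_gg[i] else tab$df_error[i],
                tab$statistic[i], tab$p_reported[i], corr,
                tab$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Bonferroni-corrected per-time-point post hocs
#'
#' Paired t tests (experimental vs control) at each post-baseline time
#' point; p values are multiplied by the number of time points in the
#' window (the per-figure annotation family) and clamped at 1.
#'
#' @inheritParams rm_anova_2x_k
#' @param rel_times Optional vector of the column time stamps, seconds.
#' @return Tibble: rel_time_s (or column index), mean_diff, statistic, df,
#'   p_value, p_adjusted, significant.
#' @export
bonferroni_posthoc <- function(matrix_exp, matrix_ctrl, rel_times = NULL,
                               alpha = 0.05) {
  matrix_exp <- as.matrix(matrix_exp)
  matrix_ctrl <- as.matrix(matrix_ctrl)
  k <- ncol(matrix_exp)
  if (is.null(rel_times)) {
    rel_times <- if (!is.null(colnames(matrix_exp))) {
      suppressWarnings(as.numeric(sub("^t", "", colnames(matrix_exp))))
    } else seq_len(k)
  }
  res <- lapply(seq_len(k), function(j) {
    pr <- paired_core(matrix_exp[, j], matrix_ctrl[, j])
    tibble(rel_time_s = rel_times[j], mean_diff = pr$mean_diff,
           statistic = pr$t, df = pr$df, p_value = pr$p)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- clamp(out$p_value * k, 0, 1)
  out$significant <- out$p_adjusted < alpha
  out
}

# Gram-Schmidt orthonormal polynomial weights on k equally spaced points;
# each column sums to zero, has unit norm, and is orthogonal to the lower
# orders. Sign convention: the quadratic column is positive at both ends
# (U-shape positive), matching a deceleration-then-acceleration pattern
# when the dip sits mid-window.
polynomial_weights <- function(k, orders = 1:3) {
  if (k < max(orders) + 1) {
    abort(sprintf("need at least %d time points for an order-%d contrast",
                  max(orders) + 1, max(orders)))
  }
  t <- seq_len(k)
  basis <- cbind(rep(1, k))
  for (d in seq_len(max(orders))) {
    v <- t^d
    for (j in seq_len(ncol(basis))) {
      b <- basis[, j]
      v <- v - sum(v * b) / sum(b * b) * b
    }
    basis <- cbind(basis, v)
  }
  W <- basis[, orders + 1, drop = FALSE]
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  # fix signs: leading coefficient positive (increasing linear, U quadratic)
  for (j in seq_len(ncol(W))) if (W[k, j] < 0) W[, j] <- -W[, j]
  colnames(W) <- c("linear", "quadratic", "cubic")[orders]
  W
}

#' Orthogonal polynomial trend contrasts
#'
#' Tests whether a within-subject time course follows linear, quadratic or
#' cubic trends. Orthonormal weights are built by Gram-Schmidt on
#' \{1, t, t^2, t^3\} over the k equally spaced post-baseline points (the
#' forced-zero baseline sample is excluded so it cannot distort
#' orthogonality). Each participant's change vector is projected onto each
#' weight vector and the resulting scores are tested against zero with a
#' one-sample t test (df = n - 1). A positive quadratic score corresponds
#' to a U-shaped (deceleration-then-acceleration) pattern — the biphasic
#' anticipatory cardiac signature.
#'
#' @param matrix An n x k matrix of change values.
#' @param orders Polynomial orders to test (subset of 1:3).
#' @return An object of class `trend_contrast` with the per-order table,
#'   the weight matrix and the per-subject scores.
#' @export
polynomial_contrast <- function(matrix, orders = 1:3) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  k <- ncol(matrix)
  W <- polynomial_weights(k, orders)
  scores <- matrix %*% W
  tab <- purrr::map_dfr(seq_along(orders), function(j) {
    s <- scores[, j]
    m <- mean(s)
    sdv <- sd(s)
    if (sdv <= 1e-12) {
      tt <- if (abs(m) <= 1e-9) 0 else sign(m) * Inf
      p <- if (abs(m) <= 1e-9) 1 else 0
    } else {
      tt <- m / (sdv / sqrt(n))
      p <- 2 * pt(abs(tt), n - 1, lower.tail = FALSE)
    }
    tibble(order = colnames(W)[j], estimate = m, statistic = tt,
           df = n - 1, p_value = p)
  })
  structure(list(table = tab, weights = W, scores = scores, n = n, k = k),
            class = "trend_contrast")
}

#' @export
print.trend_contrast <- function(x, ...) {
  cat(sprintf("Polynomial trend contrasts (n = %d, %d time points)\n", x$n, x$k))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-9s t(%d) = %7.3f, p = %.4g\n",
                tab$order[i], tab$df[i], tab$statistic[i], tab$p_value[i]))
  }
  invisible(x)
}

# shared paired-comparison core (also used by the post hocs)
paired_core <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 2) abort("need at least 2 pairs")
  m <- mean(d)
  s <- sd(d)
  if (s <= 1e-12) {
    if (abs(m) <= 1e-9) {
      list(mean_diff = 0, sd_diff = 0, t = 0, df = n - 1, p = 1, d = 0)
    } else {
      # zero spread with a nonzero shift: degenerate, flagged by sentinels
      list(mean_diff = m, sd_diff = 0, t = sign(m) * Inf, df = n - 1,
           p = 0, d = sign(m) * Inf)
    }
  } else {
    tt <- m / (s / sqrt(n))
    list(mean_diff = m, sd_diff = s, t = tt, df = n - 1,
         p = 2 * pt(abs(tt), n - 1, lower.tail = FALSE), d = m / s)
  }
}

#' Paired comparison of AUC between experimental and control conditions
#'
#' Paired t test with Cohen's d for paired data (mean difference divided by
#' the SD of the differences, so t = d * sqrt(n)). Inputs are matched by
#' participant id when AUC tables are supplied, or positionally for bare
#' numeric vectors.
#'
#' @param auc_exp,auc_ctrl Numeric vectors, or tibbles with `pid` and `auc`
#'   columns (as produced by [auc_table()]).
#' @return An object of class `paired_comparison`.
#' @export
paired_auc_test <- function(auc_exp, auc_ctrl) {
  if (is.data.frame(auc_exp)) {
    j <- dplyr::inner_join(
      dplyr::select(auc_exp, "pid", exp_auc = "auc"),
      dplyr::select(auc_ctrl, "pid", ctrl_auc = "auc"),
      by = "pid"
    )
    x <- j$exp_auc; y <- j$ctrl_auc
  } else {
    if (length(auc_exp) != length(auc_ctrl)) abort("paired vectors must have equal length")
    x <- auc_exp; y <- auc_ctrl
  }
  pr <- paired_core(x, y)
  structure(
    list(n = length(x), mean_exp = mean(x), sd_exp = sd(x),
         mean_ctrl = mean(y), sd_ctrl = sd(y),
         mean_diff = pr$mean_diff, sd_diff = pr$sd_diff,
         statistic = pr$t, df = pr$df, p_value = pr$p, cohens_d = pr$d),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: t(%d) = %.3f, p = %.4g, d = %.3f (n = %d)\n",
              x$df, x$statistic, x$p_value, x$cohens_d, x$n))
  invisible(x)
}
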