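# Independent oracle implementations used to validate the package's
# statistics: explicit-sum ANOVA decomposition, textbook paired-t formulas,
# trapezoid refinement, and direct projections. These deliberately share no
# code with the package internals.

# brute-force 2 x k within-subject ANOVA by explicit loops over cells
brute_rm_anova <- function(me, mc) {
  n <- nrow(me); k <- ncol(me)
  y <- array(NA_real_, c(n, 2, k))
  y[, 1, ] <- me
  y[, 2, ] <- mc
  g <- mean(y)
  ms <- sapply(1:n, function(i) mean(y[i, , ]))
  ma <- sapply(1:2, function(a) mean(y[, a, ]))
  mb <- sapply(1:k, function(b) mean(y[, , b]))
  msa <- outer(1:n, 1:2, Vectorize(function(i, a) mean(y[i, a, ])))
  msb <- outer(1:n, 1:k, Vectorize(function(i, b) mean(y[i, , b])))
  mab <- outer(1:2, 1:k, Vectorize(function(a, b) mean(y[, a, b])))
  ss_s <- ss_a <- ss_b <- ss_as <- ss_bs <- ss_ab <- ss_abs <- 0
  ss_s <- 2 * k * sum((ms - g)^2)
  ss_a <- n * k * sum((ma - g)^2)
  ss_b <- 2 * n * sum((mb - g)^2)
  for (i in 1:n) for (a in 1:2) {
    ss_as <- ss_as + k * (msa[i, a] - ms[i] - ma[a] + g)^2
  }
  for (i in 1:n) for (b in 1:k) {
    ss_bs <- ss_bs + 2 * (msb[i, b] - ms[i] - mb[b] + g)^2
  }
  for (a in 1:2) for (b in 1:k) {
    ss_ab <- ss_ab + n * (mab[a, b] - ma[a] - mb[b] + g)^2
  }
  for (i in 1:n) for (a in 1:2) for (b in 1:k) {
    ss_abs <- ss_abs +
      (y[i, a, b] - msa[i, a] - msb[i, b] - mab[a, b] +
         ms[i] + ma[a] + mb[b] - g)^2
  }
  f_a <- (ss_a / 1) / (ss_as / (n - 1))
  f_b <- (ss_b / (k - 1)) / (ss_bs / ((n - 1) * (k - 1)))
  f_ab <- (ss_ab / (k - 1)) / (ss_abs / ((n - 1) * (k - 1)))
  list(
    ss = c(type = ss_a, time = ss_b, interaction = ss_ab,
           type_err = ss_as, time_err = ss_bs, interaction_err = ss_abs,
           subject = ss_s),
    F = c(type = f_a, time = f_b, interaction = f_ab),
    p = c(type = pf(f_a, 1, n - 1, lower.tail = FALSE),
          time = pf(f_b, k - 1, (n - 1) * (k - 1), lower.tail = FALSE),
          interaction = pf(f_ab, k - 1, (n - 1) * (k - 1), lower.tail = FALSE)),
    eta = c(type = ss_a / (ss_a + ss_as),
            time = ss_b / (ss_b + ss_bs),
            interaction = ss_ab / (ss_ab + ss_abs))
  )
}

# Greenhouse-Geisser epsilon via the eigenvalues of the contrast covariance
brute_gg_epsilon <- function(D) {
  k <- ncol(D)
  M <- stats::contr.helmert(k)
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  lam <- eigen(t(M) %*% stats::cov(D) %*% M, symmetric = TRUE,
               only.values = TRUE)$values
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

# textbook paired t and Cohen's d
brute_paired <- function(x, y) {
  d <- x - y
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), n - 1), d = mean(d) / sd(d))
}

# one-sample t on hand-computed projection scores
brute_contrast_t <- function(m, w) {
  s <- as.numeric(m %*% w)
  tt <- mean(s) / (sd(s) / sqrt(length(s)))
  list(t = tt, p = 2 * pt(-abs(tt), length(s) - 1))
}

# fine-grid numeric integral of the piecewise-linear interpolant
brute_auc <- function(rel, change, n_fine = 100000) {
  keep <- rel >= 0
  xs <- seq(min(rel[keep]), max(rel[keep]), length.out = n_fine)
  ys <- approx(rel[keep], change[keep], xs)$y
  sum((ys[-1] + ys[-n_fine]) / 2 * diff(xs))
}

# nearest-neighbour beat matching at a tolerance (for detector fidelity)
match_beats <- function(detected, truth, tol = 0.05) {
  if (!length(detected)) {
    return(list(tp = 0, fn = length(truth), fp = 0,
                sensitivity = 0, ppv = NA_real_))
  }
  used <- rep(FALSE, length(detected))
  tp <- 0
  for (bt in truth) {
    d <- abs(detected - bt)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      tp <- tp + 1
      used[j] <- TRUE
    }
  }
  list(tp = tp, fn = length(truth) - tp, fp = sum(!used),
       sensitivity = tp / length(truth), ppv = tp / length(detected))
}

# shared small session config for fast end-to-end tests
scaled_session_config <- function(...) {
  session_config(trip_duration_s = 90,
                 cue_onsets_s = c(U = 18, P = 42, PF = 66), ...)
}
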