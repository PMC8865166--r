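# inferential machinery vs independent oracles

test_that("rm-ANOVA handles the all-equal degenerate table", {
  me <- matrix(5, 6, 4)
  mc <- matrix(5, 6, 4)
  fit <- rm_anova_2x_k(me, mc)
  expect_true(all(fit$table$statistic == 0))
  expect_true(all(fit$table$partial_eta_sq == 0))
  expect_true(all(is.finite(fit$table$statistic)))
})

test_that("rm-ANOVA matches the explicit-sums oracle on random tables", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    k <- sample(3:6, 1)
    me <- matrix(rnorm(n * k), n, k)
    mc <- matrix(rnorm(n * k), n, k)
    fit <- rm_anova_2x_k(me, mc)
    oracle <- brute_rm_anova(me, mc)
    tab <- fit$table
    for (e in c("type", "time", "interaction")) {
      expect_equal(tab$statistic[tab$effect == e], oracle$F[[e]], tolerance = 1e-8)
      expect_equal(tab$p_uncorrected[tab$effect == e], oracle$p[[e]], tolerance = 1e-8)
      expect_equal(tab$ss[tab$effect == e], oracle$ss[[e]], tolerance = 1e-8)
      expect_equal(tab$partial_eta_sq[tab$effect == e], oracle$eta[[e]], tolerance = 1e-8)
    }
  }
})

test_that("rm-ANOVA agrees with aov() and its sphericity stats with mauchly.test()/anova.mlm()", {
  set.seed(7)
  n <- 8; k <- 5
  me <- matrix(rnorm(n * k, sd = 2), n, k)
  mc <- matrix(rnorm(n * k, sd = 2), n, k)
  fit <- rm_anova_2x_k(me, mc)

  long <- expand.grid(s = factor(1:n), a = factor(1:2), b = factor(1:k))
  # expand.grid varies s fastest, then a, then b
  long$y <- as.vector(aperm(array(c(me, mc), c(n, k, 2)), c(1, 3, 2)))
  aov_fit <- summary(aov(y ~ a * b + Error(s / (a * b)), data = long))
  f_a <- aov_fit[["Error: s:a"]][[1]]["a", "F value"]
  f_b <- aov_fit[["Error: s:b"]][[1]]["b", "F value"]
  f_ab <- aov_fit[["Error: s:a:b"]][[1]]["a:b", "F value"]
  tab <- fit$table
  expect_equal(tab$statistic[tab$effect == "type"], f_a, tolerance = 1e-10)
  expect_equal(tab$statistic[tab$effect == "time"], f_b, tolerance = 1e-10)
  expect_equal(tab$statistic[tab$effect == "interaction"], f_ab, tolerance = 1e-10)

  # Mauchly and Greenhouse-Geisser for the time effect, via base R's mlm path
  D <- (me + mc) / 2
  mlm <- lm(D ~ 1)
  idata <- data.frame(time = factor(1:k))
  mt <- mauchly.test(mlm, M = ~time, X = ~1, idata = idata)
  expect_equal(tab$mauchly_w[tab$effect == "time"], unname(mt$statistic),
               tolerance = 1e-8)
  expect_equal(tab$mauchly_p[tab$effect == "time"], mt$p.value, tolerance = 5e-4)

  # epsilon against the independent eigenvalue formula
  expect_equal(tab$gg_epsilon[tab$effect == "time"], brute_gg_epsilon(D),
               tolerance = 1e-10)
  expect_equal(tab$gg_epsilon[tab$effect == "interaction"],
               brute_gg_epsilon(me - mc), tolerance = 1e-10)
})

test_that("epsilon is near 1 under compound symmetry and within its bounds", {
  set.seed(12)
  n <- 1500; k <- 6
  subj <- rnorm(n, sd = 3)
  me <- matrix(rnorm(n * k), n, k) + subj
  mc <- matrix(rnorm(n * k), n, k) + subj
  fit <- rm_anova_2x_k(me, mc)
  tab <- fit$table
  expect_gte(tab$gg_epsilon[tab$effect == "time"], 0.99)
  for (e in c("time", "interaction")) {
    expect_gte(tab$gg_epsilon[tab$effect == e], 1 / (k - 1))
    expect_lte(tab$gg_epsilon[tab$effect == e], 1)
  }
})

test_that("Bonferroni post hocs scale p by the number of time points", {
  set.seed(21)
  me <- matrix(rnorm(80), 8, 10)
  ph <- bonferroni_posthoc(me, me)
  expect_true(all(ph$p_adjusted == 1))
  expect_true(all(!ph$significant))

  mc <- me + matrix(rnorm(80, sd = 0.2), 8, 10)
  ph2 <- bonferroni_posthoc(me, mc)
  expect_equal(ph2$p_adjusted, pmin(1, ph2$p_value * 10))
  # oracle spot check at each column
  for (j in c(1, 5, 10)) {
    o <- brute_paired(me[, j], mc[, j])
    expect_equal(ph2$statistic[j], o$t, tolerance = 1e-10)
    expect_equal(ph2$p_value[j], o$p, tolerance = 1e-10)
  }
})

test_that("polynomial weights are zero-sum, orthonormal and match contr.poly", {
  for (k in c(4, 10, 16)) {
    W <- drivecr:::polynomial_weights(k)
    expect_lt(max(abs(colSums(W))), 1e-12)
    G <- t(W) %*% W
    expect_lt(max(abs(G - diag(3))), 1e-12)
    cp <- stats::contr.poly(k)[, 1:3]
    expect_lt(max(abs(abs(W) - abs(cp))), 1e-10)
    # sign convention: quadratic positive at both ends (U-shape positive)
    expect_gt(W[1, "quadratic"], 0)
    expect_gt(W[k, "quadratic"], 0)
  }
  expect_error(drivecr:::polynomial_weights(3, orders = 1:3), "order-3")
})

test_that("polynomial contrasts isolate the generating trend", {
  m_flat <- matrix(4, 20, 10)
  ct <- polynomial_contrast(m_flat)
  expect_true(all(ct$table$statistic == 0))

  set.seed(33)
  k <- 10; n <- 30
  t <- 1:k
  curve <- 0.8 * (t - mean(t))^2
  m <- matrix(rep(curve, each = n), n, k) + matrix(rnorm(n * k), n, k)
  ct2 <- polynomial_contrast(m)
  tabs <- ct2$table
  tq <- abs(tabs$statistic[tabs$order == "quadratic"])
  expect_gt(tq, abs(tabs$statistic[tabs$order == "linear"]))
  expect_gt(tq, abs(tabs$statistic[tabs$order == "cubic"]))
  expect_lt(tabs$p_value[tabs$order == "quadratic"], 0.001)
  expect_gt(tabs$statistic[tabs$order == "quadratic"], 0) # U-shape positive

  # oracle: one-sample t on hand-computed projection scores
  W <- drivecr:::polynomial_weights(k)
  for (ord in colnames(W)) {
    o <- brute_contrast_t(m, W[, ord])
    expect_equal(tabs$statistic[tabs$order == ord], o$t, tolerance = 1e-10)
    expect_equal(tabs$p_value[tabs$order == ord], o$p, tolerance = 1e-10)
  }
})

test_that("paired AUC test matches the textbook formulas and handles degeneracy", {
  x <- c(3, 4, 5, 7)
  res0 <- paired_auc_test(x, x)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$cohens_d, 0)

  res1 <- paired_auc_test(x + 1, x)
  expect_true(is.infinite(res1$cohens_d))
  expect_equal(res1$p_value, 0)

  set.seed(5)
  a <- rnorm(25); b <- rnorm(25)
  res <- paired_auc_test(a, b)
  o <- brute_paired(a, b)
  expect_equal(res$statistic, o$t, tolerance = 1e-10)
  expect_equal(res$p_value, o$p, tolerance = 1e-10)
  expect_equal(res$cohens_d, o$d, tolerance = 1e-10)
  # identity linking t and d for paired designs
  expect_equal(res$statistic, res$cohens_d * sqrt(25), tolerance = 1e-10)
  # cross-check against base R
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("partial eta squared never decreases when the effect doubles", {
  tpl1 <- ecr_template(-5, 1, 6, 3)
  tpl2 <- ecr_template(-10, 1, 12, 3)
  eta <- function(tpl, seed) {
    cohort <- simulate_change_cohort(20, template = tpl, seed = seed)
    fit <- rm_anova_2x_k(cohort$experimental, cohort$control)
    fit$table$partial_eta_sq[fit$table$effect == "interaction"]
  }
  e1 <- vapply(1:6, function(s) eta(tpl1, s), numeric(1))
  e2 <- vapply(1:6, function(s) eta(tpl2, s), numeric(1))
  expect_gte(mean(e2), mean(e1))
})

test_that("tidy and glance expose the fitted objects as tibbles", {
  set.seed(2)
  me <- matrix(rnorm(40), 8, 5); mc <- matrix(rnorm(40), 8, 5)
  fit <- rm_anova_2x_k(me, mc)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_equal(gl$interaction_F, td$statistic[td$effect == "interaction"])

  ct <- polynomial_contrast(me)
  expect_equal(nrow(tidy(ct)), 3)
  expect_true("quadratic_p" %in% names(glance(ct)))

  pr <- paired_auc_test(rnorm(10), rnorm(10))
  expect_equal(nrow(tidy(pr)), 1)
  expect_equal(glance(pr)$cohens_d, pr$cohens_d)
})
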