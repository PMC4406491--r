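test_that("block averages normalise per subject and reproduce schedules", {
  # two subjects with identical values: everything is 100% of max
  df <- data.frame(subject = rep(c("a", "b"), each = 8),
                   set = rep(1:8, 2), rep = 1L, v = 5)
  out <- block_average(df, "v", "four_sets")
  expect_equal(out$mean, c(100, 100))
  expect_equal(out$sd, c(0, 0))
  # programmed linear decline: noise-free block means equal schedule means
  sets <- 1:20
  frac <- 1 - (1 - 0.549) * (sets - 1) / 19
  df2 <- data.frame(subject = "a", set = sets, rep = 1L, v = 1069 * frac)
  out2 <- block_average(df2, "v", "four_sets")
  expected <- 100 * vapply(split(frac, (sets - 1) %/% 4),
                           mean, numeric(1)) / max(frac)
  expect_equal(out2$mean, unname(expected))
  # single-subject five-interval grouping is a pass-through mean
  out3 <- block_average(df2, "v", "five_intervals")
  expect_equal(nrow(out3), 5L)
  expect_equal(out3$n_subjects, rep(1L, 5))
})

test_that("percent change and lactate accumulation", {
  expect_equal(percent_change(100, 67.4), -32.6)
  expect_equal(percent_change(88, 88), 0)
  expect_equal(percent_change(320, 215), -32.8125)
  expect_error(percent_change(0, 10), "invalid-input")
  expect_equal(lactate_accumulation(1.3, 7.0), 5.7)
  expect_equal(lactate_accumulation(2, 2), 0)
  expect_equal(lactate_accumulation(3, 2), -1)
})

test_that("standardized OLS recovers constructed betas exactly", {
  # orthonormal z-scored predictors plus an orthogonal residual give exact
  # standardized coefficients (0.64, 0.19)
  set.seed(42)
  n <- 200
  # zero-mean, unit-SD, exactly uncorrelated variables by residualization
  a1 <- rnorm(n)
  a2 <- resid(lm(rnorm(n) ~ a1))
  a3 <- resid(lm(rnorm(n) ~ a1 + a2))
  z1 <- as.numeric(scale(a1)); z2 <- as.numeric(scale(a2))
  e <- as.numeric(scale(a3))
  resid_sd <- sqrt(1 - 0.64^2 - 0.19^2)
  y <- 0.64 * z1 + 0.19 * z2 + resid_sd * e
  fit <- ols_standardized(y, cbind(a = z1, b = z2))
  expect_equal(unname(fit$beta), c(0.64, 0.19) / sd(y), tolerance = 1e-8)
  expect_equal(fit$r2, (0.64^2 + 0.19^2) / var(y), tolerance = 1e-8)
  # closed-form oracle: solve the normal equations by hand
  zX <- scale(cbind(z1, z2)); zy <- scale(y)
  beta_hand <- solve(t(zX) %*% zX, t(zX) %*% zy)
  expect_equal(unname(fit$beta), as.numeric(beta_hand), tolerance = 1e-10)
  # y identical to one z-scored predictor: beta 1, R2 1
  fit2 <- suppressWarnings(ols_standardized(z1, cbind(x = z1 * 3 + 5)))
  expect_equal(unname(fit2$beta), 1, tolerance = 1e-12)
  expect_equal(fit2$r2, 1, tolerance = 1e-12)
  # independent noise: R2 near zero
  set.seed(7)
  fit3 <- ols_standardized(rnorm(1000), cbind(x = rnorm(1000)))
  expect_lt(fit3$r2, 0.01)
  expect_error(ols_standardized(rnorm(10), cbind(x = rep(1, 10))),
               "invalid-input")
})

test_that("standardized betas are invariant to affine predictor rescaling", {
  set.seed(9)
  x1 <- rnorm(60); x2 <- rnorm(60)
  y <- x1 + 0.5 * x2 + rnorm(60, 0, 0.3)
  f1 <- ols_standardized(y, cbind(a = x1, b = x2))
  f2 <- ols_standardized(y, cbind(a = 100 * x1 - 7, b = 0.01 * x2 + 3))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
})

test_that("forward stepwise keeps informative predictors and drops noise", {
  set.seed(12)
  n <- 120
  z1 <- rnorm(n); z2 <- rnorm(n); junk <- rnorm(n)
  y1 <- z1 + rnorm(n, 0, 0.5)
  f <- forward_stepwise(y1, cbind(signal = z1, noise = junk))
  expect_equal(f$included, "signal")
  y2 <- z1 + 0.6 * z2 + rnorm(n, 0, 0.4)
  f2 <- forward_stepwise(y2, cbind(a = z1, b = z2))
  expect_setequal(f2$included, c("a", "b"))
  y3 <- rnorm(n)
  f3 <- forward_stepwise(y3, cbind(a = rnorm(n), b = rnorm(n)))
  expect_true(f3$empty)
  expect_equal(f3$r2, 0)
  # never below the best single predictor
  for (k in 1:5) {
    set.seed(100 + k)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("p", "q", "r")))
    y <- X %*% c(0.8, 0.3, 0) + rnorm(n)
    fs <- forward_stepwise(y, X)
    best_single <- max(vapply(colnames(X), function(v)
      summary(lm(y ~ X[, v]))$r.squared, numeric(1)))
    expect_gte(fs$r2 + 1e-12, best_single)
  }
  # collinearity guard: a near-duplicate predictor is not entered
  f4 <- forward_stepwise(y1, cbind(signal = z1,
                                   dup = z1 + rnorm(n, 0, 0.01)))
  expect_equal(f4$included, "signal")
})

test_that("repeated-measures ANOVA agrees with aov and a brute-force oracle", {
  # identical columns: no condition effect
  m0 <- matrix(rep(c(3, 5, 7), 4), nrow = 4, byrow = TRUE)
  expect_equal(rm_anova(cbind(m0[, 1], m0[, 1], m0[, 1]))$F, 0)
  # random small tables against aov's Error(subject) stratum
  for (k in 1:6) {
    set.seed(200 + k)
    n <- sample(3:5, 1); p <- sample(3:5, 1)
    vals <- matrix(rnorm(n * p, mean = rep(seq_len(p), each = n)), n, p)
    out <- rm_anova(vals)
    long <- data.frame(y = as.vector(vals),
                       subj = factor(rep(seq_len(n), p)),
                       cond = factor(rep(seq_len(p), each = n)))
    av <- summary(aov(y ~ cond + Error(subj / cond), data = long))
    ftab <- av[["Error: subj:cond"]][[1]]
    expect_equal(out$F, ftab["cond", "F value"], tolerance = 1e-10)
    expect_equal(out$p, ftab["cond", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(out$df1, ftab["cond", "Df"])
    expect_equal(out$df2, ftab["Residuals", "Df"])
  }
  # a strong condition effect is detected
  set.seed(33)
  big <- sapply(c(0, 5, 10), function(m) rnorm(8, m, 0.2))
  expect_lt(rm_anova(big)$p, 1e-6)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "unbalanced")
  expect_error(rm_anova(matrix(1:3, 3, 1)), "invalid-input")
})

test_that("Tukey post hoc separates clusters and matches ptukey logic", {
  set.seed(44)
  equal <- matrix(rnorm(40, 10, 1), 8, 5)
  p_eq <- tukey_posthoc(equal)
  expect_true(all(p_eq$p > 0.2))
  clusters <- cbind(rnorm(8, 0, 0.2), rnorm(8, 0.1, 0.2),
                    rnorm(8, 8, 0.2), rnorm(8, 8.1, 0.2))
  p_cl <- tukey_posthoc(clusters)
  across <- with(p_cl, (a %in% c("c1", "c2")) != (b %in% c("c1", "c2")))
  expect_true(all(p_cl$p[across] < 0.001))
  expect_true(all(p_cl$p[!across] > 0.2))
  # k = 2 ordering matches the paired t statistic ordering
  two <- matrix(rnorm(20, rep(c(0, 1), each = 10), 1), 10, 2)
  an <- rm_anova(two)
  pt <- tukey_posthoc(two)
  expect_equal(pt$q^2 / 2, an$F, tolerance = 1e-10)  # q^2 = 2F when k = 2
})

test_that("mono-exponential fit recovers the asymptote", {
  tt <- 30 * (1:20)
  y <- 23.7 - (23.7 - 5) * exp(-tt / 60)
  f <- fit_monoexp(tt, y)
  expect_equal(f$asymptote, 23.7, tolerance = 1e-6)
  expect_equal(f$tau, 60, tolerance = 1e-4)
  expect_true(f$identifiable)
  # constant series: asymptote is the constant, tau flagged unidentifiable
  fc <- fit_monoexp(tt, rep(12.5, 20))
  expect_equal(fc$asymptote, 12.5)
  expect_false(fc$identifiable)
  expect_true(is.na(fc$tau))
  # 5% noise, 40 points: asymptote within 3%
  set.seed(77)
  t2 <- 30 * (1:40)
  y2 <- 23.7 - (23.7 - 5) * exp(-t2 / 60) + rnorm(40, 0, 0.05 * 23.7)
  f2 <- fit_monoexp(t2, y2)
  expect_lt(abs(f2$asymptote / 23.7 - 1), 0.03)
  expect_error(fit_monoexp(1:3, 1:3), "invalid-input")
})
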