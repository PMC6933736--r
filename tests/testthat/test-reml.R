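test_that("balanced one-way REML equals ANOVA method-of-moments exactly", {
  d <- data.frame(g = rep(c("a", "b", "c"), each = 2),
                  y = c(1, 3, 5, 7, 9, 11))
  fit <- fit_reml(y ~ 1, d, random = ~ g)
  # MSW = 2, MSB = 32, n = 2: sigma2_e = 2, sigma2_g = (32 - 2) / 2 = 15
  expect_equal(unname(fit$sigma2["residual"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$sigma2["random"]), 15, tolerance = 1e-7)
  # larger balanced design, against the closed form
  set.seed(1)
  d2 <- data.frame(g = rep(sprintf("g%02d", 1:12), each = 5))
  d2$y <- rnorm(12, 0, 2)[as.integer(factor(d2$g))] + rnorm(60)
  fit2 <- fit_reml(y ~ 1, d2, random = ~ g)
  msb <- 5 * var(tapply(d2$y, d2$g, mean))
  msw <- mean(tapply(d2$y, d2$g, var))
  expect_equal(unname(fit2$sigma2["residual"]), msw, tolerance = 1e-8)
  expect_equal(unname(fit2$sigma2["random"]), (msb - msw) / 5, tolerance = 1e-7)
})

test_that("profiled REML log-likelihood matches a dense grid-search oracle", {
  for (seed in c(101, 102, 103)) {
    d <- random_lmm_instance(n = 50, q = 8, seed = seed)
    fit <- fit_reml(y ~ x, d, random = ~ g)
    X <- cbind(1, d$x)
    oracle <- grid_reml_loglik(d$y, X, d$g)
    expect_equal(fit$logLik, oracle, tolerance = 1e-6)
  }
})

test_that("REML estimates agree with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  d <- random_lmm_instance(n = 150, q = 15, seed = 7)
  fit <- fit_reml(y ~ x, d, random = ~ g)
  m <- lme4::lmer(y ~ x + (1 | g), d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(unname(fit$sigma2), vc, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(m)),
               tolerance = 1e-6)
  expect_equal(unname(fit$blups[rownames(lme4::ranef(m)$g)]),
               lme4::ranef(m)$g[, 1], tolerance = 1e-5)
})

test_that("identical observations give a flagged zero-variance boundary fit", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(4, 6))
  fit <- fit_reml(y ~ 1, d, random = ~ g)
  expect_equal(unname(fit$sigma2["random"]), 0)
  expect_lt(unname(fit$sigma2["residual"]), 1e-20)
  expect_true(fit$boundary)
})

test_that("rank-deficient designs fail with the aliased columns named", {
  d <- data.frame(y = rnorm(20), a = rep(c("x", "y"), 10))
  d$b <- d$a  # perfectly aliased factor
  expect_error(fit_reml(y ~ a + b, d), "aliased")
})

test_that("REML criterion is invariant to relabeling factor levels", {
  d <- random_lmm_instance(n = 80, q = 10, seed = 19)
  fit1 <- fit_reml(y ~ x, d, random = ~ g)
  d2 <- d
  d2$g <- factor(paste0("zzz", as.integer(d2$g)))
  fit2 <- fit_reml(y ~ x, d2, random = ~ g)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-9)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-9)
})

test_that("type-III F reduces to one-way ANOVA F when sigma2_random is 0", {
  set.seed(23)
  d <- data.frame(f = factor(rep(1:4, each = 10)))
  d$y <- c(0, 1, 2, 3)[as.integer(d$f)] + rnorm(40)
  fit <- fit_reml(y ~ f, d)
  an <- anova(fit)
  ref <- anova(lm(y ~ f, d))
  expect_equal(an$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(an$df_den, ref$Df[2])
  expect_equal(an$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("Satterthwaite F and df agree with lmerTest", {
  skip_if_not_installed("lmerTest")
  set.seed(29)
  n <- 200
  d <- data.frame(g = factor(sample(1:25, n, TRUE)),
                  f = factor(sample(1:3, n, TRUE)),
                  h = factor(sample(1:2, n, TRUE)))
  d$y <- rnorm(25, 0, 1)[as.integer(d$g)] + c(0, 0.5, 1)[as.integer(d$f)] +
    c(0, 0.3)[as.integer(d$h)] + rnorm(n)
  fit <- fit_reml(y ~ f + h, d, random = ~ g)
  an <- anova(fit)
  m <- lmerTest::lmer(y ~ f + h + (1 | g), d, REML = TRUE)
  ref <- anova(m, type = 3)
  expect_equal(an$F, ref$`F value`, tolerance = 1e-4)
  expect_equal(an$df_den, ref$DenDF, tolerance = 0.05)
})

test_that("random-effect LRT follows the arithmetic contract", {
  d <- random_lmm_instance(n = 100, q = 12, seed = 31)
  full <- fit_reml(y ~ x, d, random = ~ g)
  red <- fit_reml(y ~ x, d)
  lrt <- lrt_random(full, red)
  expect_equal(lrt$chisq, max(0, 2 * (full$logLik - red$logLik)))
  expect_equal(lrt$p, pchisq(lrt$chisq, 1, lower.tail = FALSE))
  # identical log-likelihoods give chisq 0 and p 1 (clipping contract)
  fake <- full; fake$logLik <- red$logLik
  lrt0 <- lrt_random(fake, red)
  expect_equal(lrt0$chisq, 0)
  expect_equal(lrt0$p, 1)
  expect_error(lrt_random(full, fit_reml(y ~ 1, d)), "fixed structures")
})

test_that("LS means reduce to cell-mean averages and widen with noise", {
  # balanced two-factor: LS mean of a level = mean of its cell means
  set.seed(37)
  d <- expand.grid(a = factor(1:3), b = factor(1:2), rep = 1:4)
  d$y <- rnorm(nrow(d)) + as.integer(d$a)
  fit <- fit_reml(y ~ a + b, d)
  lsm <- ls_means(fit, "a")
  cells <- tapply(d$y, list(d$a, d$b), mean)
  expect_equal(lsm$lsmean, unname(rowMeans(cells)), tolerance = 1e-10)
  # unbalanced toy: equal-weight average of cell predictions, by hand
  d2 <- data.frame(a = factor(c(1, 1, 1, 1, 2, 2, 2, 2)),
                   b = factor(c(1, 1, 1, 2, 1, 2, 2, 2)),
                   y = c(3, 5, 4, 10, 1, 7, 8, 9))
  fit2 <- fit_reml(y ~ a + b, d2)
  lsm2 <- ls_means(fit2, "a")
  cf <- coef(fit2)
  # sum-to-zero coding: prediction(a_i) averaged over b = mu + alpha_i
  expect_equal(lsm2$lsmean, c(cf[1] + cf[2], cf[1] - cf[2]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # scaling the response scales sigma2_e and widens the intervals
  d3 <- d2; d3$y <- d2$y + rnorm(8, 0, 0.01)
  fit_small <- fit_reml(y ~ a + b, d3)
  d4 <- d3; d4$y <- fitted(fit_small) + 10 * residuals(fit_small)
  fit_big <- fit_reml(y ~ a + b, d4)
  expect_true(all(ls_means(fit_big, "a")$se > ls_means(fit_small, "a")$se))
})

test_that("BLUPs shrink group means exactly as the closed form dictates", {
  set.seed(41)
  q <- 10; k <- 6
  d <- data.frame(g = rep(sprintf("g%02d", 1:q), each = k))
  d$y <- rnorm(q, 0, 2)[as.integer(factor(d$g))] + rnorm(q * k)
  fit <- fit_reml(y ~ 1, d, random = ~ g)
  u <- extract_blups(fit)
  s2u <- fit$sigma2["random"]; s2e <- fit$sigma2["residual"]
  gm <- tapply(d$y - coef(fit)[1], d$g, mean)
  shrink <- s2u / (s2u + s2e / k)
  expect_equal(unname(u), as.numeric(shrink * gm), tolerance = 1e-8)
  # BLUP mean ~ 0 and shrinkage inequality
  expect_lt(abs(mean(u)), 1e-8 * sd(u))
  expect_lt(var(u), var(tapply(d$y, d$g, mean)))
  # zero random variance implies all-zero BLUPs
  d0 <- data.frame(g = rep(c("a", "b", "c", "d"), each = 4), y = rnorm(16))
  f0 <- fit_reml(y ~ 1, d0, random = ~ g)
  if (f0$sigma2["random"] == 0) expect_true(all(extract_blups(f0) == 0))
})

test_that("prediction and simulation methods are coherent with the fit", {
  d <- random_lmm_instance(n = 60, q = 6, seed = 47)
  fit <- fit_reml(y ~ x, d, random = ~ g)
  expect_equal(predict(fit, level = 1), fitted(fit), tolerance = 1e-12)
  nd <- data.frame(x = c(0, 1), g = c(levels(d$g)[1], "unseen"))
  p0 <- predict(fit, nd, level = 0)
  p1 <- predict(fit, nd, level = 1)
  expect_equal(unname(p1[2]), unname(p0[2]), tolerance = 1e-12)
  expect_equal(unname(p1[1] - p0[1]), unname(fit$blups[1]), tolerance = 1e-12)
  s <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(s), c(60L, 3L))
})

test_that("the boundary LRT is conservative under a null random effect", {
  set.seed(53)
  rej <- 0; n_rep <- 200
  for (i in seq_len(n_rep)) {
    d <- data.frame(g = factor(rep(1:10, each = 6)), y = rnorm(60))
    full <- fit_reml(y ~ 1, d, random = ~ g)
    red <- fit_reml(y ~ 1, d)
    if (lrt_random(full, red)$p <= 0.05) rej <- rej + 1
  }
  # chi-square(1) reference at a boundary null: rejection should sit at or
  # below the nominal level (asymptotically ~2.5%)
  expect_lte(rej / n_rep, 0.05)
})
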