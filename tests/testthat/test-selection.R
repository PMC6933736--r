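test_that("relativization and standardization satisfy their identities", {
  expect_equal(relative_fitness(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(relative_fitness(rep(3, 5)), rep(1, 5))
  set.seed(81)
  W <- rexp(50); yr <- rep(c("a", "b"), 25)
  w <- relative_fitness(W, yr)
  expect_lt(abs(mean(w[yr == "a"]) - 1), 1e-12)
  expect_lt(abs(mean(w[yr == "b"]) - 1), 1e-12)
  expect_error(relative_fitness(rep(0, 5)), "zero mean")
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  x <- rnorm(40)
  expect_equal(standardize(standardize(x)), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("the OLS differential equals cov(w, z) / var(z) exactly", {
  set.seed(83)
  z <- rnorm(60); w <- relative_fitness(rexp(60))
  b <- linear_differential(w, z, n_perm = 100)
  expect_equal(b$estimate, cov(w, z) / var(z), tolerance = 1e-10)
})

test_that("a perfect linear fit gives the minimal permutation p", {
  z <- seq(-2, 2, length.out = 40)
  w <- 0.5 + 0.5 * z
  res <- linear_differential(w, z, n_perm = 499, seed = 1)
  expect_equal(res$estimate, 0.5, tolerance = 1e-10)
  expect_equal(res$p, 1 / 500)
})

test_that("linear differential recovers a known surface at n = 400", {
  set.seed(85)
  z <- standardize(rnorm(400))
  tab <- data.frame(genotype = seq_along(z), year = "y", t = z)
  f <- simulate_fitness(tab, list(t = list(beta_true = 0.3, gamma_true = 0)),
                        noise_sd = 0.1, seed = 8501)
  w <- relative_fitness(f$fitness)
  b <- linear_differential(w, z, n_perm = 199, seed = 2)
  expect_gt(b$estimate, 0.25); expect_lt(b$estimate, 0.35)
  expect_lt(b$p, 0.05)
})

test_that("quadratic differential doubles the fitted curvature", {
  # exact interpolation: z = (-1, 0, 1) twice, w parabola with coef -1
  z <- rep(c(-1, 0, 1), 2)
  w <- 1.5 - z^2
  res <- quadratic_differential(w, z, n_perm = 100, seed = 1)
  expect_equal(res$estimate, -2, tolerance = 1e-10)
  expect_equal(unname(res$coefficients), c(1.5, 0, -1), tolerance = 1e-10)
  # pure linear data: curvature estimate collapses
  set.seed(87)
  z2 <- rnorm(1000); w2 <- 1 + 0.3 * z2 + rnorm(1000, 0, 0.1)
  expect_lt(abs(quadratic_differential(w2, z2, n_perm = 100, seed = 1)$estimate),
            0.05)
  # concave generator: gamma recovered near -0.4
  z3 <- standardize(rnorm(400))
  w3 <- 1 - 0.2 * z3^2 + rnorm(400, 0, 0.1)
  g <- quadratic_differential(w3, z3, n_perm = 199, seed = 3)
  expect_gt(g$estimate, -0.48); expect_lt(g$estimate, -0.32)
  expect_error(quadratic_differential(w[1:6], rep(c(0, 1), 3), n_perm = 100),
               "collinear")
})

test_that("mixed-model differential matches OLS when groups are pure noise", {
  set.seed(89)
  z <- rnorm(80); w <- 1 + 0.4 * z + rnorm(80, 0, 0.2)
  g <- factor(sample(letters[1:8], 80, TRUE))
  mm <- linear_differential(w, z, genetics = g, n_perm = 100, seed = 4)
  ols <- linear_differential(w, z, n_perm = 100, seed = 4)
  expect_lt(abs(mm$estimate - ols$estimate), 0.05)
})

test_that("selection gradients isolate the causal trait", {
  set.seed(91)
  Z <- cbind(a = rnorm(400), b = rnorm(400))
  w <- 1 + 0.3 * Z[, "a"] + rnorm(400, 0, 0.1)
  gr <- selection_gradients(w, Z, n_perm = 199, seed = 5)
  expect_lt(abs(gr$gradient[gr$trait == "a"] - 0.3), 0.05)
  expect_lt(abs(gr$gradient[gr$trait == "b"]), 0.05)
  # one-column reduction equals the differential
  g1 <- selection_gradients(w, Z[, "a", drop = FALSE], n_perm = 120, seed = 6)
  d1 <- linear_differential(w, Z[, "a"], n_perm = 120, seed = 6)
  expect_warning(linear_differential(w, Z[, "a"], n_perm = 50, seed = 6),
                 "fewer than 100")
  expect_equal(g1$gradient, d1$estimate, tolerance = 1e-10)
  # perfectly correlated traits are reported as aliased
  Z2 <- cbind(a = Z[, 1], b = Z[, 1])
  expect_error(selection_gradients(w, Z2), "aliased|collinear")
  # listwise deletion is counted
  Zm <- Z; Zm[1:7, 2] <- NA
  expect_equal(attr(selection_gradients(w, Zm, n_perm = 120), "n_dropped"), 7)
})

test_that("temporal heterogeneity test finds differing selection, not equal", {
  set.seed(93)
  n <- 300
  z <- c(standardize(rnorm(n)), standardize(rnorm(n)))
  yr <- rep(c("2009", "2010"), each = n)
  w_same <- 1 + 0.3 * z + rnorm(2 * n, 0, 0.1)
  w_diff <- 1 + ifelse(yr == "2009", 0.1, 0.4) * z + rnorm(2 * n, 0, 0.1)
  expect_lt(heterogeneity_test(w_diff, z, yr)$p, 0.001)
  # duplicating one year as the other zeroes the interaction exactly
  w1 <- w_same[yr == "2009"]; z1 <- z[yr == "2009"]
  het0 <- heterogeneity_test(c(w1, w1), c(z1, z1),
                             rep(c("2009", "2010"), each = n))
  expect_lt(abs(het0$estimate), 1e-10)
})

test_that("year-by-trait interaction test is calibrated under equal selection", {
  set.seed(95)
  hits <- 0; n_rep <- 200
  for (i in seq_len(n_rep)) {
    n <- 120
    z <- c(standardize(rnorm(n)), standardize(rnorm(n)))
    yr <- rep(c("a", "b"), each = n)
    w <- 1 + 0.3 * z + rnorm(2 * n, 0, 0.1)
    if (heterogeneity_test(w, z, yr)$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.02); expect_lt(hits / n_rep, 0.09)
})

test_that("classification applies the stabilizing/disruptive decision rule", {
  # significant positive gamma: disruptive (the leaf-drop pattern)
  expect_equal(classify_selection(0.342, 1e-4, 0.201, 1e-4, z_star = 0.5,
                                  z_range = c(-2, 2)), "disruptive")
  expect_equal(classify_selection(0.5, 0.001, 0.1, 0.4), "positive-directional")
  expect_equal(classify_selection(-0.5, 0.001, 0.1, 0.4), "negative-directional")
  expect_equal(classify_selection(0, 0.9, -0.4, 0.01, z_star = 0,
                                  z_range = c(-2, 2)), "stabilizing")
  # significant concavity with the peak outside the range is not stabilizing
  expect_equal(classify_selection(0.4, 0.01, -0.4, 0.01, z_star = 5,
                                  z_range = c(-2, 2)), "positive-directional")
  expect_equal(classify_selection(0.1, 0.5, 0.1, 0.6), "none")
  expect_error(classify_selection(0.1, 0.5, 0, 0.01), "exactly 0")
})

test_that("fitness-residual analysis reduces to the main analysis", {
  set.seed(97)
  z <- rnorm(100); w <- relative_fitness(1 + 0.3 * z + rnorm(100, 0, 0.2))
  main_l <- linear_differential(w, z, n_perm = 199, seed = 7)
  main_q <- quadratic_differential(w, z, n_perm = 199, seed = 8)
  res <- fitness_residual_check(w, z, covariates = NULL, n_perm = 199, seed = 7)
  expect_equal(res$linear$estimate, main_l$estimate, tolerance = 1e-12)
  expect_equal(res$linear$p, main_l$p)
  expect_lt(abs(mean(res$residuals)), 1e-12)
  # quadratic estimate is also preserved under mean-centering
  res_q <- fitness_residual_check(w, z, covariates = NULL, n_perm = 199, seed = 8)
  expect_equal(res_q$quadratic$estimate, main_q$estimate, tolerance = 1e-12)
})

test_that("residualizing on a confounder sharpens the differential", {
  set.seed(99)
  wins <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    g <- factor(rep(1:10, each = 30))
    u <- rnorm(10, 0, 0.6)[as.integer(g)]  # group-level fitness confounder
    z <- rnorm(300) + 0.8 * u              # trait correlated with the group
    w <- 1 + 0.3 * z + u + rnorm(300, 0, 0.1)
    naive <- cov(w, z) / var(z)
    res <- fitness_residual_check(w, z, covariates = data.frame(g = g),
                                  n_perm = 100, seed = i)
    if (abs(res$linear$estimate - 0.3) < abs(naive - 0.3)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(101)
  ps <- replicate(300, {
    z <- rnorm(50); w <- relative_fitness(rexp(50))
    linear_differential(w, z, n_perm = 120)$p
  })
  grid <- seq(0.05, 0.95, by = 0.05)
  emp <- vapply(grid, function(g) mean(ps <= g), 0)
  mc_se <- sqrt(grid * (1 - grid) / 300)
  expect_true(all(emp <= grid + 2.5 * mc_se + 1 / 100))
})
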