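test_that("degenerate variances collapse every observation to the grand mean", {
  cfg <- simulation_config(
    n_populations = 4, genotypes_per_population = 3,
    provenances_per_population = 2, ramets_per_genotype = c(2, 2),
    trait_specs = list(flat = trait_spec(grand_mean = 7, cline_slope = 0,
                                         sd_population = 0, sd_provenance = 0,
                                         sd_year = 0, sd_pop_x_year = 0,
                                         sd_genotype = 0, sd_residual = 1e-12)),
    fitness_surface = list(), seed = 3)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$observations$value, rep(7, nrow(sim$observations)),
               tolerance = 1e-6)
})

test_that("simulation is a pure function of config and seed", {
  a <- simulate_dataset(tiny_config(seed = 11))
  b <- simulate_dataset(tiny_config(seed = 11))
  c <- simulate_dataset(tiny_config(seed = 12))
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth$true_qst, b$truth$true_qst)
  expect_false(identical(a$observations$value, c$observations$value))
})

test_that("strict nesting genotype < provenance < population < deme holds", {
  sim <- simulate_dataset(tiny_config(seed = 5))
  s <- sim$structure
  expect_equal(anyDuplicated(s$genotype), 0)
  # each provenance maps to exactly one population, each population to one deme
  expect_true(all(tapply(s$population, s$provenance,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(s$deme, s$population,
                         function(v) length(unique(v))) == 1))
  ob <- sim$observations
  expect_true(all(ob$population %in% s$population))
})

test_that("one-way variance components are recovered by method of moments", {
  # 50 populations x 20 genotypes, sd_population = 2, sd_residual = 1;
  # a one-way ANOVA on genotype means must recover ~4 and ~1
  est <- sapply(21:25, function(seed) {
    cfg <- simulation_config(
      n_populations = 50, genotypes_per_population = 20,
      provenances_per_population = 1, ramets_per_genotype = c(1, 1),
      years = "2009",
      trait_specs = list(t = trait_spec(cline_slope = 0, sd_population = 2,
                                        sd_provenance = 0, sd_year = 0,
                                        sd_pop_x_year = 0, sd_genotype = 0,
                                        sd_residual = 1)),
      fitness_surface = list(), seed = seed)
    d <- simulate_dataset(cfg)$observations
    k <- 20
    msb <- k * var(tapply(d$value, d$population, mean))
    msw <- mean(tapply(d$value, d$population, var))
    c(s2_pop = (msb - msw) / k, s2_res = msw)
  })
  # the between-population moment estimator has ~20% sampling SD at 50
  # populations, so the recovery bound is checked on the replicate median
  expect_lt(abs(median(est["s2_pop", ]) - 4) / 4, 0.15)
  expect_lt(abs(median(est["s2_res", ]) - 1), 0.15)
})

test_that("missingness is applied at the configured rate", {
  cfg <- tiny_config(seed = 9)
  cfg$trait_specs$t1$missing_rate <- 0.4
  full <- tiny_config(seed = 9)
  n_full <- sum(simulate_dataset(full)$observations$trait == "t1")
  n_miss <- sum(simulate_dataset(cfg)$observations$trait == "t1")
  expect_lt(abs(n_miss / n_full - 0.6), 0.1)
})

test_that("fitness surface is recovered and degenerate cases are exact", {
  set.seed(100)
  z <- rnorm(1000)
  tab <- data.frame(genotype = paste0("G", seq_along(z)), year = "2009",
                    t = (z - mean(z)) / sd(z))
  # null surface: no correlation with the trait
  f0 <- simulate_fitness(tab, list(t = list(beta_true = 0, gamma_true = 0)),
                         noise_sd = 1, seed = 1)
  expect_lt(abs(cor(f0$fitness, tab$t)), 0.1)
  # noise-free linear surface: exact affine function of z
  f1 <- simulate_fitness(tab, list(t = list(beta_true = 1, gamma_true = 0)),
                         noise_sd = 0, seed = 1)
  fit <- lm(f1$fitness ~ tab$t)
  expect_equal(unname(coef(fit)), c(1, 1), tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-10)
  # beta recovered by OLS of relative fitness at n = 1000
  set.seed(2)
  f2 <- simulate_fitness(tab, list(t = list(beta_true = 0.3, gamma_true = 0)),
                         noise_sd = 0.1, seed = 2)
  w <- relative_fitness(f2$fitness)
  expect_lt(abs(coef(lm(w ~ tab$t))[[2]] - 0.3), 0.05)
  # unknown trait in the surface errors
  expect_error(simulate_fitness(tab, list(zz = list(beta_true = 1, gamma_true = 0))),
               "absent trait")
})

test_that("optional fitness floor keeps fitness positive and logs clipping", {
  set.seed(7)
  tab <- data.frame(genotype = paste0("G", 1:500), year = "2009",
                    t = scale(rnorm(500))[, 1])
  f <- simulate_fitness(tab, list(t = list(beta_true = 0.3, gamma_true = -0.4)),
                        noise_sd = 0.1, floor = 0.01, seed = 3)
  expect_true(all(f$fitness > 0))
  expect_gte(attr(f, "clipped_fraction"), 0)
  f2 <- simulate_fitness(tab, list(t = list(beta_true = 0.3, gamma_true = -0.4)),
                         noise_sd = 0.1, seed = 3)
  expect_true(attr(f2, "negative_fraction") >= 0)
})

test_that("Balding-Nichols markers have binomial support and target Fst", {
  cfg <- simulation_config(n_populations = 29, genotypes_per_population = 10,
                           trait_specs = list(t = trait_spec()),
                           fitness_surface = list(),
                           marker_spec = list(n_loci = 500, fst_true = 0.1,
                                              ancestral_freq_range = c(0.1, 0.9)),
                           seed = 31)
  G <- simulate_markers(cfg, seed = 31)
  expect_true(all(G %in% 0:2))
  th <- weir_cockerham_fst(G, seed = 1)$theta
  expect_gte(th, 0.08); expect_lte(th, 0.12)
  # F -> 0 limit: near-zero differentiation
  cfg$marker_spec$fst_true <- 1e-4
  G0 <- simulate_markers(cfg, seed = 32)
  expect_lt(abs(weir_cockerham_fst(G0, seed = 1)$theta), 0.01)
  expect_error(simulate_markers(list(n_loci = 10, fst_true = 1.2,
                                     ancestral_freq_range = c(0.1, 0.9)),
                                populations = rep(c("a", "b"), 5)),
               "fst_true")
})

test_that("Brownian pair generator matches its covariance model", {
  # star tree with unit branches: tips are iid bivariate normal
  star <- ape::stree(400, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  p <- simulate_bm_pair(star, rho = 0.7, seed = 41)
  expect_lt(abs(cor(p$x, p$y) - 0.7), 0.08)
  expect_lt(abs(var(p$x) - 1), 0.25)
  # rho = 0 on a structured tree: independent contrasts uncorrelated
  set.seed(42)
  tr <- ape::rtree(200)
  p0 <- simulate_bm_pair(tr, rho = 0, seed = 43)
  picx <- ape::pic(setNames(p0$x, p0$tip), tr)
  picy <- ape::pic(setNames(p0$y, p0$tip), tr)
  expect_lt(abs(cor(picx, picy)), 0.15)
  # rho = 0.9: ML (contrast-based GLS) correlation recovered
  p9 <- simulate_bm_pair(tr, rho = 0.9, seed = 44)
  r <- cor(ape::pic(setNames(p9$x, p9$tip), tr),
           ape::pic(setNames(p9$y, p9$tip), tr))
  expect_lt(abs(r - 0.9), 0.1)
  expect_error(simulate_bm_pair(tr, rho = 1.2), "rho")
})

test_that("ground-truth Qst follows the generating variance components", {
  cfg <- tiny_config(seed = 2)
  sim <- simulate_dataset(cfg)
  sp <- cfg$trait_specs$t1
  expected <- sp$sd_population^2 /
    (sp$sd_population^2 + 2 * (sp$sd_provenance^2 + sp$sd_genotype^2))
  expect_equal(unname(sim$truth$true_qst["t1"]), expected)
})

test_that("datasets round-trip to tidy text files", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(tiny_config(seed = 8))
  files <- write_dataset(sim, dir)
  expect_true(all(file.exists(files)))
  back <- read.csv(file.path(dir, "observations.csv"))
  expect_equal(nrow(back), nrow(sim$observations))
  expect_equal(back$value, sim$observations$value, tolerance = 1e-12)
})
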