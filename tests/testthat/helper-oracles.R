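# Independent oracles used across tests. These deliberately take the slow,
# dense-matrix route so they share no code with the package internals.

# Dense REML log-likelihood for y = X b + Z u + e at variance ratio lambda,
# with sigma2_e profiled out. Used to brute-force the profile criterion.
dense_reml_loglik <- function(y, X, group, lambda) {
  n <- length(y); p <- ncol(X)
  Z <- stats::model.matrix(~ 0 + group)
  V0 <- diag(n) + lambda * tcrossprod(Z)
  V0i <- solve(V0)
  XtViX <- t(X) %*% V0i %*% X
  beta <- solve(XtViX, t(X) %*% V0i %*% y)
  r <- y - X %*% beta
  rViR <- drop(t(r) %*% V0i %*% r)
  s2 <- rViR / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
            as.numeric(determinant(V0)$modulus) +
            as.numeric(determinant(XtViX)$modulus))
}

# Brute-force maximization of the dense REML profile: coarse grid over
# log-lambda followed by golden-section refinement.
grid_reml_loglik <- function(y, X, group) {
  f <- function(u) dense_reml_loglik(y, X, group, exp(u))
  us <- seq(-14, 14, length.out = 141)
  vals <- vapply(us, f, 0)
  i <- which.max(vals)
  opt <- stats::optimize(f, interval = c(us[max(1, i - 1)], us[min(141, i + 1)]),
                         maximum = TRUE, tol = 1e-10)
  best0 <- dense_reml_loglik(y, X, group, 0)
  max(opt$objective, best0)
}

# Random one-way-plus-covariate dataset for REML oracle checks.
random_lmm_instance <- function(n = 50, q = 8, seed) {
  set.seed(seed)
  g <- factor(sample(seq_len(q), n, replace = TRUE))
  while (nlevels(droplevels(g)) < 2) g <- factor(sample(seq_len(q), n, TRUE))
  x <- rnorm(n)
  y <- rnorm(q, 0, runif(1, 0, 2))[as.integer(g)] + 0.5 * x + rnorm(n)
  data.frame(y = y, x = x, g = droplevels(g))
}

# Dense bivariate Brownian log-likelihood via the explicit 2n x 2n
# covariance; oracle for the Kronecker/Cholesky implementation.
dense_bm_loglik <- function(tree, x, y, mu, rates, rho) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]; y <- y[rownames(C)]
  R <- diag(sqrt(rates)) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sqrt(rates))
  S <- kronecker(R, C)
  v <- c(x - mu[1], y - mu[2])
  ch <- chol(S)
  -0.5 * (length(v) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, v, transpose = TRUE)^2))
}

# Analytic log marginal likelihood of the conjugate normal toy:
# y_i ~ N(theta, s2) with known s2, theta ~ N(m0, t02).
conjugate_normal_logml <- function(y, s2, m0, t02) {
  n <- length(y)
  S <- diag(s2, n) + t02
  ch <- chol(S)
  v <- y - m0
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, v, transpose = TRUE)^2))
}

# Minimal nested design for the Gibbs sampler tests.
nested_sim <- function(n_pop, n_prov_per_pop, n_geno_per_prov, n_rep,
                       sd_pop, sd_prov, sd_geno, sd_res, seed, mu = 10) {
  set.seed(seed)
  pop <- rep(seq_len(n_pop), each = n_prov_per_pop * n_geno_per_prov * n_rep)
  prov <- rep(seq_len(n_pop * n_prov_per_pop), each = n_geno_per_prov * n_rep)
  gen <- rep(seq_len(n_pop * n_prov_per_pop * n_geno_per_prov), each = n_rep)
  y <- mu + rnorm(n_pop, 0, sd_pop)[pop] +
    rnorm(max(prov), 0, sd_prov)[prov] +
    rnorm(max(gen), 0, sd_geno)[gen] + rnorm(length(pop), 0, sd_res)
  data.frame(population = paste0("P", pop), provenance = paste0("V", prov),
             genotype = paste0("G", gen), value = y,
             stringsAsFactors = FALSE)
}

# Two-trait quick simulation config used in several tests.
tiny_config <- function(seed = 1, ...) {
  simulation_config(
    n_populations = 6, genotypes_per_population = 5,
    provenances_per_population = 2, ramets_per_genotype = c(2, 3),
    trait_specs = list(t1 = trait_spec(sd_population = 2),
                       t2 = trait_spec(cline_slope = -0.5)),
    fitness_surface = list(t1 = list(beta_true = 0.3, gamma_true = -0.4)),
    marker_spec = list(n_loci = 80, fst_true = 0.1,
                       ancestral_freq_range = c(0.1, 0.9)),
    bm_spec = list(rho_true = 0.6, rate_x = 1, rate_y = 1, n_tips = 30),
    seed = seed, ...)
}
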