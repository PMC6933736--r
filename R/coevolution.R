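#' Neighbor-joining tree from a genetic distance matrix
#'
#' Builds a neighbor-joining tree, clamps any negative branch lengths to
#' zero, midpoint-roots it and normalizes total height (maximum root-to-tip
#' path) to 1. Two taxa form a degenerate cherry with the distance split
#' equally.
#'
#' @param distances symmetric, zero-diagonal, non-negative matrix (or
#'   `dist`) of pairwise genetic distances with labelled taxa.
#' @return An `ape::phylo` tree.
#' @export
build_nj_tree <- function(distances) {
  D <- as.matrix(distances)
  if (anyNA(D)) stop("distance matrix contains NAs")
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(D < 0)) stop("distances must be non-negative")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 2L) {
    tree <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                          labs[1], D[1, 2] / 2,
                                          labs[2], D[1, 2] / 2))
  } else {
    dimnames(D) <- list(labs, labs)
    tree <- ape::nj(stats::as.dist(D))
    tree$edge.length[tree$edge.length < 0] <- 0
    tree <- phangorn::midpoint(tree)
  }
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(length(tree$tip.label))])
  if (h > 0) tree$edge.length <- tree$edge.length / h
  tree
}

#' Log-likelihood of a bivariate Brownian-motion model
#'
#' Matrix-normal density of two tip-value vectors under correlated Brownian
#' motion: vec(Y) ~ N(mu, R kron C) with C the shared-branch-length matrix
#' of the tree and R the 2x2 trait covariance built from the rates and
#' correlation. Computed through one Cholesky factor of C (n x n); the
#' 2n x 2n covariance is never formed.
#'
#' @param tree `phylo` tree.
#' @param x,y numeric tip vectors named by tip label (or aligned with
#'   `tree$tip.label`).
#' @param model list with `mu` (length 2), `rates` (length 2, positive) and
#'   `rho` (|rho| < 1; 0 gives the independent model).
#' @return log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, x, y, model) {
  C <- ape::vcv(tree)
  n <- nrow(C)
  if (!is.null(names(x))) x <- x[rownames(C)]
  if (!is.null(names(y))) y <- y[rownames(C)]
  stopifnot(length(x) == n, length(y) == n, !anyNA(x), !anyNA(y))
  st <- bm_suffstats(C, x, y)
  bm_loglik_from_stats(st, model$mu[1], model$mu[2],
                       model$rates[1], model$rates[2], model$rho)
}

# Sufficient statistics for fast repeated BM likelihood evaluation: the
# Gram matrix of (1, x, y) whitened by chol(C), plus log|C|. Duplicate or
# zero-length tips can make C singular; a relative jitter is applied and
# recorded.
bm_suffstats <- function(C, x = NULL, y = NULL) {
  n <- nrow(C)
  jitter <- 0
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-8 * mean(diag(C))
    ch <- chol(C + diag(jitter, n))
  }
  M <- cbind(1, x, y)
  Mt <- backsolve(ch, M, transpose = TRUE)  # chol upper: t(ch) %*% Mt = M
  list(S = crossprod(Mt), logdetC = 2 * sum(log(diag(ch))), n = n,
       jitter = jitter)
}

bm_loglik_from_stats <- function(st, mux, muy, s2x, s2y, rho) {
  if (s2x <= 0 || s2y <= 0 || abs(rho) >= 1) return(-Inf)
  S <- st$S; n <- st$n
  # whitened cross-products of residuals (x - mux 1), (y - muy 1)
  Qxx <- S[2, 2] - 2 * mux * S[1, 2] + mux^2 * S[1, 1]
  Qyy <- S[3, 3] - 2 * muy * S[1, 3] + muy^2 * S[1, 1]
  Qxy <- S[2, 3] - mux * S[1, 3] - muy * S[1, 2] + mux * muy * S[1, 1]
  one_m_r2 <- 1 - rho^2
  quad <- (Qxx / s2x + Qyy / s2y - 2 * rho * Qxy / sqrt(s2x * s2y)) / one_m_r2
  -0.5 * (2 * n * log(2 * pi) + n * log(s2x * s2y * one_m_r2) +
            2 * st$logdetC + quad)
}

#' Posterior sampling for the bivariate Brownian model
#'
#' Metropolis-within-Gibbs over (mu_x, mu_y, log sigma2_x, log sigma2_y,
#' rho), with rho fixed at 0 for the independent model. Tip data are
#' standardized internally (the reported chain is mapped back to the data
#' scale). Priors on the standardized scale: mu ~ N(0, prior_mu_sd^2),
#' log sigma2 ~ Uniform over `prior_log_rate_range`, rho ~ Uniform(-1, 1).
#' Random-walk proposals are mixed with independent prior draws so chains
#' also mix under flat (low-power) posteriors.
#'
#' @param tree `phylo` tree.
#' @param x,y tip vectors (named by tip or aligned to `tree$tip.label`).
#' @param dependent if `FALSE`, rho is fixed at 0.
#' @param n_iter iterations after `burnin`.
#' @param burnin discarded initial iterations.
#' @param seed optional integer seed.
#' @param prior_mu_sd,prior_log_rate_range prior settings (standardized
#'   scale).
#' @return Object of class `"bm_mcmc"`: `samples` (data-scale draws of
#'   mu_x, mu_y, s2x, s2y, rho), `acceptance`, `ess`, `rho_mean`,
#'   `rho_ci`. A warning is raised if ESS(rho) < 200 in the dependent
#'   model.
#' @export
mcmc_bm <- function(tree, x, y, dependent = TRUE, n_iter = 5000,
                    burnin = 1000, seed = NULL, prior_mu_sd = 5,
                    prior_log_rate_range = c(log(1e-2), log(1e2))) {
  C <- ape::vcv(tree)
  if (!is.null(names(x))) x <- x[rownames(C)]
  if (!is.null(names(y))) y <- y[rownames(C)]
  stopifnot(!anyNA(x), !anyNA(y))
  if (!is.null(seed)) set.seed(seed)
  mx <- mean(x); sx <- stats::sd(x); my <- mean(y); sy <- stats::sd(y)
  st <- bm_suffstats(C, (x - mx) / sx, (y - my) / sy)
  run <- bm_mh_chain(st, dependent, n_iter = n_iter, burnin = burnin,
                     beta = 1, prior_mu_sd = prior_mu_sd,
                     prior_log_rate_range = prior_log_rate_range)
  draws <- run$samples
  # back-transform to the data scale
  out <- cbind(mu_x = mx + sx * draws[, 1], mu_y = my + sy * draws[, 2],
               s2x = sx^2 * exp(draws[, 3]), s2y = sy^2 * exp(draws[, 4]),
               rho = draws[, 5])
  ess_vals <- apply(out, 2, ess)
  if (dependent && ess_vals["rho"] < 200)
    warning("ESS of rho below 200; consider more iterations")
  structure(list(samples = out, acceptance = run$acceptance, ess = ess_vals,
                 rho_mean = mean(out[, "rho"]),
                 rho_ci = stats::quantile(out[, "rho"], c(0.025, 0.975),
                                          names = FALSE),
                 dependent = dependent),
            class = "bm_mcmc")
}

#' @export
print.bm_mcmc <- function(x, ...) {
  cat(sprintf("Bivariate Brownian-motion posterior (%s model)\n",
              if (x$dependent) "dependent" else "independent"))
  cat(sprintf("  rho: mean %.3f, 95%% CI (%.3f, %.3f), ESS %.0f\n",
              x$rho_mean, x$rho_ci[1], x$rho_ci[2], x$ess["rho"]))
  invisible(x)
}

# One MH chain targeting prior * likelihood^beta for the (standardized)
# bivariate BM model. Proposals: component-wise random walks mixed with
# independent prior draws (probability 0.25 each update), so the chain
# covers the prior when beta is small. Returns kept draws of
# (mux, muy, log s2x, log s2y, rho), acceptance rate, and the log
# likelihood trace of the kept draws.
bm_mh_chain <- function(st, dependent, n_iter, burnin, beta,
                        prior_mu_sd, prior_log_rate_range,
                        init = NULL, rw_sd = c(0.1, 0.1, 0.25, 0.25, 0.1)) {
  lo <- prior_log_rate_range[1]; hi <- prior_log_rate_range[2]
  logprior <- function(p) {
    if (p[3] < lo || p[3] > hi || p[4] < lo || p[4] > hi) return(-Inf)
    if (dependent && abs(p[5]) >= 1) return(-Inf)
    stats::dnorm(p[1], 0, prior_mu_sd, log = TRUE) +
      stats::dnorm(p[2], 0, prior_mu_sd, log = TRUE)
    # log-uniform rates and uniform rho contribute constants
  }
  rprior1 <- function(j) {
    switch(j,
           stats::rnorm(1, 0, prior_mu_sd),
           stats::rnorm(1, 0, prior_mu_sd),
           stats::runif(1, lo, hi),
           stats::runif(1, lo, hi),
           stats::runif(1, -1, 1))
  }
  loglik <- function(p) bm_loglik_from_stats(st, p[1], p[2], exp(p[3]),
                                             exp(p[4]), p[5])
  p <- init
  if (is.null(p)) p <- c(0, 0, 0, 0, 0)
  if (!dependent) p[5] <- 0
  lp <- logprior(p); ll <- loglik(p)
  n_par <- if (dependent) 5L else 4L
  total <- burnin + n_iter
  keep <- matrix(NA_real_, n_iter, 5)
  ll_trace <- numeric(n_iter)
  acc <- 0L; tries <- 0L
  for (it in seq_len(total)) {
    for (j in seq_len(n_par)) {
      from_prior <- stats::runif(1) < 0.25
      pn <- p
      pn[j] <- if (from_prior) rprior1(j) else p[j] + stats::rnorm(1, 0, rw_sd[j])
      lpn <- logprior(pn)
      if (!is.finite(lpn)) next
      lln <- loglik(pn)
      tries <- tries + 1L
      # independence (prior) proposals need the proposal-density ratio;
      # it is non-constant only for the Gaussian mu components
      log_q_ratio <- if (from_prior && j <= 2)
        stats::dnorm(p[j], 0, prior_mu_sd, log = TRUE) -
          stats::dnorm(pn[j], 0, prior_mu_sd, log = TRUE) else 0
      if (log(stats::runif(1)) <
            (lpn + beta * lln) - (lp + beta * ll) + log_q_ratio) {
        p <- pn; lp <- lpn; ll <- lln
        acc <- acc + 1L
      }
    }
    if (it > burnin) {
      keep[it - burnin, ] <- p
      ll_trace[it - burnin] <- ll
    }
  }
  list(samples = keep, acceptance = acc / max(tries, 1L),
       loglik = ll_trace, state = p)
}
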