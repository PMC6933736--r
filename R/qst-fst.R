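#' Gibbs sampler for nested variance components
#'
#' Bayesian nested Gaussian ANOVA
#' y = mu + population + provenance(population) + genotype + residual with
#' inverse-gamma priors (the univariate inverse-Wishart) on each variance
#' and a flat prior on mu. Full conditionals are conjugate throughout, so
#' the chain is a plain Gibbs sampler. Draws are thinned post burn-in.
#'
#' @param data long observation data.frame with columns `population`,
#'   `provenance`, `genotype`, `value` (already subset to one trait), or a
#'   full table plus `trait` to subset.
#' @param trait optional trait name to subset on.
#' @param n_iter total MCMC iterations (default 50000).
#' @param burnin fraction of iterations discarded (default 0.10).
#' @param thin keep every `thin`-th draw after burn-in.
#' @param prior list with `shape` and `rate` of the inverse-gamma prior on
#'   every variance component.
#' @param transform response transform applied first: "none", "log" or
#'   "sqrt" (used to improve homoscedasticity).
#' @param seed optional integer seed; identical seeds give identical chains.
#' @return Object of class `"vc_mcmc"`: `samples` (matrix with columns
#'   `sigma2_pop`, `sigma2_prov`, `sigma2_geno`, `sigma2_resid`, `mu`),
#'   `ess` per component, and the call settings. A warning is raised when
#'   any ESS falls below 200.
#' @export
mcmc_variance_components <- function(data, trait = NULL, n_iter = 50000,
                                     burnin = 0.10, thin = 10,
                                     prior = list(shape = 0.001, rate = 0.001),
                                     transform = c("none", "log", "sqrt"),
                                     seed = NULL) {
  transform <- match.arg(transform)
  if (!is.null(trait)) data <- data[data$trait == trait, ]
  data <- data[!is.na(data$value), ]
  stopifnot(all(c("population", "provenance", "genotype", "value") %in%
                  names(data)))
  if (prior$shape <= 0 || prior$rate <= 0)
    stop("prior hyperparameters must be positive")
  if (length(unique(data$population)) < 2L) stop("need at least 2 populations")
  y <- switch(transform, none = data$value, log = log(data$value),
              sqrt = sqrt(data$value))
  if (any(!is.finite(y))) stop("transform produced non-finite values")
  if (!is.null(seed)) set.seed(seed)

  fpop <- factor(data$population)
  fprov <- factor(data$provenance)
  fgen <- factor(data$genotype)
  ip <- as.integer(fpop); iv <- as.integer(fprov); ig <- as.integer(fgen)
  np <- nlevels(fpop); nv <- nlevels(fprov); ngn <- nlevels(fgen)
  n <- length(y)
  n_p <- tabulate(ip, np); n_v <- tabulate(iv, nv); n_g <- tabulate(ig, ngn)

  a0 <- prior$shape; b0 <- prior$rate
  # initial values from crude moment splits
  s2e <- stats::var(y) / 2 + 1e-8
  s2p <- s2v <- s2g <- stats::var(y) / 6 + 1e-8
  mu <- mean(y)
  ap <- numeric(np); av <- numeric(nv); ag <- numeric(ngn)

  n_burn <- floor(n_iter * burnin)
  keep_idx <- seq(n_burn + 1L, n_iter, by = thin)
  out <- matrix(NA_real_, length(keep_idx), 5,
                dimnames = list(NULL, c("sigma2_pop", "sigma2_prov",
                                        "sigma2_geno", "sigma2_resid", "mu")))
  k <- 0L
  for (it in seq_len(n_iter)) {
    resid_base <- y - ap[ip] - av[iv] - ag[ig]
    mu <- stats::rnorm(1, mean(resid_base), sqrt(s2e / n))
    # population effects
    r <- y - mu - av[iv] - ag[ig]
    sums <- drop(rowsum(r, ip))
    prec <- n_p / s2e + 1 / s2p
    ap <- stats::rnorm(np, (sums / s2e) / prec, sqrt(1 / prec))
    # provenance effects
    r <- y - mu - ap[ip] - ag[ig]
    sums <- drop(rowsum(r, iv))
    prec <- n_v / s2e + 1 / s2v
    av <- stats::rnorm(nv, (sums / s2e) / prec, sqrt(1 / prec))
    # genotype effects
    r <- y - mu - ap[ip] - av[iv]
    sums <- drop(rowsum(r, ig))
    prec <- n_g / s2e + 1 / s2g
    ag <- stats::rnorm(ngn, (sums / s2e) / prec, sqrt(1 / prec))
    # variances
    s2p <- 1 / stats::rgamma(1, a0 + np / 2, b0 + sum(ap^2) / 2)
    s2v <- 1 / stats::rgamma(1, a0 + nv / 2, b0 + sum(av^2) / 2)
    s2g <- 1 / stats::rgamma(1, a0 + ngn / 2, b0 + sum(ag^2) / 2)
    e <- y - mu - ap[ip] - av[iv] - ag[ig]
    s2e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
    if (it > n_burn && (it - n_burn - 1L) %% thin == 0L) {
      k <- k + 1L
      out[k, ] <- c(s2p, s2v, s2g, s2e, mu)
    }
  }
  ess_vals <- apply(out, 2, ess)
  if (any(ess_vals < 200))
    warning("low effective sample size (< 200) for: ",
            paste(names(ess_vals)[ess_vals < 200], collapse = ", "))
  structure(list(samples = out, ess = ess_vals, n_iter = n_iter,
                 burnin = burnin, thin = thin, prior = prior,
                 transform = transform, trait = trait,
                 levels = c(population = np, provenance = nv,
                            genotype = ngn, n = n)),
            class = "vc_mcmc")
}

#' @export
print.vc_mcmc <- function(x, ...) {
  cat("Nested variance-component posterior (Gibbs)\n")
  cat(sprintf("  %d kept draws (%d iterations, %.0f%% burn-in, thin %d)\n",
              nrow(x$samples), x$n_iter, 100 * x$burnin, x$thin))
  print(round(rbind(median = apply(x$samples, 2, stats::median),
                    ess = x$ess), 3))
  invisible(x)
}

#' Qst posterior from nested variance-component draws
#'
#' Per draw, Qst = sigma2_between / (sigma2_between + 2 sigma2_within). The
#' between term is the population variance; the within term defaults to the
#' genetic variance within populations (provenance + genotype components,
#' the clone-mean reading of a clonal design), excluding the non-genetic
#' residual. Summaries are the posterior median and the equal-tailed 95%
#' interval.
#'
#' @param samples a `"vc_mcmc"` object or its `samples` matrix.
#' @param within character vector of components summed into sigma2_within,
#'   from c("provenance", "genotype", "residual").
#' @param trait optional trait label carried through.
#' @return Object of class `"qst_estimate"`: `qst` (posterior median),
#'   `ci` (2.5%, 97.5%), `draws`, `ess`, `n_dropped` (draws with zero
#'   denominator).
#' @export
compute_qst <- function(samples, within = c("provenance", "genotype"),
                        trait = NULL) {
  m <- if (inherits(samples, "vc_mcmc")) samples$samples else samples
  if (!nrow(m)) stop("no posterior draws")
  within <- match.arg(within, c("provenance", "genotype", "residual"),
                      several.ok = TRUE)
  cols <- c(provenance = "sigma2_prov", genotype = "sigma2_geno",
            residual = "sigma2_resid")[within]
  s2b <- m[, "sigma2_pop"]
  s2w <- rowSums(m[, cols, drop = FALSE])
  denom <- s2b + 2 * s2w
  ok <- denom > 0
  q <- s2b[ok] / denom[ok]
  if (!length(q)) stop("all draws had zero denominator")
  if (is.null(trait) && inherits(samples, "vc_mcmc")) trait <- samples$trait
  structure(list(trait = trait,
                 qst = stats::median(q),
                 ci = stats::quantile(q, c(0.025, 0.975), names = FALSE),
                 draws = q,
                 ess = ess(q),
                 n_dropped = sum(!ok)),
            class = "qst_estimate")
}

#' @export
print.qst_estimate <- function(x, ...) {
  cat(sprintf("Qst%s = %.3f, 95%% CI (%.3f, %.3f), ESS %.0f\n",
              if (is.null(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$qst, x$ci[1], x$ci[2], x$ess))
  invisible(x)
}

#' Multi-locus Weir-Cockerham Fst with a bootstrap interval
#'
#' Ratio-of-averages Weir-Cockerham (1984) theta from a diploid
#' genotype-by-locus allele-count matrix (entries 0/1/2), with a percentile
#' bootstrap over loci for the 95% confidence interval.
#'
#' @param markers integer matrix, genotypes x loci, values in {0, 1, 2}.
#' @param populations character/factor vector of population labels, one per
#'   row of `markers` (defaults to the matrix's `"population"` attribute).
#' @param n_boot bootstrap replicates over loci.
#' @param seed optional integer seed for the bootstrap.
#' @return Object of class `"fst_estimate"`: `theta`, `ci`, and the
#'   per-locus variance components `a`, `b`, `c`.
#' @export
weir_cockerham_fst <- function(markers, populations = NULL, n_boot = 1000,
                               seed = NULL) {
  if (is.null(populations)) populations <- attr(markers, "population")
  stopifnot(!is.null(populations), nrow(markers) == length(populations))
  pops <- factor(populations)
  if (nlevels(pops) < 2L) stop("need at least 2 populations")
  comp <- wc_components(markers, pops)
  poly <- comp$poly
  if (!any(poly)) stop("all loci are monomorphic; Fst undefined")
  theta <- sum(comp$a[poly]) / sum(comp$a[poly] + comp$b[poly] + comp$c[poly])
  ci <- c(NA_real_, NA_real_)
  if (sum(poly) >= 2L) {
    if (!is.null(seed)) set.seed(seed)
    ia <- comp$a[poly]; ib <- comp$b[poly]; ic <- comp$c[poly]
    L <- length(ia)
    boot <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(L, L, replace = TRUE)
      sum(ia[j]) / sum(ia[j] + ib[j] + ic[j])
    }, 0)
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  }
  structure(list(theta = theta, ci = ci,
                 a = comp$a, b = comp$b, c = comp$c,
                 n_loci = ncol(markers), n_polymorphic = sum(poly)),
            class = "fst_estimate")
}

# Weir & Cockerham (1984) per-locus variance components for a biallelic
# locus without within-individual data beyond the heterozygote count.
wc_components <- function(markers, pops) {
  L <- ncol(markers)
  r_lev <- nlevels(pops)
  a <- b <- cc <- numeric(L)
  poly <- logical(L)
  # per-population allele frequency and heterozygote frequency per locus
  for (l in seq_len(L)) {
    g <- markers[, l]
    ok <- !is.na(g)
    pk <- pops[ok]; gk <- g[ok]
    ni_all <- tabulate(pk, r_lev)
    use <- ni_all > 0
    ni <- ni_all[use]
    r <- length(ni)
    if (r < 2L) next
    agg <- rowsum(cbind(gk, as.numeric(gk == 1L)), pk)
    full <- matrix(0, r_lev, 2)
    full[match(rownames(agg), levels(pops)), ] <- agg
    sums <- full[use, 1]
    hets <- full[use, 2]
    pi <- sums / (2 * ni)
    hi <- hets / ni
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) { poly[l] <- FALSE; next }
    poly[l] <- TRUE
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[l] <- hbar / 2
  }
  list(a = a, b = b, c = cc, poly = poly)
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %.4f, 95%% bootstrap CI (%.4f, %.4f)\n",
              x$theta, x$ci[1], x$ci[2]))
  cat(sprintf("  %d loci (%d polymorphic)\n", x$n_loci, x$n_polymorphic))
  invisible(x)
}

#' Classify trait divergence against the neutral expectation
#'
#' Divergent selection is inferred only when both the Qst point estimate and
#' the entire Qst 95% credible interval lie above the upper bound of the
#' Fst interval; any overlap is conservatively reported as consistent with
#' drift.
#'
#' @param qst a `"qst_estimate"` (or list with `qst` and `ci`).
#' @param fst a `"fst_estimate"` (or list with `ci`), or a length-2 numeric
#'   vector giving the neutral interval directly.
#' @return `"divergent_selection"` or `"consistent_with_drift"`.
#' @export
classify_divergence <- function(qst, fst) {
  fst_ci <- if (is.numeric(fst)) fst else fst$ci
  stopifnot(length(fst_ci) == 2L, !anyNA(fst_ci), fst_ci[1] <= fst_ci[2])
  if (qst$qst > fst_ci[2] && qst$ci[1] > fst_ci[2])
    "divergent_selection" else "consistent_with_drift"
}
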