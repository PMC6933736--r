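#' Relative fitness within a grouping
#'
#' w = W / mean(W), computed within each level of `grouping` (typically the
#' measurement year), so mean relative fitness is 1 in every group.
#'
#' @param W non-negative fitness values.
#' @param grouping optional factor (e.g. year); `NULL` treats all values as
#'   one group.
#' @return numeric vector of relative fitness.
#' @export
relative_fitness <- function(W, grouping = NULL) {
  if (any(W < 0, na.rm = TRUE))
    warning("negative fitness values supplied; relative fitness is still ",
            "defined but check the fitness construction")
  if (is.null(grouping)) grouping <- rep(1L, length(W))
  means <- stats::ave(W, grouping, FUN = function(v) mean(v, na.rm = TRUE))
  if (any(means <= 0, na.rm = TRUE)) stop("zero mean fitness in a group")
  W / means
}

#' Standardize trait values (z-scores) within a grouping
#'
#' z = (x - mean) / sd computed within each group, with the sample (n - 1)
#' standard deviation.
#'
#' @param x numeric trait values.
#' @param grouping optional factor (e.g. year).
#' @return numeric vector of z-scores.
#' @export
standardize <- function(x, grouping = NULL) {
  if (is.null(grouping)) grouping <- rep(1L, length(x))
  s <- stats::ave(x, grouping, FUN = function(v) stats::sd(v, na.rm = TRUE))
  if (any(s == 0, na.rm = TRUE))
    stop("constant trait within a group: standardization undefined")
  m <- stats::ave(x, grouping, FUN = function(v) mean(v, na.rm = TRUE))
  (x - m) / s
}

# Permutation p-value with the add-one estimator (two-sided on |stat|).
perm_pvalue <- function(obs, perm) (1 + sum(abs(perm) >= abs(obs))) / (length(perm) + 1)

# OLS coefficients for many permuted responses at once: returns the
# requested coefficient for each column of Wmat.
perm_ols_coef <- function(X, Wmat, coef_index) {
  B <- solve(crossprod(X), crossprod(X, Wmat))
  B[coef_index, ]
}

#' Linear selection differential with permutation significance
#'
#' beta is the coefficient of the standardized trait z in a regression of
#' relative fitness w on z, optionally with a random genetic-group
#' intercept (the mixed-model form). Significance comes from a seeded
#' permutation test: w is permuted across genotypes and the add-one
#' two-sided p-value reported.
#'
#' @param w relative fitness per genotype (one year).
#' @param z standardized trait values, aligned with `w`.
#' @param genetics optional factor of genetic groups for a random
#'   intercept; `NULL` gives the OLS form (with a fast vectorized
#'   permutation path).
#' @param n_perm number of permutations (default 5000; a warning is raised
#'   below 100).
#' @param seed optional integer seed.
#' @return Object of class `"selection_diff"`: `estimate` (beta), `p`,
#'   `coefficients` of the underlying fit, `n`, `n_perm`, `type = "linear"`.
#' @export
linear_differential <- function(w, z, genetics = NULL, n_perm = 5000,
                                seed = NULL) {
  ok <- stats::complete.cases(w, z)
  w <- w[ok]; z <- z[ok]
  if (!is.null(genetics)) genetics <- droplevels(factor(genetics[ok]))
  n <- length(w)
  if (n < 5L) stop("need at least 5 paired observations")
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  d <- data.frame(w = w, z = z)
  if (is.null(genetics)) {
    X <- cbind(1, z)
    fit <- stats::lm.fit(X, w)
    beta <- fit$coefficients[2]
    Wmat <- vapply(seq_len(n_perm), function(i) w[sample.int(n)],
                   numeric(n))
    perm <- perm_ols_coef(X, Wmat, 2L)
    coefs <- stats::setNames(fit$coefficients, c("(Intercept)", "z"))
  } else {
    d$g <- genetics
    fit <- fit_reml(w ~ z, d, random = ~ g)
    beta <- fit$coefficients["z"]
    perm <- vapply(seq_len(n_perm), function(i) {
      d$w <- w[sample.int(n)]
      fit_reml(w ~ z, d, random = ~ g)$coefficients["z"]
    }, 0)
    coefs <- fit$coefficients
  }
  structure(list(estimate = unname(beta), p = perm_pvalue(beta, perm),
                 coefficients = coefs, n = n, n_perm = n_perm,
                 type = "linear"),
            class = "selection_diff")
}

#' Quadratic selection differential with permutation significance
#'
#' Fits w ~ z + z^2 (plus an optional random genetic-group intercept) and
#' reports gamma = 2 times the quadratic coefficient, following the
#' convention that doubles the quadratic regression estimate to put it on
#' the selection-differential scale. The permutation test permutes w and
#' recomputes gamma.
#'
#' @inheritParams linear_differential
#' @return Object of class `"selection_diff"`: `estimate` (gamma), `p`,
#'   `coefficients` (including the linear term), `z_star` (stationary point
#'   -b_z / (2 b_z2) of the fitted parabola), `type = "quadratic"`.
#' @export
quadratic_differential <- function(w, z, genetics = NULL, n_perm = 5000,
                                   seed = NULL) {
  ok <- stats::complete.cases(w, z)
  w <- w[ok]; z <- z[ok]
  if (!is.null(genetics)) genetics <- droplevels(factor(genetics[ok]))
  n <- length(w)
  if (n < 6L) stop("need at least 6 paired observations")
  if (length(unique(z)) < 3L) stop("z and z^2 are collinear on this support")
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genetics)) {
    X <- cbind(1, z, z^2)
    fit <- stats::lm.fit(X, w)
    bq <- fit$coefficients[3]
    Wmat <- vapply(seq_len(n_perm), function(i) w[sample.int(n)], numeric(n))
    perm <- 2 * perm_ols_coef(X, Wmat, 3L)
    coefs <- stats::setNames(fit$coefficients, c("(Intercept)", "z", "z2"))
  } else {
    d <- data.frame(w = w, z = z, z2 = z^2, g = genetics)
    fit <- fit_reml(w ~ z + z2, d, random = ~ g)
    bq <- fit$coefficients["z2"]
    perm <- vapply(seq_len(n_perm), function(i) {
      d$w <- w[sample.int(n)]
      2 * fit_reml(w ~ z + z2, d, random = ~ g)$coefficients["z2"]
    }, 0)
    coefs <- fit$coefficients
  }
  gamma <- unname(2 * bq)
  z_star <- if (bq != 0) unname(-coefs[2] / (2 * bq)) else NA_real_
  structure(list(estimate = gamma, p = perm_pvalue(gamma, perm),
                 coefficients = coefs, z_star = z_star, n = n,
                 n_perm = n_perm, type = "quadratic"),
            class = "selection_diff")
}

#' @export
print.selection_diff <- function(x, ...) {
  lab <- if (x$type == "linear") "beta" else "gamma"
  cat(sprintf("%s selection differential: %s = %.4f, permutation p = %.4g (n = %d, %d perms)\n",
              x$type, lab, x$estimate, x$p, x$n, x$n_perm))
  invisible(x)
}

#' Multivariate linear selection gradients
#'
#' Multiple regression of relative fitness on all standardized traits
#' simultaneously (complete cases only; the number dropped is reported).
#' Permutation p-values permute w against whole trait rows.
#'
#' @param w relative fitness per genotype.
#' @param Z matrix or data.frame of standardized traits (columns = traits).
#' @param n_perm permutations.
#' @param seed optional integer seed.
#' @return data.frame `trait`, `gradient`, `p`, with attribute
#'   `n_dropped` (incomplete rows removed).
#' @export
selection_gradients <- function(w, Z, n_perm = 5000, seed = NULL) {
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("trait", seq_len(ncol(Z)))
  ok <- stats::complete.cases(w, Z)
  n_dropped <- sum(!ok)
  w <- w[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(w)
  if (n < ncol(Z) + 2L) stop("too few complete cases for the gradient model")
  X <- cbind(`(Intercept)` = 1, Z)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("collinear traits; aliased: ", paste(aliased, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  bhat <- qr.coef(qrx, w)
  Wmat <- vapply(seq_len(n_perm), function(i) w[sample.int(n)], numeric(n))
  Bperm <- solve(crossprod(X), crossprod(X, Wmat))  # p x n_perm
  grads <- bhat[-1L]
  pvals <- vapply(seq_along(grads), function(j)
    perm_pvalue(grads[j], Bperm[j + 1L, ]), 0)
  out <- data.frame(trait = colnames(Z), gradient = unname(grads), p = pvals,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Temporal heterogeneity of directional selection
#'
#' Pools the two years and tests the year-by-trait interaction in
#' w ~ z * year (optionally with a random genetic-group intercept): a
#' significant interaction rejects the null that the linear selection
#' differentials are equivalent between years.
#'
#' @param w relative fitness (relativized within year).
#' @param z standardized trait (within year).
#' @param year factor of year labels (exactly two levels).
#' @param genetics optional factor for a random intercept.
#' @return List with `estimate` (interaction coefficient), `F`, `df_num`,
#'   `df_den`, `p`.
#' @export
heterogeneity_test <- function(w, z, year, genetics = NULL) {
  ok <- stats::complete.cases(w, z, year)
  w <- w[ok]; z <- z[ok]; year <- droplevels(factor(year[ok]))
  if (nlevels(year) != 2L) stop("need exactly two years")
  d <- data.frame(w = w, z = z, year = year)
  if (!is.null(genetics)) {
    d$g <- droplevels(factor(genetics[ok]))
    fit <- fit_reml(w ~ z + year + z:year, d, random = ~ g)
  } else {
    fit <- fit_reml(w ~ z + year + z:year, d)
  }
  an <- anova(fit)
  row <- an[an$term == "z:year", ]
  int_idx <- which(fit$assign == match("z:year", attr(fit$terms, "term.labels")))
  list(estimate = unname(fit$coefficients[int_idx]),
       F = row$F, df_num = row$df_num, df_den = row$df_den, p = row$p)
}

#' Classify the mode of selection on a trait
#'
#' Applies the standard decision rule: a significant negative gamma whose
#' fitted peak z* lies inside the observed standardized trait range is
#' stabilizing selection; a significant positive gamma is disruptive; an
#' otherwise significant beta gives positive/negative directional
#' selection; anything else is "none".
#'
#' @param beta,p_beta linear differential and its p-value.
#' @param gamma,p_gamma quadratic differential and its p-value (may be NA).
#' @param z_star stationary point of the fitted quadratic.
#' @param z_range observed range of the standardized trait, length 2.
#' @param alpha significance level.
#' @return One of "stabilizing", "disruptive", "positive-directional",
#'   "negative-directional", "none".
#' @export
classify_selection <- function(beta, p_beta, gamma = NA, p_gamma = NA,
                               z_star = NA, z_range = c(-Inf, Inf),
                               alpha = 0.05) {
  if (!is.na(gamma) && !is.na(p_gamma) && p_gamma <= alpha) {
    if (gamma == 0) stop("gamma exactly 0 cannot be significant")
    if (gamma > 0) return("disruptive")
    if (!is.na(z_star) && z_star >= z_range[1] && z_star <= z_range[2])
      return("stabilizing")
    # significant curvature with an exterior peak: directional by beta
  }
  if (!is.na(p_beta) && p_beta <= alpha)
    return(if (beta > 0) "positive-directional" else "negative-directional")
  "none"
}

#' Robustness twin of the selection analysis on fitness residuals
#'
#' Residualizes relative fitness on a covariate set (default: genetic-group
#' intercepts) and reruns the linear and quadratic differential machinery
#' on the residuals. With an empty covariate set the residualization only
#' removes the mean, and the analysis equals the main one.
#'
#' @param w relative fitness.
#' @param z standardized trait.
#' @param covariates data.frame of covariates for the residual model, or
#'   `NULL` for intercept-only.
#' @param n_perm,seed passed to the differential functions.
#' @return List with `linear` and `quadratic` `"selection_diff"` objects
#'   and the residuals used.
#' @export
fitness_residual_check <- function(w, z, covariates = NULL, n_perm = 5000,
                                   seed = NULL) {
  if (is.null(covariates)) {
    res <- w - mean(w, na.rm = TRUE)
  } else {
    covariates <- as.data.frame(covariates)
    res <- stats::residuals(stats::lm(w ~ ., data = covariates,
                                      na.action = stats::na.exclude))
  }
  list(linear = linear_differential(res, z, n_perm = n_perm, seed = seed),
       quadratic = quadratic_differential(res, z, n_perm = n_perm, seed = seed),
       residuals = res)
}
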