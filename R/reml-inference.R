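#' Type-III tests of fixed effects with Satterthwaite denominator df
#'
#' Wald F statistics for each fixed-effect term, adjusting for all other
#' terms (valid as type-III tests because [fit_reml()] codes factors with
#' sum-to-zero contrasts). The denominator degrees of freedom use the
#' Satterthwaite approximation: the covariance of each independent contrast
#' is differentiated with respect to the variance components (numerically)
#' and combined with the inverse curvature of the REML surface; multi-df
#' terms combine the per-contrast df through their harmonic-type mean. For a
#' model without a random term, the exact residual df n - p is used.
#'
#' @param object a `"reml_fit"`.
#' @param ... unused.
#' @return data.frame with one row per term: `term`, `F`, `df_num`,
#'   `df_den`, `p`.
#' @export
anova.reml_fit <- function(object, ...) {
  labs <- attr(object$terms, "term.labels")
  if (!length(labs)) stop("model has no fixed-effect terms to test")
  asgn <- object$assign
  Vtheta <- if (!is.null(object$group)) reml_vcov_theta(object) else NULL
  rows <- lapply(seq_along(labs), function(ti) {
    idx <- which(asgn == ti)
    q <- length(idx)
    b <- object$coefficients[idx]
    Vb <- object$vcov[idx, idx, drop = FALSE]
    Fstat <- drop(crossprod(b, solve(Vb, b))) / q
    if (is.null(object$group)) {
      df_den <- object$n - object$p
    } else {
      df_den <- satterthwaite_df(object, idx, Vtheta)
    }
    data.frame(term = labs[ti], F = Fstat, df_num = q, df_den = df_den,
               p = stats::pf(Fstat, q, df_den, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_reml", "data.frame")
  out
}

#' @export
print.anova_reml <- function(x, digits = 4, ...) {
  cat("Type-III tests of fixed effects (Satterthwaite df)\n")
  y <- x
  y$F <- signif(y$F, digits); y$df_den <- round(y$df_den, 1)
  y$p <- format.pval(y$p, digits = 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# Asymptotic covariance of (sigma2_u, sigma2_e): inverse of the negative
# numerical Hessian of the REML log-likelihood. At a boundary estimate the
# Hessian is singular; callers fall back to residual df.
reml_vcov_theta <- function(fit) {
  th <- c(max(fit$sigma2["random"], 0), fit$sigma2["residual"])
  h <- pmax(1e-4 * th, 1e-8)
  if (th[1] <= 1e-10) return(NULL)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (reml_loglik_at(fit, th + ei + ej) -
                  reml_loglik_at(fit, th + ei - ej) -
                  reml_loglik_at(fit, th - ei + ej) +
                  reml_loglik_at(fit, th - ei - ej)) / (4 * h[i] * h[j])
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (!is.null(V) && any(!is.finite(V))) V <- NULL
  V
}

# Satterthwaite denominator df for the Wald F of the coefficients `idx`.
# Eigen-decomposes the contrast covariance into independent 1-df contrasts,
# computes each contrast's df from the delta-method variance of its
# variance estimate, and combines (Fai-Cornelius style, as in lmerTest).
satterthwaite_df <- function(fit, idx, Vtheta) {
  n_res <- fit$n - fit$p
  if (is.null(Vtheta)) return(n_res)
  th <- c(fit$sigma2["random"], fit$sigma2["residual"])
  q <- length(idx)
  Vb <- fit$vcov[idx, idx, drop = FALSE]
  ed <- eigen(Vb, symmetric = TRUE)
  dfs <- numeric(q)
  h <- pmax(1e-4 * th, 1e-8)
  for (i in seq_len(q)) {
    u <- ed$vectors[, i]
    phi <- function(theta) {
      Cb <- beta_cov_at(fit, theta)[idx, idx, drop = FALSE]
      drop(crossprod(u, Cb %*% u))
    }
    g <- c((phi(th + c(h[1], 0)) - phi(th - c(h[1], 0))) / (2 * h[1]),
           (phi(th + c(0, h[2])) - phi(th - c(0, h[2]))) / (2 * h[2]))
    denom <- drop(crossprod(g, Vtheta %*% g))
    dfs[i] <- if (denom > 0) 2 * ed$values[i]^2 / denom else n_res
  }
  dfs <- pmin(pmax(dfs, 1 + 1e-6), n_res)
  if (q == 1L) return(dfs)
  E <- sum(dfs / (dfs - 2) * (dfs > 2))
  if (E <= q) return(n_res)
  2 * E / (E - q)
}

#' Likelihood-ratio test for the random intercept
#'
#' Compares a full REML fit with its reduction without the random term
#' (identical fixed structure). The statistic 2 (ll_full - ll_reduced) is
#' clipped at zero and referred to a chi-square with 1 df; because the null
#' value sigma2_u = 0 lies on the boundary of the parameter space this
#' reference is conservative.
#'
#' @param full `"reml_fit"` with the random term.
#' @param reduced `"reml_fit"` without it, same fixed formula.
#' @return List with `chisq`, `df`, `p`.
#' @export
lrt_random <- function(full, reduced) {
  stopifnot(inherits(full, "reml_fit"), inherits(reduced, "reml_fit"))
  if (!identical(attr(full$terms, "term.labels"),
                 attr(reduced$terms, "term.labels")))
    stop("full and reduced models have different fixed structures")
  if (is.null(full$group) || !is.null(reduced$group))
    stop("'full' must contain the random term and 'reduced' must not")
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Least-squares (OLS) means for a fixed-effect term
#'
#' Model-based marginal means: predictions are formed on the full reference
#' grid (the cross of all factor levels in the fixed part) and averaged with
#' equal weight over the levels of every other factor. Intervals come from
#' the fixed-effect covariance with the residual-based t reference.
#'
#' @param fit a `"reml_fit"`.
#' @param term character, a factor term in the fixed part; an interaction is
#'   written `"a:b"`, giving one mean per combination.
#' @param level confidence level for the intervals.
#' @return data.frame with the term's factor columns, `lsmean`, `se`,
#'   `lower`, `upper`, and a logical `estimable`.
#' @export
ls_means <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "reml_fit"))
  facs <- strsplit(term, ":", fixed = TRUE)[[1]]
  mm_facs <- names(fit$model)[sapply(fit$model, is.factor)]
  if (!all(facs %in% mm_facs))
    stop("term '", term, "' does not name factor(s) in the model")
  old_opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_opts), add = TRUE)
  xlev <- lapply(fit$model[, mm_facs, drop = FALSE], levels)
  grid <- do.call(expand.grid, c(xlev, list(stringsAsFactors = TRUE)))
  # continuous covariates, if any, are held at their mean
  nums <- setdiff(names(fit$model)[-1L], mm_facs)
  for (nm in nums) grid[[nm]] <- mean(fit$model[[nm]])
  tt <- stats::delete.response(fit$terms)
  Xg <- stats::model.matrix(tt, stats::model.frame(tt, grid, xlev = xlev))
  key <- interaction(grid[, facs, drop = FALSE], drop = FALSE, sep = ":")
   A <- rowsum(Xg, key) / as.vector(table(key))
  est <- drop(A %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((A %*% fit$vcov) * A), 0))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$n - fit$p)
  lv <- do.call(rbind, strsplit(rownames(A), ":", fixed = TRUE))
  out <- as.data.frame(lv, stringsAsFactors = FALSE)
  names(out) <- facs
  out$lsmean <- est
  out$se <- se
  out$lower <- est - tcrit * se
  out$upper <- est + tcrit * se
  # a cell is non-estimable when no data fall in it under the nesting
  obs_key <- interaction(fit$model[, facs, drop = FALSE], drop = FALSE, sep = ":")
  out$estimable <- rownames(A) %in% levels(droplevels(obs_key))
  rownames(out) <- NULL
  out
}

#' Extract genotype BLUPs from a REML fit
#'
#' Best linear unbiased predictions of the random intercepts: the group mean
#' of the marginal residuals shrunk by
#' sigma2_u / (sigma2_u + sigma2_e / n_g).
#'
#' @param fit a `"reml_fit"` with a random term.
#' @return Named numeric vector, one BLUP per group level.
#' @export
extract_blups <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(fit$group)) stop("model has no random term")
  fit$blups
}
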