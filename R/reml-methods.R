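#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat("  formula: ", deparse(stats::formula(x$terms)), "\n")
  if (!is.null(x$group))
    cat("  random intercept:", nlevels(x$group), "groups\n")
  cat(sprintf("  n = %d, REML logLik = %.*f, AIC = %.*f\n",
              x$n, digits, x$logLik, digits, x$aic))
  cat("  variance components:\n")
  print(round(x$sigma2, digits))
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = object$coefficients / se)
  out <- list(coefficients = tab, sigma2 = object$sigma2,
              lambda = object$lambda, logLik = object$logLik,
              aic = object$aic, r_squared = object$r_squared,
              n = object$n, boundary = object$boundary,
              formula = stats::formula(object$terms),
              n_groups = if (is.null(object$group)) NA_integer_
                         else nlevels(object$group))
  class(out) <- "summary.reml_fit"
  out
}

#' @export
print.summary.reml_fit <- function(x, digits = 4, ...) {
  cat("REML linear mixed model:", deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nsigma2 (random) = %.4g, sigma2 (residual) = %.4g\n",
              x$sigma2["random"], x$sigma2["residual"]))
  cat(sprintf("REML logLik = %.4f, AIC = %.4f, R2 = %.3f, n = %d\n",
              x$logLik, x$aic, x$r_squared, x$n))
  if (isTRUE(x$boundary)) cat("note: variance estimate on the boundary\n")
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$coefficients

#' @export
vcov.reml_fit <- function(object, ...) object$vcov

#' @export
fitted.reml_fit <- function(object, ...) object$fitted

#' @export
residuals.reml_fit <- function(object, ...) object$residuals

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logLik, df = object$p + if (is.null(object$group)) 1 else 2,
            nobs = object$n, class = "logLik")
}

#' Predict from a REML mixed-model fit
#'
#' @param object a `"reml_fit"`.
#' @param newdata optional data.frame; defaults to the training frame.
#' @param level 0 for population-level (fixed effects only), 1 to add the
#'   BLUP of known groups (unknown groups get 0).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.reml_fit <- function(object, newdata = NULL, level = 0, ...) {
  old_opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_opts), add = TRUE)
  if (is.null(newdata)) {
    pred <- drop(object$X %*% object$coefficients)
    if (level > 0 && !is.null(object$group))
      pred <- pred + object$blups[as.integer(object$group)]
    return(pred)
  }
  tt <- stats::delete.response(object$terms)
  # align factor levels with the training frame
  xlev <- lapply(object$model[, sapply(object$model, is.factor), drop = FALSE],
                 levels)
  mf <- stats::model.frame(tt, newdata, xlev = xlev)
  Xn <- stats::model.matrix(tt, mf)
  pred <- drop(Xn %*% object$coefficients[colnames(Xn)])
  if (level > 0 && !is.null(object$group)) {
    gvar <- all.vars(object$call$random)
    if (length(gvar) == 1L && gvar %in% names(newdata)) {
      u <- object$blups[as.character(newdata[[gvar]])]
      u[is.na(u)] <- 0
      pred <- pred + u
    }
  }
  pred
}

#' Simulate responses from a fitted REML model
#'
#' Draws new random-intercept values and residuals at the estimated variance
#' components, keeping the fixed-effect predictions.
#'
#' @param object a `"reml_fit"`.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.reml_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- drop(object$X %*% object$coefficients)
  n <- object$n
  out <- matrix(0, n, nsim)
  for (j in seq_len(nsim)) {
    e <- stats::rnorm(n, 0, sqrt(object$sigma2["residual"]))
    if (!is.null(object$group)) {
      u <- stats::rnorm(nlevels(object$group), 0,
                        sqrt(object$sigma2["random"]))
      e <- e + u[as.integer(object$group)]
    }
    out[, j] <- mu + e
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}
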