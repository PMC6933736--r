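#' Fit a random-intercept linear mixed model by REML
#'
#' Fits y = X beta + Z u + e with a single random intercept grouping factor,
#' u ~ N(0, sigma2_u I), e ~ N(0, sigma2_e I). The variance ratio
#' lambda = sigma2_u / sigma2_e is profiled out of the REML criterion and
#' located by bounded one-dimensional optimization on the log scale
#' (coarse bracketing grid followed by golden-section refinement, tolerance
#' 1e-8 on lambda), with the boundary lambda = 0 checked explicitly. Fixed
#' effects are the GLS solution at the optimum. All factors in the fixed
#' formula are coded with sum-to-zero contrasts, as required for type-III
#' tests.
#'
#' The grouped structure enters the profiled criterion only through
#' closed-form Woodbury identities, so each evaluation costs
#' O(n p + q p^2 + p^3) for n observations, q groups and p fixed
#' coefficients; no n-by-n matrix is ever formed.
#'
#' @param fixed two-sided model formula for the fixed effects, e.g.
#'   `value ~ year + year:population`.
#' @param data data.frame containing all model variables.
#' @param random one-sided formula naming the random grouping factor, e.g.
#'   `~ genotype`, or `NULL` for an ordinary (REML-criterion) linear model.
#' @param lambda_interval search interval for log(lambda).
#' @return Object of class `"reml_fit"`: coefficients, their covariance,
#'   `sigma2` (named `random`, `residual`), `lambda`, REML log-likelihood,
#'   BLUPs, fitted values (conditional on the BLUPs), residuals, AIC
#'   (REML criterion + 2 parameters), and R-squared (squared correlation of
#'   fitted and observed).
#' @seealso [anova.reml_fit()], [lrt_random()], [ls_means()],
#'   [extract_blups()]
#' @examples
#' d <- data.frame(g = rep(letters[1:3], each = 2), y = c(1, 3, 5, 7, 9, 11))
#' fit <- fit_reml(y ~ 1, d, random = ~ g)
#' fit$sigma2  # balanced one-way: matches ANOVA method-of-moments (15, 2)
#' @export
fit_reml <- function(fixed, data, random = NULL,
                     lambda_interval = c(-18, 18)) {
  stopifnot(inherits(fixed, "formula"), is.data.frame(data))
  mf_call <- match.call()
  gv <- character(0)
  if (!is.null(random)) {
    gv <- all.vars(random)
    if (length(gv) != 1L) stop("random must name exactly one grouping factor")
    if (!gv %in% names(data)) stop("random factor '", gv, "' not found in data")
  }
  vars <- unique(c(all.vars(fixed), gv))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) stop("variables not found in data: ",
                                 paste(missing_vars, collapse = ", "))
  dat <- droplevels(stats::na.omit(data[, vars, drop = FALSE]))
  for (v in vars) if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])

  # sum-to-zero contrasts on every factor in the fixed part
  old_opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_opts), add = TRUE)
  terms_obj <- stats::terms(fixed, data = dat)
  mf <- stats::model.frame(terms_obj, dat)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(terms_obj, mf)
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  if (n <= p) stop("not enough observations for REML (n <= p)")

  group <- NULL
  if (length(gv)) {
    group <- droplevels(as.factor(dat[[gv]]))
    if (nlevels(group) < 2L) stop("need at least 2 levels in the random factor")
  }

  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)

  if (is.null(group)) {
    beta <- qr.coef(qrX, y)
    r <- y - drop(X %*% beta)
    rss <- sum(r^2)
    sigma2_e <- rss / (n - p)
    ldXtX <- as.numeric(determinant(XtX, logarithm = TRUE)$modulus)
    ll <- if (sigma2_e > 0)
      -0.5 * ((n - p) * (log(2 * pi * sigma2_e) + 1) + ldXtX) else Inf
    vcov_beta <- sigma2_e * chol2inv(qr.R(qrX))
    dimnames(vcov_beta) <- list(colnames(X), colnames(X))
    fit <- list(coefficients = stats::setNames(drop(beta), colnames(X)),
                vcov = vcov_beta,
                sigma2 = c(random = NA_real_, residual = sigma2_e),
                lambda = NA_real_, logLik = ll,
                blups = NULL, group = NULL,
                fitted = drop(X %*% beta), residuals = r,
                n = n, p = p, y = y, X = X,
                assign = attr(X, "assign"), terms = terms_obj,
                model = mf, boundary = sigma2_e == 0,
                call = mf_call)
  } else {
    ng <- as.vector(table(group))
    Xg <- rowsum(X, group)            # q x p, Z'X
    yg <- drop(rowsum(y, group))      # Z'y (group sums)

    profile <- function(lambda) {
      d <- lambda / (1 + lambda * ng)
      XtViX <- XtX - crossprod(Xg * sqrt(d))
      XtViy <- Xty - drop(crossprod(Xg, d * yg))
      ch <- tryCatch(chol(XtViX), error = function(e) NULL)
      if (is.null(ch)) return(list(obj = Inf))
      beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
      yViy <- yty - sum(d * yg^2)
      rViR <- max(yViy - sum(beta * XtViy), 0)
      ldV <- sum(log1p(lambda * ng))
      ldXtViX <- 2 * sum(log(diag(ch)))
      obj <- (n - p) * log(max(rViR, 1e-300)) + ldV + ldXtViX
      list(obj = obj, beta = beta, rViR = rViR, ldV = ldV,
           ldXtViX = ldXtViX, chol = ch, d = d)
    }

    # analytic derivative of the profiled criterion in lambda; lets the
    # optimum be polished far beyond golden-section (sqrt(eps)) accuracy
    score <- function(lambda) {
      pr <- profile(lambda)
      if (!is.finite(pr$obj)) return(NA_real_)
      shr <- 1 / (1 + lambda * ng)
      Bv <- pr$chol
      B <- Xg * shr                       # Z' V0^-1 X
      zpy <- (yg - drop(Xg %*% pr$beta)) * shr  # Z' P y
      W <- forwardsolve(t(Bv), t(B))      # solve chol' for trace term
      -(n - p) * sum(zpy^2) / max(pr$rViR, 1e-300) +
        sum(ng * shr) - sum(W^2)
    }
    # coarse grid on log(lambda), then golden-section bracketing and a
    # root-polish of the score; the lambda = 0 boundary is compared last
    us <- seq(lambda_interval[1], lambda_interval[2], length.out = 41L)
    vals <- vapply(us, function(u) profile(exp(u))$obj, 0)
    i0 <- which.min(vals)
    lo <- us[max(1L, i0 - 1L)]; hi <- us[min(length(us), i0 + 1L)]
    opt <- stats::optimize(function(u) profile(exp(u))$obj,
                           interval = c(lo, hi), tol = 1e-10)
    lambda <- exp(opt$minimum)
    s_lo <- score(exp(lo)); s_hi <- score(exp(hi))
    if (is.finite(s_lo) && is.finite(s_hi) && s_lo < 0 && s_hi > 0) {
      root <- tryCatch(
        stats::uniroot(score, interval = c(exp(lo), exp(hi)),
                       f.lower = s_lo, f.upper = s_hi,
                       tol = 1e-12 * (1 + lambda)),
        error = function(e) NULL)
      if (!is.null(root)) lambda <- root$root
    }
    best <- profile(lambda)
    bound <- profile(0)
    boundary <- FALSE
    if (bound$obj <= best$obj + 1e-10) {
      lambda <- 0; best <- bound; boundary <- TRUE
    }
    if (!is.finite(best$obj)) stop("REML profile optimization failed to converge;\n",
                                   "  profile trace: ",
                                   paste(sprintf("(%.2f, %.4g)", us, vals),
                                         collapse = " "))

    sigma2_e <- best$rViR / (n - p)
    sigma2_u <- lambda * sigma2_e
    beta <- best$beta
    r_marg <- y - drop(X %*% beta)
    u <- drop(best$d * rowsum(r_marg, group))  # shrunken group residual sums
    fitted <- drop(X %*% beta) + u[as.integer(group)]
    ll <- if (sigma2_e > 0)
      -0.5 * ((n - p) * (log(2 * pi * sigma2_e) + 1) + best$ldV +
                best$ldXtViX) else Inf
    vcov_beta <- sigma2_e * chol2inv(best$chol)
    dimnames(vcov_beta) <- list(colnames(X), colnames(X))
    fit <- list(coefficients = stats::setNames(drop(beta), colnames(X)),
                vcov = vcov_beta,
                sigma2 = c(random = sigma2_u, residual = sigma2_e),
                lambda = lambda, logLik = ll,
                blups = stats::setNames(u, levels(group)), group = group,
                fitted = fitted, residuals = y - fitted,
                n = n, p = p, y = y, X = X,
                Xg = Xg, yg = yg, ng = ng, XtX = XtX, Xty = Xty, yty = yty,
                assign = attr(X, "assign"), terms = terms_obj,
                model = mf, boundary = boundary,
                call = mf_call)
  }
  fit$aic <- -2 * fit$logLik + 2 * (p + if (is.null(group)) 1 else 2)
  fit$r_squared <- if (stats::sd(fit$fitted) > 0 && stats::sd(y) > 0)
    stats::cor(fit$fitted, y)^2 else NA_real_
  class(fit) <- "reml_fit"
  fit
}

# REML log-likelihood at arbitrary variance components theta = (s2u, s2e),
# with beta profiled (GLS at the implied ratio). Used by the Satterthwaite
# machinery, which needs the curvature of the REML surface in theta.
reml_loglik_at <- function(fit, theta) {
  s2u <- theta[1]; s2e <- theta[2]
  if (s2e <= 0 || s2u < 0) return(-Inf)
  lambda <- s2u / s2e
  n <- fit$n; p <- fit$p; ng <- fit$ng
  d <- lambda / (1 + lambda * ng)
  XtViX <- fit$XtX - crossprod(fit$Xg * sqrt(d))
  XtViy <- fit$Xty - drop(crossprod(fit$Xg, d * fit$yg))
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
  yViy <- fit$yty - sum(d * fit$yg^2)
  rViR <- yViy - sum(beta * XtViy)
  ldV <- sum(log1p(lambda * ng))
  ldXtViX <- 2 * sum(log(diag(ch)))
  -0.5 * ((n - p) * log(2 * pi * s2e) + ldV + ldXtViX + rViR / s2e)
}

# Covariance of the fixed effects at arbitrary variance components.
beta_cov_at <- function(fit, theta) {
  s2u <- theta[1]; s2e <- theta[2]
  lambda <- s2u / s2e
  d <- lambda / (1 + lambda * fit$ng)
  XtViX <- fit$XtX - crossprod(fit$Xg * sqrt(d))
  s2e * chol2inv(chol(XtViX))
}
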