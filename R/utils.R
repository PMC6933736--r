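#' Effective sample size of an MCMC draw vector
#'
#' Initial positive-sequence estimator: the integrated autocorrelation time is
#' truncated at the first non-positive autocorrelation estimate.
#'
#' @param x numeric vector of (thinned) MCMC draws.
#' @return Estimated effective sample size, capped at `length(x)`.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Holm (sequential Bonferroni) adjustment with rejection flags
#'
#' Step-down adjustment controlling the family-wise error rate: p-values are
#' sorted ascending, the i-th smallest is multiplied by (m - i + 1),
#' monotonicity is enforced and values capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise significance level for the rejection flags.
#' @return List with `p_adjusted` (original order) and logical `reject`.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(p), length(p) >= 1L)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  list(p_adjusted = adj, reject = adj <= alpha)
}

#' Significance stars for a p-value vector
#' @param p numeric vector.
#' @return character vector in c("", "*", "**", "***").
#' @keywords internal
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = TRUE)
}

# Derive a stage seed from a master seed by a fixed offset, kept inside the
# 32-bit signed-integer range R requires of set.seed().
stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) + offset) %% 2147483647)
}

# FNV-1a hash of a serialized R object; used only to stamp outputs with a
# short configuration fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
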