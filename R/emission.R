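#' Lognormal probability density
#'
#' Density of the state-conditional latency model,
#' \deqn{p(z \mid \mu, \sigma) = \frac{1}{z \sqrt{2\pi}\,\sigma}
#'   \exp\!\left(-\frac{(\log z - \mu)^2}{2\sigma^2}\right),}
#' i.e. \eqn{\log z \sim N(\mu, \sigma^2)}.
#'
#' @param z positive latency (vectorized).
#' @param mu location (mean of log z).
#' @param sigma scale (sd of log z), positive.
#' @return Density value(s).
#' @examples
#' lognormalPdf(exp(5), 5, 0.2)  # 1 / (exp(5) * sqrt(2*pi) * 0.2)
#' @export
lognormalPdf <- function(z, mu, sigma) {
  if (any(!is.finite(z)) || any(z <= 0))
    stop("lognormalPdf is defined for positive finite z only")
  if (any(sigma <= 0)) stop("sigma must be positive")
  stats::dlnorm(z, meanlog = mu, sdlog = sigma)
}

#' Mixed emission probability
#'
#' Joint emission density of one trial under the conditional-independence
#' assumption: \eqn{b_m(y, z) = \Pr(y \mid S = m)\, p(z \mid \mu_m, \sigma_m)}.
#' The binary factor is Bernoulli with success probability `bern[m]`; the
#' latency factor is lognormal.  With `useLatency = FALSE` the latency factor
#' is replaced by 1 (outcome-only model).
#'
#' @param y binary outcome (0 or 1).
#' @param z positive latency.
#' @param state state label in {0, 1} (0 = unattended maps to index 1).
#' @param params an [HSMMParameters-class].
#' @param useLatency include the lognormal latency factor?
#' @return Nonnegative density value.
#' @export
emissionProb <- function(y, z, state, params, useLatency = TRUE) {
  stopifnot(state %in% c(0L, 1L), y %in% c(0L, 1L))
  m <- state + 1L
  p <- if (y == 1L) params@bern[m] else 1 - params@bern[m]
  if (useLatency)
    p <- p * lognormalPdf(z, params@mu[m], params@sigma[m])
  p
}

# T x M matrix of emission densities for a whole sequence (internal hot path).
emissionMatrix <- function(seq, params, useLatency = TRUE) {
  y <- seq@y
  z <- seq@z
  M <- length(params@bern)
  B <- matrix(1, length(y), M)
  for (m in seq_len(M)) {
    B[, m] <- ifelse(y == 1L, params@bern[m], 1 - params@bern[m])
    if (useLatency)
      B[, m] <- B[, m] * stats::dlnorm(z, params@mu[m], params@sigma[m])
  }
  B
}
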