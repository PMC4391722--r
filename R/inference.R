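#' @useDynLib attentionHSMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# cube (M, D, T) from C++ -> R array (T, M, D)
.cubeToArray <- function(x) aperm(x, c(3L, 1L, 2L))

#' Forward pass
#'
#' Runs the forward recursion of the explicit-duration HSMM over a trial
#' sequence.  The predicted joint posterior is initialized as
#' \eqn{\alpha_{1|0}(m,d) = \pi_m p_m(d)} and propagated by
#' \deqn{\alpha_{t|t-1}(m,d) = F_{t-1}(m)\,p_m(d) +
#'   \rho_m(y_{t-1},z_{t-1})\,\alpha_{t-1|t-2}(m,d+1),}
#' with \eqn{\rho_m = b_m(y_t,z_t) / r_t^{-1}},
#' \eqn{r_t^{-1} = \sum_m \gamma_{t|t-1}(m) b_m(y_t,z_t)},
#' \eqn{E_t(m) = \alpha_{t|t-1}(m,1)\rho_m} and
#' \eqn{F_t(m) = \sum_n a_{nm} E_t(n)}.  All forward quantities are proper
#' conditional probabilities (self-normalizing), and
#' \eqn{\log L = \sum_t \log r_t^{-1}}.
#'
#' @param seq a [TrialSequence-class].
#' @param params validated [HSMMParameters-class].
#' @param useLatency include the lognormal latency factor in emissions?
#' @return A partial [FBCache-class] (forward slots and `logLik` filled).
#' @export
forwardPass <- function(seq, params, useLatency = TRUE) {
  B <- emissionMatrix(seq, params, useLatency)
  fw <- hsmmForwardCpp(B, params@pi, params@A, params@Pdur)
  new("FBCache",
      alphaPred = .cubeToArray(fw$alphaPred),
      rho = fw$rho, rInv = as.numeric(fw$rInv),
      E = fw$E, F = fw$F,
      beta = array(NA_real_, c(0L, 0L, 0L)),
      EStar = matrix(NA_real_, 0L, 0L), FStar = matrix(NA_real_, 0L, 0L),
      alphaSmooth = array(NA_real_, c(0L, 0L, 0L)),
      gammaSmooth = matrix(NA_real_, 0L, 0L),
      DSmooth = array(NA_real_, c(0L, 0L, 0L)),
      TSmooth = array(NA_real_, c(0L, 0L, 0L)),
      logLik = fw$logLik)
}

#' Backward pass
#'
#' Runs the backward recursion, initialized as
#' \eqn{\beta_T(m,d) = \rho_m(y_T, z_T)} for every d and propagated by
#' \eqn{\beta_t(m,1) = F^*_{t+1}(m)\rho_m(y_t,z_t)},
#' \eqn{\beta_t(m,d) = \beta_{t+1}(m,d-1)\rho_m(y_t,z_t)} for d > 1, with
#' \eqn{E^*_t(m) = \sum_d p_m(d)\beta_t(m,d)} and
#' \eqn{F^*_t(m) = \sum_n a_{mn} E^*_t(n)}.
#'
#' @param seq a [TrialSequence-class] (for interface symmetry; the pass
#'   depends on the data only through `fwd`).
#' @param params validated [HSMMParameters-class].
#' @param fwd the [FBCache-class] returned by [forwardPass()].
#' @return `fwd` with the backward slots (`beta`, `EStar`, `FStar`) filled.
#' @export
backwardPass <- function(seq, params, fwd) {
  bw <- hsmmBackwardCpp(fwd@rho, params@A, params@Pdur)
  fwd@beta <- .cubeToArray(bw$beta)
  fwd@EStar <- bw$EStar
  fwd@FStar <- bw$FStar
  fwd
}

#' Smoothed posteriors
#'
#' Combines the two passes: \eqn{\alpha_{t|T} = \alpha_{t|t-1} \beta_t},
#' \eqn{\gamma_{t|T}(m) = \sum_d \alpha_{t|T}(m,d)},
#' \eqn{\mathcal{D}_{t|T}(m,d) = F_{t-1}(m) p_m(d) \beta_t(m,d)} (with
#' \eqn{\pi_m} in place of \eqn{F_0} at t = 1) and
#' \eqn{\mathcal{T}_{t|T}(m,n) = E_{t-1}(m) a_{mn} E^*_t(n)}.  The
#' consistency \eqn{\sum_d \mathcal{D}_{t|T}(n,d) = \sum_m
#' \mathcal{T}_{t|T}(m,n)} (segment starts in state n at t = transitions
#' into n at t) holds for every t >= 2 and n.
#'
#' @param fwd cache after [forwardPass()] and [backwardPass()].
#' @param params validated [HSMMParameters-class].
#' @return The completed [FBCache-class].
#' @export
smoothPosteriors <- function(fwd, params) {
  if (length(fwd@beta) == 0L)
    stop("run backwardPass() before smoothPosteriors()")
  sm <- hsmmSmoothCpp(aperm(fwd@alphaPred, c(2L, 3L, 1L)),
                      aperm(fwd@beta, c(2L, 3L, 1L)),
                      fwd@E, fwd@F, fwd@EStar,
                      params@pi, params@A, params@Pdur)
  fwd@alphaSmooth <- .cubeToArray(sm$alphaSmooth)
  fwd@gammaSmooth <- sm$gammaSmooth
  fwd@DSmooth <- .cubeToArray(sm$DSmooth)
  fwd@TSmooth <- .cubeToArray(sm$TSmooth)
  fwd
}

#' One complete E-step
#'
#' Convenience wrapper: forward pass, backward pass and smoothing.
#'
#' @inheritParams forwardPass
#' @return A completed [FBCache-class].
#' @export
eStep <- function(seq, params, useLatency = TRUE) {
  fwd <- forwardPass(seq, params, useLatency)
  fwd <- backwardPass(seq, params, fwd)
  smoothPosteriors(fwd, params)
}
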