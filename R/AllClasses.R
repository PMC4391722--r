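#' @import methods
NULL

#' Paired binary-outcome / latency trial sequence
#'
#' Container for the observed data of a behavioral session: one binary
#' outcome \eqn{y_t \in \{0,1\}} (0 = incorrect, 1 = correct) and one
#' positive response latency \eqn{z_t} per trial, in a fixed time unit.
#'
#' @slot y integer vector of binary outcomes, length \eqn{T}.
#' @slot z numeric vector of positive, finite latencies, length \eqn{T}.
#'
#' @seealso [TrialSequence()] for construction, [simulateHSMM()] to draw
#'   sequences from a model.
#' @export
setClass("TrialSequence",
  representation(y = "integer", z = "numeric"))

setValidity("TrialSequence", function(object) {
  if (length(object@y) != length(object@z))
    return("y and z must have equal length")
  if (length(object@y) < 1L)
    return("a TrialSequence needs at least one trial (T >= 1)")
  if (!all(object@y %in% c(0L, 1L)))
    return("every outcome y must be 0 or 1")
  if (!all(is.finite(object@z)) || any(object@z <= 0))
    return("every latency z must be positive and finite")
  TRUE
})

#' Construct a TrialSequence
#'
#' @param y binary outcomes (0/1), coerced to integer.
#' @param z positive latencies, same length as `y`.
#' @return A validated [TrialSequence-class] object.
#' @examples
#' ts <- TrialSequence(y = c(1, 0, 1), z = c(150, 410, 148))
#' nTrials(ts)
#' @export
TrialSequence <- function(y, z) {
  obj <- new("TrialSequence", y = as.integer(y), z = as.numeric(z))
  validObject(obj)
  obj
}

#' Parameters of the two-state explicit-duration HSMM
#'
#' Full parameter set of the attentional-state model: initial distribution,
#' sojourn-end transition matrix, explicit (or geometric) state-duration
#' distribution, Bernoulli outcome probabilities and state-conditional
#' lognormal latency parameters.  State index 1 carries label 0
#' ("unattended"), state index 2 carries label 1 ("attended").
#'
#' @slot pi initial-state probabilities, length M.
#' @slot A M x M transition matrix; row m is the distribution of the state
#'   entered when state m's sojourn ends (rows sum to one).
#' @slot Pdur M x dMax explicit duration matrix; entry (m, d) is
#'   \eqn{\Pr(\tau = d \mid S = m)} (rows sum to one).
#' @slot bern length-M vector, \eqn{\Pr(y_t = 1 \mid S_t = m)}.
#' @slot mu length-M lognormal location (mean of \eqn{\log z}).
#' @slot sigma length-M lognormal scale (sd of \eqn{\log z}), all positive.
#' @slot dMax maximum sojourn duration (positive integer).
#' @slot durationModel `"explicit"` (nonparametric rows of `Pdur`) or
#'   `"geometric"` (truncated, renormalized geometric built from `geomRate`).
#' @slot geomRate length-M per-trial stopping rates in (0, 1], used only when
#'   `durationModel = "geometric"`.
#'
#' @export
setClass("HSMMParameters",
  representation(pi = "numeric", A = "matrix", Pdur = "matrix",
                 bern = "numeric", mu = "numeric", sigma = "numeric",
                 dMax = "integer", durationModel = "character",
                 geomRate = "numeric"))

.rowSumTol <- 1e-8

.checkSimplex <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    return(sprintf("%s must contain probabilities in [0, 1]", what))
  if (abs(sum(x) - 1) > .rowSumTol)
    return(sprintf("%s must sum to 1 (got %.10g)", what, sum(x)))
  NULL
}

setValidity("HSMMParameters", function(object) {
  M <- length(object@pi)
  if (M < 2L) return("at least two states are required")
  msg <- .checkSimplex(object@pi, "pi")
  if (!is.null(msg)) return(msg)
  if (!all(dim(object@A) == c(M, M)))
    return("A must be an M x M matrix")
  for (m in seq_len(M)) {
    msg <- .checkSimplex(object@A[m, ], sprintf("row %d of A", m))
    if (!is.null(msg)) return(msg)
  }
  if (length(object@dMax) != 1L || is.na(object@dMax) || object@dMax < 1L)
    return("dMax must be a positive integer (dMax >= 1)")
  if (!all(dim(object@Pdur) == c(M, object@dMax)))
    return("Pdur must be an M x dMax matrix")
  for (m in seq_len(M)) {
    msg <- .checkSimplex(object@Pdur[m, ], sprintf("row %d of Pdur", m))
    if (!is.null(msg)) return(msg)
  }
  if (length(object@bern) != M || any(!is.finite(object@bern)) ||
      any(object@bern < 0) || any(object@bern > 1))
    return("bern must be M probabilities in [0, 1]")
  if (length(object@mu) != M || any(!is.finite(object@mu)))
    return("mu must be M finite values")
  if (length(object@sigma) != M || any(!is.finite(object@sigma)) ||
      any(object@sigma <= 0))
    return("sigma must be M positive values")
  if (!object@durationModel %in% c("explicit", "geometric"))
    return("durationModel must be 'explicit' or 'geometric'")
  if (object@durationModel == "geometric") {
    if (length(object@geomRate) != M || any(!is.finite(object@geomRate)) ||
        any(object@geomRate <= 0) || any(object@geomRate > 1))
      return("geomRate must be M rates in (0, 1]")
  }
  TRUE
})

#' Construct HSMM parameters
#'
#' @param pi initial-state probabilities.
#' @param A sojourn-end transition matrix (rows sum to one).
#' @param Pdur explicit duration matrix (M x dMax, rows sum to one). When
#'   `durationModel = "geometric"` it may be omitted and is built from
#'   `geomRate` as a truncated, renormalized geometric on `1:dMax`.
#' @param bern per-state probabilities of a correct outcome.
#' @param mu,sigma per-state lognormal latency parameters (log scale).
#' @param dMax maximum sojourn duration.
#' @param durationModel `"explicit"` or `"geometric"`.
#' @param geomRate per-state geometric stopping rates (geometric model only).
#' @return A validated [HSMMParameters-class] object.
#' @examples
#' p <- HSMMParameters(
#'   pi = c(0.5, 0.5),
#'   A = rbind(c(0.3, 0.7), c(0.15, 0.85)),
#'   Pdur = rbind(c(0.15, 0.5, 0.3, 0.05), c(0.01, 0.2, 0.6, 0.19)),
#'   bern = c(0.3, 0.95), mu = c(6, 5), sigma = c(0.5, 0.2))
#' dMax(p)
#' @export
HSMMParameters <- function(pi, A, Pdur = NULL, bern, mu, sigma,
                           dMax = if (!is.null(Pdur)) ncol(Pdur) else 1L,
                           durationModel = c("explicit", "geometric"),
                           geomRate = numeric(0)) {
  durationModel <- match.arg(durationModel)
  dMax <- as.integer(dMax)
  if (is.null(Pdur)) {
    if (durationModel != "geometric")
      stop("Pdur is required for the explicit duration model")
    Pdur <- geometricDurations(geomRate, dMax)
  }
  obj <- new("HSMMParameters", pi = as.numeric(pi), A = as.matrix(A),
             Pdur = as.matrix(Pdur), bern = as.numeric(bern),
             mu = as.numeric(mu), sigma = as.numeric(sigma),
             dMax = dMax, durationModel = durationModel,
             geomRate = as.numeric(geomRate))
  validObject(obj)
  obj
}

#' Validate HSMM parameters
#'
#' Returns its argument unchanged when all invariants hold (simplex rows
#' within 1e-8, positive sigma, dMax >= 1); otherwise raises an error naming
#' the first violated invariant.
#'
#' @param params an [HSMMParameters-class] object.
#' @return `params`, unchanged.
#' @export
validateParams <- function(params) {
  validObject(params)
  params
}

#' Truncated geometric duration distribution
#'
#' Builds the M x dMax duration matrix \eqn{p_m(d) \propto (1-q_m)^{d-1} q_m}
#' for \eqn{d = 1, \dots, d_{max}}, renormalized so each row sums to one
#' (the untruncated geometric places mass beyond dMax).  The untruncated
#' distribution has mean \eqn{1/q_m} and variance \eqn{(1-q_m)/q_m^2}.
#'
#' @param geomRate per-state stopping rates in (0, 1].
#' @param dMax maximum duration.
#' @return An M x dMax row-stochastic matrix.
#' @export
geometricDurations <- function(geomRate, dMax) {
  stopifnot(all(geomRate > 0), all(geomRate <= 1), dMax >= 1)
  P <- t(vapply(geomRate,
                function(q) (1 - q)^(seq_len(dMax) - 1) * q,
                numeric(dMax)))
  P / rowSums(P)
}

#' Latent state path with sojourn bookkeeping
#'
#' Ground-truth (simulated) or decoded state sequence, the remaining sojourn
#' time at each trial, and the segment decomposition.  The final segment may
#' be censored by the end of the sequence.
#'
#' @slot state integer vector in {0, 1} (0 = unattended, 1 = attended).
#' @slot tau integer vector of remaining sojourn times (tau >= 1).
#' @slot segments data.frame with columns `start`, `state`, `duration`,
#'   `censored`; segments tile `1:T` without gaps or overlaps.
#'
#' @export
setClass("LatentPath",
  representation(state = "integer", tau = "integer", segments = "data.frame"))

setValidity("LatentPath", function(object) {
  Tn <- length(object@state)
  if (length(object@tau) != Tn) return("state and tau must have equal length")
  if (!all(object@state %in% c(0L, 1L))) return("states must be 0 or 1")
  if (any(object@tau < 1L)) return("remaining sojourn tau must be >= 1")
  if (Tn > 1L) {
    cont <- object@tau[-Tn] > 1L
    if (any(object@tau[-1L][cont] != object@tau[-Tn][cont] - 1L))
      return("tau must decrement by 1 within a sojourn")
    if (any(object@state[-1L][cont] != object@state[-Tn][cont]))
      return("state must be constant within a sojourn")
  }
  seg <- object@segments
  need <- c("start", "state", "duration", "censored")
  if (!all(need %in% names(seg))) return("segments must have start/state/duration/censored")
  if (nrow(seg) > 0L) {
    ends <- seg$start + seg$duration - 1L
    if (seg$start[1L] != 1L || ends[nrow(seg)] != Tn ||
        (nrow(seg) > 1L && any(seg$start[-1L] != ends[-nrow(seg)] + 1L)))
      return("segments must tile 1..T without gaps or overlaps")
  }
  TRUE
})

#' Construct a LatentPath
#'
#' @param state state labels in {0, 1}, length T.
#' @param tau remaining sojourn times; if missing, reconstructed from the
#'   segment table (each segment counts down to 1).  Durations are observed
#'   spans: a censored final segment records the trials actually emitted.
#' @param segments optional data.frame (start, state, duration, censored);
#'   if missing, reconstructed from runs of `state`.  A generator that allows
#'   re-entering the same state should pass its true segment table, since
#'   adjacent same-state segments are indistinguishable from the state
#'   vector alone.
#' @param censored is the final segment cut short by the end of the sequence
#'   (only used when `segments` is reconstructed)?
#' @return A validated [LatentPath-class] object.
#' @export
LatentPath <- function(state, tau = NULL, segments = NULL, censored = FALSE) {
  state <- as.integer(state)
  if (is.null(segments)) {
    r <- rle(state)
    segments <- data.frame(
      start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
      state = r$values, duration = r$lengths,
      censored = c(rep(FALSE, length(r$lengths) - 1L), censored))
  }
  if (is.null(tau))
    tau <- unlist(lapply(segments$duration, function(d) rev(seq_len(d))))
  obj <- new("LatentPath", state = state, tau = as.integer(tau),
             segments = segments)
  validObject(obj)
  obj
}

#' Forward-backward cache
#'
#' All quantities produced by one E-step over a trial sequence.  Arrays are
#' indexed `[trial, state, duration]` (or `[trial, state, state]` for the
#' transition posterior).
#'
#' @slot alphaPred predicted joint posterior \eqn{\alpha_{t|t-1}(m,d)}.
#' @slot rho per-trial update ratios \eqn{\rho_m(y_t, z_t)}.
#' @slot rInv one-step-ahead predictive densities \eqn{r_t^{-1}}.
#' @slot E,F forward segment-boundary probabilities.
#' @slot beta backward ratios \eqn{\beta_t(m,d)}.
#' @slot EStar,FStar backward segment-boundary ratios.
#' @slot alphaSmooth smoothed joint posterior \eqn{\alpha_{t|T}(m,d)}.
#' @slot gammaSmooth smoothed state posterior \eqn{\gamma_{t|T}(m)}.
#' @slot DSmooth smoothed segment-start posterior
#'   \eqn{P(S_t=m, \tau_{t-1}=1, \tau_t=d \mid \mathrm{data})}.
#' @slot TSmooth smoothed transition posterior
#'   \eqn{P(S_{t-1}=m, S_t=n, \tau_{t-1}=1 \mid \mathrm{data})}.
#' @slot logLik observed-data log-likelihood \eqn{\sum_t \log r_t^{-1}}.
#' @export
setClass("FBCache",
  representation(alphaPred = "array", rho = "matrix", rInv = "numeric",
                 E = "matrix", F = "matrix",
                 beta = "array", EStar = "matrix", FStar = "matrix",
                 alphaSmooth = "array", gammaSmooth = "matrix",
                 DSmooth = "array", TSmooth = "array", logLik = "numeric"))

#' EM fit result
#'
#' @slot params final [HSMMParameters-class].
#' @slot posterior the [FBCache-class] of the final E-step (matches `params`).
#' @slot logLikTrace per-iteration log-likelihood of the winning restart.
#' @slot nIter iterations used by the winning restart.
#' @slot converged did the increment fall below `tol` before `maxIter`?
#' @slot nRestartsUsed independent initializations attempted.
#' @slot bestRestartSeed seed of the winning initialization.
#' @slot useLatency were latencies used in the emission model?
#' @export
setClass("HSMMFit",
  representation(params = "HSMMParameters", posterior = "FBCache",
                 logLikTrace = "numeric", nIter = "integer",
                 converged = "logical", nRestartsUsed = "integer",
                 bestRestartSeed = "integer", useLatency = "logical"))

#' State-estimation error metrics
#'
#' `err` is the squared error of the decoded states against the truth,
#' `err0` the baseline squared error of the raw outcomes `y` used as state
#' estimates, and `rip = (err0 - err) / err0` the relative improvement
#' (stored as a fraction; `defined` is FALSE when `err0 == 0`).
#'
#' @export
setClass("EvalMetrics",
  representation(err = "numeric", err0 = "numeric", rip = "numeric",
                 defined = "logical"))

#' Likelihood-based model scores
#'
#' @slot logLik fitted log-likelihood.
#' @slot aic \eqn{-2 \log L + 2\ell}.
#' @slot bic \eqn{-2 \log L + \ell \log T}.
#' @slot orderScore \eqn{-\log L + 2 c^2 \log T} with \eqn{c = 4 d_{max}^2}.
#' @slot nFreeParams free-parameter count \eqn{\ell}.
#' @slot predLogLik predictive log-likelihood on held-out trials (0 with
#'   `predDefined = FALSE` when no held-out trials were given).
#' @slot predDefined whether held-out trials were supplied.
#' @export
setClass("ModelScore",
  representation(logLik = "numeric", aic = "numeric", bic = "numeric",
                 orderScore = "numeric", nFreeParams = "integer",
                 predLogLik = "numeric", predDefined = "logical"))
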