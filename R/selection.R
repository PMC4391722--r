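#' Count free parameters
#'
#' Degrees of freedom \eqn{\ell} of the model: \eqn{(M-1)} for the initial
#' distribution, \eqn{M(M-1)} for the transition rows, \eqn{M(d_{max}-1)}
#' for explicit duration rows (or \eqn{M} geometric rates), plus \eqn{M}
#' Bernoulli and \eqn{2M} lognormal emission parameters.  For M = 2:
#' 15 at `dMax = 4` (explicit), 11 (geometric).
#'
#' @param params an [HSMMParameters-class].
#' @return Integer \eqn{\ell}.
#' @export
countFreeParams <- function(params) {
  M <- length(params@pi)
  dur <- if (params@durationModel == "geometric") M
         else M * (params@dMax - 1L)
  as.integer((M - 1L) + M * (M - 1L) + dur + M + 2L * M)
}

#' Likelihood-based model scores
#'
#' Computes \eqn{\mathrm{AIC} = -2\log L + 2\ell},
#' \eqn{\mathrm{BIC} = -2\log L + \ell \log T}, the alternative order score
#' \eqn{-\log L + 2 c^2 \log T} with \eqn{c = 4 d_{max}^2} (exposed for
#' completeness; its penalty dominates the likelihood at session-sized T, so
#' it is not the default selection criterion), and, when held-out trials are
#' supplied, the predictive log-likelihood: the forward pass is run over the
#' concatenated training + held-out sequence with frozen parameters and the
#' per-trial log predictive densities \eqn{\log r_t^{-1}} are summed over
#' the held-out trials only (this respects the latent-state carryover at the
#' split point).
#'
#' @param fit an [HSMMFit-class].
#' @param seq the training [TrialSequence-class].
#' @param heldout optional [TrialSequence-class] that chronologically
#'   follows `seq`; `NULL` for none.
#' @return A [ModelScore-class].
#' @export
modelScores <- function(fit, seq, heldout = NULL) {
  ll <- fit@posterior@logLik
  l <- countFreeParams(fit@params)
  Tn <- nTrials(seq)
  cc <- 4 * fit@params@dMax^2
  pred <- 0
  predDefined <- FALSE
  if (!is.null(heldout) && nTrials(heldout) > 0L) {
    joint <- TrialSequence(c(seq@y, heldout@y), c(seq@z, heldout@z))
    fwd <- forwardPass(joint, fit@params, useLatency = fit@useLatency)
    testIdx <- Tn + seq_len(nTrials(heldout))
    pred <- sum(log(fwd@rInv[testIdx]))
    predDefined <- TRUE
  }
  new("ModelScore", logLik = ll,
      aic = -2 * ll + 2 * l,
      bic = -2 * ll + l * log(Tn),
      orderScore = -ll + 2 * cc^2 * log(Tn),
      nFreeParams = l, predLogLik = pred, predDefined = predDefined)
}

#' Select the model order d_max
#'
#' Fits the model for each candidate `dMax` on the chronologically first
#' `splitFraction` of trials (the data are a time series; a random split
#' would break the sojourn structure), scores each fit, and returns the
#' candidate minimizing the criterion (maximizing, for the predictive
#' log-likelihood on the remaining trials).  Ties go to the smaller `dMax`;
#' candidates whose fit fails are recorded as `NA` and excluded.
#'
#' @param seq a [TrialSequence-class].
#' @param dMaxGrid candidate maximum durations (nonempty).
#' @param criterion `"aic"`, `"bic"`, `"orderScore"` or `"predLogLik"`.
#' @param splitFraction fraction of trials used for fitting, in (0, 1).
#' @param durationModel,useLatency,nRestarts,seed passed to [fitHSMM()].
#' @return A list with `dMax` (the chosen order) and `table` (a data.frame
#'   with one row per candidate: dMax, logLik, nFreeParams, aic, bic,
#'   orderScore, predLogLik).
#' @export
selectOrder <- function(seq, dMaxGrid,
                        criterion = c("aic", "bic", "orderScore",
                                      "predLogLik"),
                        splitFraction = 0.8,
                        durationModel = c("explicit", "geometric"),
                        useLatency = TRUE, nRestarts = 10L, seed = NULL) {
  criterion <- match.arg(criterion)
  durationModel <- match.arg(durationModel)
  if (length(dMaxGrid) < 1L) stop("dMaxGrid must be nonempty")
  if (splitFraction <= 0 || splitFraction >= 1)
    stop("splitFraction must lie in (0, 1)")
  Tn <- nTrials(seq)
  nTrain <- max(2L, floor(splitFraction * Tn))
  train <- TrialSequence(seq@y[seq_len(nTrain)], seq@z[seq_len(nTrain)])
  heldout <- if (nTrain < Tn)
    TrialSequence(seq@y[(nTrain + 1L):Tn], seq@z[(nTrain + 1L):Tn])
  else NULL

  rows <- lapply(sort(dMaxGrid), function(d) {
    sc <- tryCatch({
      fit <- fitHSMM(train, dMaxVal = d, durationModel = durationModel,
                     useLatency = useLatency, nRestarts = nRestarts,
                     seed = seed)
      modelScores(fit, train, heldout)
    }, error = function(e) NULL)
    if (is.null(sc))
      data.frame(dMax = d, logLik = NA_real_, nFreeParams = NA_integer_,
                 aic = NA_real_, bic = NA_real_, orderScore = NA_real_,
                 predLogLik = NA_real_)
    else
      data.frame(dMax = d, logLik = sc@logLik, nFreeParams = sc@nFreeParams,
                 aic = sc@aic, bic = sc@bic, orderScore = sc@orderScore,
                 predLogLik = if (sc@predDefined) sc@predLogLik else NA_real_)
  })
  tab <- do.call(rbind, rows)
  score <- tab[[criterion]]
  if (criterion == "predLogLik") score <- -score
  if (all(is.na(score))) stop("every candidate fit failed")
  best <- tab$dMax[which.min(score)]  # which.min skips NA, first = smallest d
  list(dMax = best, table = tab)
}
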