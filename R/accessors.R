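#' @describeIn nTrials trial count of a sequence
#' @export
setMethod("nTrials", "TrialSequence", function(x) length(x@y))

#' @describeIn nTrials trial count of a latent path
#' @export
setMethod("nTrials", "LatentPath", function(x) length(x@state))

#' @describeIn outcomes outcomes of a sequence
#' @export
setMethod("outcomes", "TrialSequence", function(x) x@y)

#' @describeIn latencies latencies of a sequence
#' @export
setMethod("latencies", "TrialSequence", function(x) x@z)

#' @describeIn states decoded or simulated state labels
#' @export
setMethod("states", "LatentPath", function(x) x@state)

#' @describeIn sojourns remaining sojourn times
#' @export
setMethod("sojourns", "LatentPath", function(x) x@tau)

#' @describeIn segments segment table
#' @export
setMethod("segments", "LatentPath", function(x) x@segments)

#' @describeIn dMax of a parameter set
#' @export
setMethod("dMax", "HSMMParameters", function(x) x@dMax)

#' @describeIn dMax of a fit
#' @export
setMethod("dMax", "HSMMFit", function(x) x@params@dMax)

#' @describeIn transMatrix of a parameter set
#' @export
setMethod("transMatrix", "HSMMParameters", function(x) x@A)

#' @describeIn transMatrix of a fit
#' @export
setMethod("transMatrix", "HSMMFit", function(x) x@params@A)

#' @describeIn durMatrix of a parameter set
#' @export
setMethod("durMatrix", "HSMMParameters", function(x) x@Pdur)

#' @describeIn durMatrix of a fit
#' @export
setMethod("durMatrix", "HSMMFit", function(x) x@params@Pdur)

#' @describeIn modelParams parameters of a fit
#' @export
setMethod("modelParams", "HSMMFit", function(x) x@params)

#' @describeIn logLikOf of a fit
#' @export
setMethod("logLikOf", "HSMMFit", function(x) x@posterior@logLik)

#' @describeIn logLikOf of a forward-backward cache
#' @export
setMethod("logLikOf", "FBCache", function(x) x@logLik)

#' @describeIn logLikOf of a model score
#' @export
setMethod("logLikOf", "ModelScore", function(x) x@logLik)

#' @describeIn statePosterior of a cache
#' @export
setMethod("statePosterior", "FBCache", function(x) x@gammaSmooth)

#' @describeIn statePosterior of a fit
#' @export
setMethod("statePosterior", "HSMMFit", function(x) x@posterior@gammaSmooth)

setMethod("show", "TrialSequence", function(object) {
  cat(sprintf("TrialSequence with %d trials: %.1f%% correct, latency range [%.3g, %.3g]\n",
              nTrials(object), 100 * mean(object@y), min(object@z), max(object@z)))
})

setMethod("show", "HSMMParameters", function(object) {
  cat(sprintf("HSMMParameters: %d states, dMax = %d, %s durations\n",
              length(object@pi), object@dMax, object@durationModel))
  cat("  bern:", format(object@bern, digits = 3),
      "| mu:", format(object@mu, digits = 4),
      "| sigma:", format(object@sigma, digits = 3), "\n")
})

setMethod("show", "LatentPath", function(object) {
  cat(sprintf("LatentPath with %d trials, %d segments (%.1f%% attended)\n",
              nTrials(object), nrow(object@segments),
              100 * mean(object@state == 1L)))
})

setMethod("show", "HSMMFit", function(object) {
  cat(sprintf("HSMMFit: logLik %.4f after %d EM iterations (%s), %d restart(s)\n",
              object@posterior@logLik, object@nIter,
              if (object@converged) "converged" else "max iterations",
              object@nRestartsUsed))
  show(object@params)
})

setMethod("show", "EvalMetrics", function(object) {
  if (object@defined)
    cat(sprintf("EvalMetrics: err = %g, err0 = %g, RIP = %.4f\n",
                object@err, object@err0, object@rip))
  else
    cat(sprintf("EvalMetrics: err = %g, err0 = 0 (RIP undefined)\n", object@err))
})

setMethod("show", "ModelScore", function(object) {
  cat(sprintf("ModelScore: logLik %.4f, AIC %.3f, BIC %.3f (l = %d)\n",
              object@logLik, object@aic, object@bic, object@nFreeParams))
  if (object@predDefined)
    cat(sprintf("  predictive logLik on held-out trials: %.4f\n", object@predLogLik))
})
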