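#' Number of trials
#' @param x a [TrialSequence-class] or [LatentPath-class].
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Binary outcomes
#' @param x a [TrialSequence-class].
#' @return integer vector of 0/1 outcomes.
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' Response latencies
#' @param x a [TrialSequence-class].
#' @return numeric vector of positive latencies.
#' @export
setGeneric("latencies", function(x) standardGeneric("latencies"))

#' State labels of a latent path
#' @param x a [LatentPath-class].
#' @return integer vector in {0, 1}.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Remaining sojourn times
#' @param x a [LatentPath-class].
#' @return integer vector, tau >= 1.
#' @export
setGeneric("sojourns", function(x) standardGeneric("sojourns"))

#' Segment decomposition of a latent path
#' @param x a [LatentPath-class].
#' @return data.frame with columns start, state, duration, censored.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' Maximum sojourn duration
#' @param x an [HSMMParameters-class] or [HSMMFit-class].
#' @return integer dMax.
#' @export
setGeneric("dMax", function(x) standardGeneric("dMax"))

#' Transition matrix
#' @param x an [HSMMParameters-class] or [HSMMFit-class].
#' @return M x M row-stochastic matrix.
#' @export
setGeneric("transMatrix", function(x) standardGeneric("transMatrix"))

#' Duration distribution matrix
#' @param x an [HSMMParameters-class] or [HSMMFit-class].
#' @return M x dMax row-stochastic matrix.
#' @export
setGeneric("durMatrix", function(x) standardGeneric("durMatrix"))

#' Fitted or specified model parameters
#' @param x an [HSMMFit-class].
#' @return an [HSMMParameters-class].
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' Log-likelihood accessor
#' @param x an [HSMMFit-class], [FBCache-class] or [ModelScore-class].
#' @return numeric scalar.
#' @export
setGeneric("logLikOf", function(x) standardGeneric("logLikOf"))

#' Smoothed per-trial state posterior
#' @param x an [HSMMFit-class] or [FBCache-class].
#' @return T x M matrix, rows summing to one.
#' @export
setGeneric("statePosterior", function(x) standardGeneric("statePosterior"))
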