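#' Simulate from the explicit-duration HSMM
#'
#' Draws a latent path and mixed observations: the initial state comes from
#' `pi` and a sojourn duration from the state's row of the duration matrix;
#' the state is held for that many trials; at the sojourn end the next state
#' is drawn from the current state's row of `A` (so `A = identity` pins the
#' chain to its initial state) and a fresh duration is drawn.  The final
#' sojourn may be censored at trial `nTrials` (flagged in the segment table,
#' never resampled).  Per trial, `y_t ~ Bernoulli(bern[S_t])` and
#' `z_t ~ Lognormal(mu[S_t], sigma[S_t])`.
#'
#' Random draws are consumed in a fixed order (state, duration per segment,
#' then y, z per trial), so a given seed yields bit-identical output.
#'
#' @param params an [HSMMParameters-class].
#' @param nTrials number of trials T >= 1.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A list with elements `path` ([LatentPath-class]) and `trials`
#'   ([TrialSequence-class]).
#' @examples
#' sim <- simulateHSMM(studyParameters(), nTrials = 100, seed = 1)
#' table(states(sim$path))
#' @export
simulateHSMM <- function(params, nTrials, seed = NULL) {
  validateParams(params)
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulateStates(params@pi, params@A, params@Pdur, nTrials)
  .emitTrials(sim, params@bern, params@mu, params@sigma, nTrials)
}

# state/duration segment chain; segment durations are the observed spans,
# with the final one flagged censored when the drawn sojourn overran T
.simulateStates <- function(pi, A, P, nTrials) {
  M <- length(pi)
  dmax <- ncol(P)
  state <- integer(nTrials)
  starts <- integer(0)
  segState <- integer(0)
  segDur <- integer(0)
  t <- 1L
  s <- sample.int(M, 1L, prob = pi)
  censored <- FALSE
  while (t <= nTrials) {
    d <- sample.int(dmax, 1L, prob = P[s, ])
    end <- t + d - 1L
    if (end > nTrials) {
      censored <- TRUE
      end <- nTrials
    }
    state[t:end] <- s
    starts <- c(starts, t)
    segState <- c(segState, s - 1L)
    segDur <- c(segDur, end - t + 1L)
    t <- end + 1L
    if (t <= nTrials) s <- sample.int(M, 1L, prob = A[s, ])
  }
  seg <- data.frame(start = starts, state = segState, duration = segDur,
                    censored = c(rep(FALSE, length(starts) - 1L), censored))
  list(state = state, segments = seg)
}

.emitTrials <- function(sim, bern, mu, sigma, nTrials) {
  s <- sim$state
  y <- integer(nTrials)
  z <- numeric(nTrials)
  for (t in seq_len(nTrials)) {
    y[t] <- stats::rbinom(1L, 1L, bern[s[t]])
    z[t] <- stats::rlnorm(1L, mu[s[t]], sigma[s[t]])
  }
  list(path = LatentPath(s - 1L, segments = sim$segments),
       trials = TrialSequence(y, z))
}

#' Simulate with a mid-sequence parameter change
#'
#' Generates a nonstationary sequence: segments starting at or before trial
#' `floor(nTrials/2)` use `paramsA`'s transition/duration model, later
#' segments use `paramsB`'s; emission parameters switch exactly at trial
#' `floor(nTrials/2) + 1`.  With `paramsA` identical to `paramsB` the draw
#' sequence, and hence the output, is identical to [simulateHSMM()].
#'
#' @param paramsA,paramsB [HSMMParameters-class] for the two halves; must
#'   share `dMax`.
#' @param nTrials number of trials.
#' @param seed integer seed.
#' @return As [simulateHSMM()].
#' @export
simulateNonstationary <- function(paramsA, paramsB, nTrials, seed = NULL) {
  validateParams(paramsA)
  validateParams(paramsB)
  if (paramsA@dMax != paramsB@dMax)
    stop("paramsA and paramsB must share dMax")
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  half <- nTrials %/% 2L
  M <- length(paramsA@pi)
  state <- integer(nTrials)
  starts <- integer(0)
  segState <- integer(0)
  segDur <- integer(0)
  t <- 1L
  s <- sample.int(M, 1L, prob = paramsA@pi)
  censored <- FALSE
  while (t <= nTrials) {
    p <- if (t <= half) paramsA else paramsB
    d <- sample.int(p@dMax, 1L, prob = p@Pdur[s, ])
    end <- t + d - 1L
    if (end > nTrials) {
      censored <- TRUE
      end <- nTrials
    }
    state[t:end] <- s
    starts <- c(starts, t)
    segState <- c(segState, s - 1L)
    segDur <- c(segDur, end - t + 1L)
    t <- end + 1L
    if (t <= nTrials) s <- sample.int(M, 1L, prob = p@A[s, ])
  }
  seg <- data.frame(start = starts, state = segState, duration = segDur,
                    censored = c(rep(FALSE, length(starts) - 1L), censored))
  y <- integer(nTrials)
  z <- numeric(nTrials)
  for (tt in seq_len(nTrials)) {
    p <- if (tt <= half) paramsA else paramsB
    y[tt] <- stats::rbinom(1L, 1L, p@bern[state[tt]])
    z[tt] <- stats::rlnorm(1L, p@mu[state[tt]], p@sigma[state[tt]])
  }
  list(path = LatentPath(state - 1L, segments = seg),
       trials = TrialSequence(y, z))
}

#' Simulate from a first-order Markov chain
#'
#' Per-trial state transitions by `A` (equivalently an HSMM with geometric
#' sojourns of per-trial stopping rate `1 - A[m, m]`), with the same mixed
#' emissions as [simulateHSMM()].  States are drawn first, then y and z per
#' trial.
#'
#' @param pi initial-state probabilities.
#' @param A per-trial transition matrix, rows summing to one.
#' @param bern,mu,sigma emission parameters as in [HSMMParameters()].
#' @param nTrials number of trials.
#' @param seed integer seed.
#' @return As [simulateHSMM()].
#' @export
simulateMarkov <- function(pi, A, bern, mu, sigma, nTrials, seed = NULL) {
  if (abs(sum(pi) - 1) > 1e-8 || any(abs(rowSums(A) - 1) > 1e-8))
    stop("pi and the rows of A must sum to one")
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  M <- length(pi)
  state <- integer(nTrials)
  state[1L] <- sample.int(M, 1L, prob = pi)
  for (t in seq_len(nTrials)[-1L])
    state[t] <- sample.int(M, 1L, prob = A[state[t - 1L], ])
  .emitTrials(list(state = state, censored = FALSE), bern, mu, sigma, nTrials)
}
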