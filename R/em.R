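.degenerate <- function(msg) {
  stop(structure(class = c("degenerateStateError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# floors applied during re-estimation; the lognormal likelihood is unbounded
# as sigma -> 0, so restarts must not be allowed to win on a density spike
.SIGMA_FLOOR <- 0.01
.WEIGHT_TOL <- 1e-8

#' M-step re-estimation
#'
#' Re-estimates all parameters from one E-step's smoothed posteriors:
#' \eqn{\hat\pi_m \propto \gamma_{1|T}(m)},
#' \eqn{\hat a_{mn} \propto \sum_{t\ge2} \mathcal{T}_{t|T}(m,n)},
#' \eqn{\hat p_{md} \propto \sum_{t\ge2} \mathcal{D}_{t|T}(m,d)},
#' \eqn{\widehat{\mathrm{bern}}_m = \sum_t \gamma_{t|T}(m) I(y_t=1) /
#'   \sum_t \gamma_{t|T}(m)}, and the reliability-weighted unbiased lognormal
#' estimates
#' \eqn{\hat\mu_m = \sum_t w_t(m) \log z_t},
#' \eqn{\hat\sigma^2_m = \frac{1}{1 - \sum_t w_t(m)^2}
#'   \sum_t w_t(m)(\log z_t - \hat\mu_m)^2}
#' with weights normalized over trials,
#' \eqn{w_t(m) = \gamma_{t|T}(m) / \sum_{t'} \gamma_{t'|T}(m)}.
#'
#' @param seq the [TrialSequence-class] being fitted.
#' @param cache a completed [FBCache-class].
#' @param params current [HSMMParameters-class] (carries dMax and the
#'   duration-model flavor; under the geometric model the duration rows are
#'   rebuilt from [mStepGeometric()] instead of the nonparametric update).
#' @return Updated [HSMMParameters-class].
#' @export
mStep <- function(seq, cache, params) {
  d <- seq_len(dim(cache@DSmooth)[3L])
  stats <- list(
    gamma = cache@gammaSmooth,
    Asum = apply(cache@TSmooth[-1L, , , drop = FALSE], c(2L, 3L), sum),
    Psum = apply(cache@DSmooth[-1L, , , drop = FALSE], c(2L, 3L), sum),
    DdurSum = vapply(seq_len(ncol(cache@gammaSmooth)), function(m)
      sum(sweep(cache@DSmooth[-1L, m, , drop = FALSE], 3L, d, "*")),
      numeric(1)))
  th <- .mStepCore(stats, seq@y, log(seq@z), params@durationModel,
                   params@dMax)
  HSMMParameters(pi = th$pi, A = th$A, Pdur = th$P, bern = th$bern,
                 mu = th$mu, sigma = th$sigma, dMax = params@dMax,
                 durationModel = params@durationModel,
                 geomRate = th$geomRate)
}

# shared M-step arithmetic on sufficient statistics; theta as a plain list
.mStepCore <- function(stats, y, lz, durationModel, dMaxVal) {
  g <- stats$gamma
  M <- ncol(g)
  tot <- colSums(g)
  if (any(tot < .WEIGHT_TOL))
    .degenerate(sprintf("state %d received vanishing posterior weight",
                        which.min(tot)))
  piHat <- g[1L, ] / sum(g[1L, ])
  if (any(rowSums(stats$Asum) < .WEIGHT_TOL))
    .degenerate("a state never ends a sojourn; transition rows undefined")
  Ahat <- stats$Asum / rowSums(stats$Asum)
  bernHat <- colSums(g * (y == 1L)) / tot
  w <- sweep(g, 2L, tot, "/")
  muHat <- colSums(w * lz)
  s2 <- vapply(seq_len(M), function(m) {
    sum(w[, m] * (lz - muHat[m])^2) / (1 - sum(w[, m]^2))
  }, numeric(1))
  sigmaHat <- pmax(sqrt(pmax(s2, 0)), .SIGMA_FLOOR)
  if (durationModel == "geometric") {
    num <- colSums(g[-1L, , drop = FALSE])
    if (any(stats$DdurSum < .WEIGHT_TOL))
      .degenerate("zero expected sojourn mass in geometric duration update")
    q <- pmin(pmax(num / stats$DdurSum, 1e-6), 1)
    Phat <- geometricDurations(q, dMaxVal)
    geomRate <- q
  } else {
    if (any(rowSums(stats$Psum) < .WEIGHT_TOL))
      .degenerate("a state never starts a sojourn; duration rows undefined")
    Phat <- stats$Psum / rowSums(stats$Psum)
    geomRate <- numeric(0)
  }
  list(pi = piHat, A = Ahat, P = Phat, bern = bernHat, mu = muHat,
       sigma = sigmaHat, geomRate = geomRate)
}

#' Geometric-duration M-step
#'
#' Moment-matching update of the per-state stopping rates:
#' \deqn{\hat q_m = \frac{\sum_{t\ge2} \gamma_{t|T}(m)}
#'   {\sum_{t\ge2} \sum_d d\, \mathcal{D}_{t|T}(m,d)}.}
#' Under the geometric sojourn law \eqn{p_m(d) = (1-q_m)^{d-1} q_m},
#' \eqn{E[\tau_m] = 1/q_m} and \eqn{\mathrm{var}[\tau_m] = (1-q_m)/q_m^2};
#' `q = 1` puts all mass on d = 1 (a pure Markov chain).
#'
#' @param cache a completed [FBCache-class].
#' @return Numeric vector of rates, clamped to (0, 1].
#' @export
mStepGeometric <- function(cache) {
  g <- cache@gammaSmooth
  M <- ncol(g)
  d <- seq_len(dim(cache@DSmooth)[3L])
  num <- colSums(g[-1L, , drop = FALSE])
  den <- vapply(seq_len(M), function(m) {
    sum(sweep(cache@DSmooth[-1L, m, , drop = FALSE], 3L, d, "*"))
  }, numeric(1))
  if (any(den < .WEIGHT_TOL))
    .degenerate("zero expected sojourn mass in geometric duration update")
  pmin(pmax(num / den, 1e-6), 1)
}

#' Random initialization for EM
#'
#' Uniform initial distribution; transition and duration rows drawn from a
#' symmetric Dirichlet(5) (a moderate perturbation of uniform); lognormal
#' parameters seeded by splitting trials at the median of log z, with the
#' lower-latency half seeding the attended state (index 2); Bernoulli
#' probabilities seeded by the outcome means within each half (clamped to
#' [0.05, 0.95]); sigma seeds floored at 0.01.
#'
#' @param seq a [TrialSequence-class] with at least 2 trials.
#' @param dMaxVal maximum duration of the initialized model.
#' @param seed integer seed (deterministic output for a given seed).
#' @param durationModel `"explicit"` or `"geometric"`.
#' @return An [HSMMParameters-class].
#' @export
initParams <- function(seq, dMaxVal, seed = NULL,
                       durationModel = c("explicit", "geometric")) {
  durationModel <- match.arg(durationModel)
  if (nTrials(seq) < 2L) stop("initialization needs at least 2 trials")
  if (!is.null(seed)) set.seed(seed)
  M <- 2L
  dirRow <- function(k) {
    gmm <- stats::rgamma(k, shape = 5)
    gmm / sum(gmm)
  }
  A <- t(vapply(seq_len(M), function(i) dirRow(M), numeric(M)))

  lz <- log(seq@z)
  lower <- lz <= stats::median(lz)
  if (all(lower) || !any(lower)) lower <- seq_along(lz) %% 2L == 0L
  # attended state (index 2) <- faster (lower-latency) half
  mu <- c(mean(lz[!lower]), mean(lz[lower]))
  sg <- pmax(c(stats::sd(lz[!lower]), stats::sd(lz[lower])), 0.01)
  sg[is.na(sg)] <- 0.01
  bern <- pmin(pmax(c(mean(seq@y[!lower]), mean(seq@y[lower])), 0.05), 0.95)

  if (durationModel == "geometric") {
    q <- stats::runif(M, 0.2, 0.9)
    HSMMParameters(pi = rep(1 / M, M), A = A, bern = bern, mu = mu,
                   sigma = sg, dMax = dMaxVal,
                   durationModel = "geometric", geomRate = q)
  } else {
    P <- t(vapply(seq_len(M), function(i) dirRow(dMaxVal), numeric(dMaxVal)))
    if (dMaxVal == 1L) P <- matrix(1, M, 1L)
    HSMMParameters(pi = rep(1 / M, M), A = A, Pdur = P, bern = bern,
                   mu = mu, sigma = sg, dMax = dMaxVal,
                   durationModel = "explicit")
  }
}

#' Fit the HSMM by EM
#'
#' Alternates E-steps ([eStep()]) and M-steps ([mStep()]) until the absolute
#' consecutive log-likelihood increment falls below `tol` or `maxIter` is
#' reached, over `nRestarts` independent initializations; the
#' highest-likelihood restart wins.  Restarts whose E/M-step degenerates
#' (a state losing all posterior weight) are discarded; if every restart
#' degenerates an error is raised.  With `dMax = 1` the procedure is exactly
#' the Baum-Welch algorithm for a standard HMM.
#'
#' @param seq a [TrialSequence-class] with at least 2 trials.
#' @param dMaxVal maximum sojourn duration of the fitted model.
#' @param durationModel `"explicit"` (nonparametric duration rows) or
#'   `"geometric"`.
#' @param useLatency use both outcomes and latencies (`TRUE`) or outcomes
#'   only (`FALSE`, the latency factor is dropped from the emission).
#' @param tol convergence threshold on the absolute log-likelihood increment.
#' @param maxIter iteration cap per restart.
#' @param nRestarts number of independent initializations.
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @return An [HSMMFit-class].
#' @examples
#' sim <- simulateHSMM(studyParameters(), nTrials = 100, seed = 1)
#' fit <- fitHSMM(sim$trials, dMaxVal = 4, nRestarts = 2, seed = 1)
#' logLikOf(fit)
#' @export
fitHSMM <- function(seq, dMaxVal, durationModel = c("explicit", "geometric"),
                    useLatency = TRUE, tol = 1e-5, maxIter = 500L,
                    nRestarts = 10L, seed = NULL) {
  durationModel <- match.arg(durationModel)
  if (nTrials(seq) < 2L) stop("fitting needs at least 2 trials")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - nRestarts, 1L)
  best <- NULL
  nFailed <- 0L
  for (r in seq_len(nRestarts)) {
    rseed <- seed + r - 1L
    res <- tryCatch(
      .emSingle(seq, dMaxVal, durationModel, useLatency, tol, maxIter, rseed),
      degenerateStateError = function(e) NULL)
    if (is.null(res)) {
      nFailed <- nFailed + 1L
      next
    }
    if (is.null(best) || res$logLik > best$logLik) {
      best <- res
      best$seed <- rseed
    }
  }
  if (is.null(best))
    stop(sprintf("all %d EM restarts degenerated; cannot fit", nRestarts))
  best$cache <- eStep(seq, best$params, useLatency)
  new("HSMMFit", params = best$params, posterior = best$cache,
      logLikTrace = best$trace, nIter = as.integer(best$nIter),
      converged = best$converged, nRestartsUsed = as.integer(nRestarts),
      bestRestartSeed = as.integer(best$seed), useLatency = useLatency)
}

.emSingle <- function(seq, dMaxVal, durationModel, useLatency, tol, maxIter,
                      seed) {
  p0 <- initParams(seq, dMaxVal, seed = seed, durationModel = durationModel)
  th <- list(pi = p0@pi, A = p0@A, P = p0@Pdur, bern = p0@bern, mu = p0@mu,
             sigma = p0@sigma, geomRate = p0@geomRate)
  y <- seq@y
  lz <- log(seq@z)
  isOne <- y == 1L
  ldens <- NULL   # per-state lognormal densities recomputed per iteration
  emat <- function(th) {
    M <- length(th$bern)
    B <- matrix(0, length(y), M)
    for (m in seq_len(M)) {
      B[, m] <- ifelse(isOne, th$bern[m], 1 - th$bern[m])
      if (useLatency)
        B[, m] <- B[, m] * stats::dlnorm(seq@z, th$mu[m], th$sigma[m])
    }
    B
  }
  trace <- numeric(maxIter)
  converged <- FALSE
  nIter <- 0L
  thPrev <- th
  for (it in seq_len(maxIter)) {
    stats <- hsmmEStepStatsCpp(emat(th), th$pi, th$A, th$P)
    if (it > 1L && stats$logLik < trace[it - 1L]) {
      # the unbiased (not exact-MLE) latency-scale update can step slightly
      # downhill when a state's effective sample size is small: stop at the
      # last parameter set that improved the likelihood
      th <- thPrev
      converged <- TRUE
      break
    }
    nIter <- it
    trace[it] <- stats$logLik
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (it < maxIter) {
      thPrev <- th
      th <- .mStepCore(stats, y, lz, durationModel, dMaxVal)
    }
  }
  params <- HSMMParameters(pi = th$pi, A = th$A, Pdur = th$P, bern = th$bern,
                           mu = th$mu, sigma = th$sigma, dMax = dMaxVal,
                           durationModel = durationModel,
                           geomRate = th$geomRate)
  list(params = params, trace = trace[seq_len(nIter)],
       nIter = nIter, converged = converged, logLik = trace[nIter])
}

#' Resolve label switching
#'
#' Relabels a fitted 2-state model so that the attended label (state index 2,
#' label 1) is the state with the larger probability of a correct outcome;
#' on an exact tie, the state with the smaller lognormal location (faster
#' latencies).  All parameter blocks and posterior arrays are permuted
#' consistently.
#'
#' @param fit an [HSMMFit-class].
#' @return The fit, relabeled if needed.
#' @export
alignStates <- function(fit) {
  b <- fit@params@bern
  attended <- if (b[2L] != b[1L]) which.max(b)
              else which.min(fit@params@mu)
  if (attended == 2L) return(fit)
  perm <- c(2L, 1L)
  p <- fit@params
  fit@params <- HSMMParameters(
    pi = p@pi[perm], A = p@A[perm, perm, drop = FALSE],
    Pdur = p@Pdur[perm, , drop = FALSE], bern = p@bern[perm],
    mu = p@mu[perm], sigma = p@sigma[perm], dMax = p@dMax,
    durationModel = p@durationModel,
    geomRate = if (length(p@geomRate)) p@geomRate[perm] else numeric(0))
  cc <- fit@posterior
  cc@alphaPred <- cc@alphaPred[, perm, , drop = FALSE]
  cc@rho <- cc@rho[, perm, drop = FALSE]
  cc@E <- cc@E[, perm, drop = FALSE]
  cc@F <- cc@F[, perm, drop = FALSE]
  cc@beta <- cc@beta[, perm, , drop = FALSE]
  cc@EStar <- cc@EStar[, perm, drop = FALSE]
  cc@FStar <- cc@FStar[, perm, drop = FALSE]
  cc@alphaSmooth <- cc@alphaSmooth[, perm, , drop = FALSE]
  cc@gammaSmooth <- cc@gammaSmooth[, perm, drop = FALSE]
  cc@DSmooth <- cc@DSmooth[, perm, , drop = FALSE]
  cc@TSmooth <- cc@TSmooth[, perm, perm, drop = FALSE]
  fit@posterior <- cc
  fit
}
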