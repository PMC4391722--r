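#' Canonical simulation-study parameters
#'
#' The two-state attention model used throughout the package's Monte-Carlo
#' evaluation: sojourn-end transition rows (0.30, 0.70) / (0.15, 0.85),
#' duration rows (0.15, 0.50, 0.30, 0.05) for the unattended state (mode at
#' 2 trials) and (0.01, 0.20, 0.60, 0.19) for the attended state (mode at 3),
#' correct-outcome probabilities 0.30 / 0.95, and lognormal latencies
#' logn(6, 0.5) (unattended, slow) and logn(5, 0.2) (attended, fast) —
#' about 13.5% overlap in latency density.  `mu1` can be lowered toward
#' `mu2 = 5` to make the two latency distributions overlap more.
#'
#' @param mu1 lognormal location of the unattended state.
#' @param sigma1,mu2,sigma2 remaining latency parameters.
#' @return An [HSMMParameters-class] with `dMax = 4`.
#' @export
studyParameters <- function(mu1 = 6, sigma1 = 0.5, mu2 = 5, sigma2 = 0.2) {
  HSMMParameters(
    pi = c(0.5, 0.5),
    A = rbind(c(0.30, 0.70), c(0.15, 0.85)),
    Pdur = rbind(c(0.15, 0.50, 0.30, 0.05), c(0.01, 0.20, 0.60, 0.19)),
    bern = c(0.30, 0.95),
    mu = c(mu1, mu2), sigma = c(sigma1, sigma2), dMax = 4L)
}

#' Alternative transition/duration regime for the nonstationary study
#'
#' The second-half regime of the transition-nonstationarity experiment:
#' transition rows (0.50, 0.50) / (0.35, 0.65) and duration rows
#' (0.20, 0.60, 0.15, 0.05) / (0.05, 0.30, 0.35, 0.30); emissions unchanged.
#'
#' @inheritParams studyParameters
#' @return An [HSMMParameters-class] with `dMax = 4`.
#' @export
studyParametersShifted <- function(mu1 = 6, sigma1 = 0.5, mu2 = 5,
                                   sigma2 = 0.2) {
  HSMMParameters(
    pi = c(0.5, 0.5),
    A = rbind(c(0.50, 0.50), c(0.35, 0.65)),
    Pdur = rbind(c(0.20, 0.60, 0.15, 0.05), c(0.05, 0.30, 0.35, 0.30)),
    bern = c(0.30, 0.95),
    mu = c(mu1, mu2), sigma = c(sigma1, sigma2), dMax = 4L)
}

#' Condition sojourn-end transitions on leaving the state
#'
#' Zeroes the diagonal of a transition matrix and renormalizes its rows:
#' the distribution of the next state given that the sojourn ends *and* the
#' state changes.  In the canonical semi-Markov convention a sojourn end is
#' a state change (re-entering the same state is indistinguishable from a
#' longer sojourn), so the simulation study draws successor states from the
#' conditioned rows; with two states this alternates the segments.  The
#' fitted model keeps its transition matrix unconstrained.
#'
#' @param A row-stochastic transition matrix with no row equal to a point
#'   mass on its own state.
#' @return Row-stochastic matrix with zero diagonal.
#' @export
conditionOnChange <- function(A) {
  B <- A
  diag(B) <- 0
  rs <- rowSums(B)
  if (any(rs <= 0)) stop("a row of A has all mass on the diagonal")
  B / rs
}

.mcGenerate <- function(generator, mu1, nTrials) {
  base <- studyParameters(mu1 = mu1)
  gen <- HSMMParameters(pi = base@pi, A = conditionOnChange(base@A),
                        Pdur = base@Pdur, bern = base@bern, mu = base@mu,
                        sigma = base@sigma, dMax = base@dMax)
  switch(generator,
    hsmm = simulateHSMM(gen, nTrials),
    markov = simulateMarkov(base@pi, base@A, base@bern, base@mu, base@sigma,
                            nTrials),
    nonstatTransition = {
      alt <- studyParametersShifted(mu1 = mu1)
      gen2 <- HSMMParameters(pi = alt@pi, A = conditionOnChange(alt@A),
                             Pdur = alt@Pdur, bern = alt@bern, mu = alt@mu,
                             sigma = alt@sigma, dMax = alt@dMax)
      simulateNonstationary(gen, gen2, nTrials)
    },
    nonstatDrift = {
      drift <- studyParameters(mu1 = 5.5, sigma1 = 0.35, mu2 = 4.5,
                               sigma2 = 0.15)
      gen2 <- HSMMParameters(pi = drift@pi, A = conditionOnChange(drift@A),
                             Pdur = drift@Pdur, bern = drift@bern,
                             mu = drift@mu, sigma = drift@sigma,
                             dMax = drift@dMax)
      simulateNonstationary(gen, gen2, nTrials)
    },
    stop("unknown generator: ", generator))
}

.mcMethods <- data.frame(
  method = c("hsmm_both", "hsmm_y", "hmm_both"),
  useLatency = c(TRUE, FALSE, TRUE),
  isHMM = c(FALSE, FALSE, TRUE))

#' Monte-Carlo evaluation of state estimation
#'
#' Repeats, for `nRuns` seeded replicates: simulate a session from the
#' chosen generator, fit each method by EM, resolve label switching, MAP
#' decode, and score the decoded states with [ripMetrics()].  Methods:
#' `hsmm_both` (explicit-duration model, outcomes + latencies, fitted at
#' `dMaxFit`), `hsmm_y` (same model, outcomes only) and `hmm_both`
#' (`dMax = 1`, the standard HMM, outcomes + latencies).  Runs whose fit
#' fails or whose baseline error is zero are excluded from the summary (the
#' effective count is reported).
#'
#' @param generator `"hsmm"` (stationary semi-Markov study),
#'   `"markov"` (first-order Markov chain, per-trial transitions),
#'   `"nonstatTransition"` (second-half switch to the alternative
#'   transition/duration regime) or `"nonstatDrift"` (second-half latency
#'   drift to logn(5.5, 0.35) / logn(4.5, 0.15)).
#' @param nRuns number of Monte-Carlo replicates.
#' @param seed master seed; every simulation and fit seed derives from it.
#' @param methods subset of `c("hsmm_both", "hsmm_y", "hmm_both")`.
#' @param dMaxFit maximum duration of the fitted semi-Markov methods.
#' @param mu1 generative lognormal location of the unattended state.
#' @param nTrials trials per session.
#' @param nRestarts EM restarts per fit.
#' @param tol,maxIter EM control, as in [fitHSMM()].
#' @return A list with `summary` (one row per method: mean and standard
#'   error of RIP, mean aligned parameter estimates, effective run count)
#'   and `runs` (per-run RIP and parameter estimates).
#' @examples
#' mc <- runMonteCarlo("hsmm", nRuns = 2, seed = 1, nRestarts = 2)
#' mc$summary
#' @export
runMonteCarlo <- function(generator = c("hsmm", "markov",
                                        "nonstatTransition", "nonstatDrift"),
                          nRuns = 100L, seed = 1L,
                          methods = c("hsmm_both", "hsmm_y", "hmm_both"),
                          dMaxFit = 4L, mu1 = 6, nTrials = 100L,
                          nRestarts = 10L, tol = 1e-5, maxIter = 500L) {
  generator <- match.arg(generator)
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  simSeeds <- sample.int(.Machine$integer.max - 1L, nRuns)
  fitSeeds <- matrix(sample.int(.Machine$integer.max - nRestarts,
                                nRuns * length(methods)),
                     nrow = nRuns)

  rows <- vector("list", nRuns * length(methods))
  k <- 0L
  for (r in seq_len(nRuns)) {
    set.seed(simSeeds[r])
    sim <- .mcGenerate(generator, mu1, nTrials)
    sTrue <- states(sim$path)
    y <- outcomes(sim$trials)
    for (j in seq_along(methods)) {
      spec <- .mcMethods[.mcMethods$method == methods[j], ]
      d <- if (spec$isHMM) 1L else as.integer(dMaxFit)
      k <- k + 1L
      res <- tryCatch({
        fit <- fitHSMM(sim$trials, dMaxVal = d, useLatency = spec$useLatency,
                       tol = tol, maxIter = maxIter, nRestarts = nRestarts,
                       seed = fitSeeds[r, j])
        fit <- alignStates(fit)
        dec <- mapDecode(fit)
        m <- ripMetrics(dec$state, sTrue, y)
        data.frame(run = r, method = methods[j], dMaxFit = d,
                   rip = if (m@defined) m@rip else NA_real_,
                   err = m@err, err0 = m@err0,
                   muUnattended = fit@params@mu[1L],
                   muAttended = fit@params@mu[2L],
                   sigmaUnattended = fit@params@sigma[1L],
                   sigmaAttended = fit@params@sigma[2L])
      }, error = function(e)
        data.frame(run = r, method = methods[j], dMaxFit = d,
                   rip = NA_real_, err = NA_real_, err0 = NA_real_,
                   muUnattended = NA_real_, muAttended = NA_real_,
                   sigmaUnattended = NA_real_, sigmaAttended = NA_real_))
      rows[[k]] <- res
    }
  }
  runs <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(methods, function(mm) {
    x <- runs[runs$method == mm & !is.na(runs$rip), ]
    data.frame(method = mm,
               dMaxFit = if (nrow(x)) x$dMaxFit[1L] else NA_integer_,
               meanRip = mean(x$rip), semRip = stats::sd(x$rip) / sqrt(nrow(x)),
               nEffective = nrow(x),
               muUnattended = mean(x$muUnattended),
               muAttended = mean(x$muAttended),
               sigmaUnattended = mean(x$sigmaUnattended),
               sigmaAttended = mean(x$sigmaAttended))
  }))
  list(summary = summ, runs = runs)
}
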