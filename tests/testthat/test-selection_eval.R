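test_that("free-parameter counts follow the simplex dimensions", {
  p4 <- studyParameters()                       # M = 2, dMax = 4, explicit
  expect_identical(countFreeParams(p4), 15L)    # 1 + 2 + 6 + 2 + 4
  pg <- HSMMParameters(pi = p4@pi, A = p4@A, bern = p4@bern, mu = p4@mu,
                       sigma = p4@sigma, dMax = 4L,
                       durationModel = "geometric", geomRate = c(0.5, 0.5))
  expect_identical(countFreeParams(pg), 11L)    # 1 + 2 + 2 + 2 + 4
  p1 <- HSMMParameters(pi = p4@pi, A = p4@A, Pdur = matrix(1, 2, 1),
                       bern = p4@bern, mu = p4@mu, sigma = p4@sigma,
                       dMax = 1L)
  expect_identical(countFreeParams(p1), 9L)     # explicit P contributes 0
})

.scoreFixture <- function(logLik, params, Tn) {
  cache <- new("FBCache", alphaPred = array(0, c(0, 0, 0)),
               rho = matrix(0, 0, 0), rInv = numeric(0),
               E = matrix(0, 0, 0), F = matrix(0, 0, 0),
               beta = array(0, c(0, 0, 0)), EStar = matrix(0, 0, 0),
               FStar = matrix(0, 0, 0), alphaSmooth = array(0, c(0, 0, 0)),
               gammaSmooth = matrix(0, 0, 0), DSmooth = array(0, c(0, 0, 0)),
               TSmooth = array(0, c(0, 0, 0)), logLik = logLik)
  fit <- new("HSMMFit", params = params, posterior = cache,
             logLikTrace = logLik, nIter = 1L, converged = TRUE,
             nRestartsUsed = 1L, bestRestartSeed = 1L, useLatency = TRUE)
  modelScores(fit, TrialSequence(rep(1L, Tn), rep(100, Tn)))
}

test_that("AIC/BIC/order-score arithmetic", {
  p <- studyParameters()
  sc <- .scoreFixture(-50, p, 100)
  expect_equal(sc@aic, 130)                       # -2(-50) + 2*15
  expect_equal(sc@bic, 100 + 15 * log(100), tolerance = 1e-10)  # ~169.08
  expect_equal(sc@orderScore, 50 + 2 * (4 * 16)^2 * log(100), tolerance = 1e-9)
  expect_false(sc@predDefined)
  expect_identical(sc@predLogLik, 0)
})

test_that("predictive log-likelihood sums the held-out predictive terms", {
  p <- studyParameters()
  sim <- simulateHSMM(p, 120, seed = 71)
  train <- TrialSequence(outcomes(sim$trials)[1:96],
                         latencies(sim$trials)[1:96])
  test <- TrialSequence(outcomes(sim$trials)[97:120],
                        latencies(sim$trials)[97:120])
  fit <- fitHSMM(train, 4, nRestarts = 3, seed = 5)
  sc <- modelScores(fit, train, test)
  expect_true(sc@predDefined)
  # independent identity: forward pass over the concatenation minus the
  # training-prefix terms (the prefix is unaffected by future data)
  joint <- TrialSequence(c(train@y, test@y), c(train@z, test@z))
  fullLL <- forwardPass(joint, fit@params)@logLik
  trainLL <- forwardPass(train, fit@params)@logLik
  expect_equal(sc@predLogLik, fullLL - trainLL, tolerance = 1e-10)
})

test_that("order selection returns a choice and honors the grid", {
  p <- studyParameters()
  gen <- HSMMParameters(pi = p@pi, A = conditionOnChange(p@A), Pdur = p@Pdur,
                        bern = p@bern, mu = p@mu, sigma = p@sigma, dMax = 4L)
  sim <- simulateHSMM(gen, 100, seed = 81)
  one <- selectOrder(sim$trials, dMaxGrid = 3, nRestarts = 2, seed = 1)
  expect_identical(one$dMax, 3)
  expect_identical(nrow(one$table), 1L)

  res <- selectOrder(sim$trials, dMaxGrid = 1:4, criterion = "aic",
                     nRestarts = 3, seed = 2)
  expect_true(res$dMax %in% 1:4)
  expect_equal(res$table$dMax, c(1, 2, 3, 4))
  expect_true(all(is.finite(res$table$aic)))
  expect_true(all(is.finite(res$table$predLogLik)))
})

test_that("AIC prefers duration structure when it is really there", {
  p <- studyParameters()
  gen <- HSMMParameters(pi = p@pi, A = conditionOnChange(p@A), Pdur = p@Pdur,
                        bern = p@bern, mu = p@mu, sigma = p@sigma, dMax = 4L)
  hits <- 0
  for (s in 1:6) {
    sim <- simulateHSMM(gen, 150, seed = 300 + s)
    res <- selectOrder(sim$trials, dMaxGrid = 1:3, criterion = "aic",
                       nRestarts = 3, seed = s)
    if (res$dMax >= 2) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("RIP metrics follow their defining identities", {
  S <- c(1L, 1L, 0L, 0L, 1L)
  y <- c(1L, 0L, 0L, 1L, 1L)
  perfect <- ripMetrics(S, S, y)
  expect_equal(perfect@rip, 1)
  expect_identical(perfect@err, 0)
  baseline <- ripMetrics(y, S, y)
  expect_equal(baseline@rip, 0)

  # permutation invariance
  set.seed(2)
  Shat <- c(1L, 0L, 0L, 1L, 1L)
  perm <- sample(5)
  expect_equal(ripMetrics(Shat, S, y)@rip,
               ripMetrics(Shat[perm], S[perm], y[perm])@rip)

  und <- ripMetrics(c(0L, 1L), c(1L, 0L), c(1L, 0L))  # err0 = 0
  expect_false(und@defined)
  expect_error(ripMetrics(c(1L, 0L), c(1L), c(1L)), "equal length")
})

test_that("latency overlap is a symmetric fraction with known endpoints", {
  expect_equal(latencyOverlap(5, 0.2, 5, 0.2), 1, tolerance = 1e-6)
  a <- latencyOverlap(6, 0.5, 5, 0.2)
  b <- latencyOverlap(5, 0.2, 6, 0.5)
  expect_equal(a, b, tolerance = 1e-9)
  expect_gt(a, 0.13)
  expect_lt(a, 0.14)
  expect_true(latencyOverlap(9, 0.1, 2, 0.1) < 1e-6)
})

test_that("Monte-Carlo driver is seeded and reports coherent summaries", {
  m1 <- runMonteCarlo("hsmm", nRuns = 2, seed = 5, methods = "hsmm_both",
                      nRestarts = 2)
  m2 <- runMonteCarlo("hsmm", nRuns = 2, seed = 5, methods = "hsmm_both",
                      nRestarts = 2)
  expect_identical(m1$summary$meanRip, m2$summary$meanRip)
  expect_identical(m1$runs$rip, m2$runs$rip)

  m4 <- runMonteCarlo("hsmm", nRuns = 4, seed = 6, methods = "hsmm_both",
                      nRestarts = 2)
  x <- m4$runs$rip[!is.na(m4$runs$rip)]
  expect_equal(m4$summary$semRip, sd(x) / sqrt(length(x)), tolerance = 1e-12)
  expect_identical(m4$summary$nEffective, length(x))
})

test_that("latency information improves decoding over outcomes alone", {
  mc <- runMonteCarlo("hsmm", nRuns = 8, seed = 7,
                      methods = c("hsmm_both", "hsmm_y"), nRestarts = 4)
  s <- mc$summary
  expect_gt(s$meanRip[s$method == "hsmm_both"],
            s$meanRip[s$method == "hsmm_y"])
})
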