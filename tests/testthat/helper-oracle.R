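# Independent reference implementations used as oracles.  These share no
# code with the package: the brute-force oracle enumerates every latent
# (state, remaining-duration) path; the HMM helpers are the textbook
# forward algorithm and Baum-Welch.

# emission table b_m(y_t, z_t), computed directly from the density formula
oracleEmissions <- function(y, z, bern, mu, sigma) {
  Tn <- length(y)
  M <- length(bern)
  B <- matrix(0, Tn, M)
  for (m in seq_len(M)) {
    py <- ifelse(y == 1, bern[m], 1 - bern[m])
    pz <- exp(-(log(z) - mu[m])^2 / (2 * sigma[m]^2)) /
      (z * sqrt(2 * pi) * sigma[m])
    B[, m] <- py * pz
  }
  B
}

# enumerate all latent paths; returns likelihood and exact posteriors
bruteForceHSMM <- function(y, z, pi, A, P, bern, mu, sigma) {
  Tn <- length(y)
  M <- length(pi)
  D <- ncol(P)
  B <- oracleEmissions(y, z, bern, mu, sigma)
  codes <- expand.grid(rep(list(seq_len(M * D)), Tn))
  dec <- function(code) c((code - 1) %/% D + 1, (code - 1) %% D + 1)

  lik <- 0
  post <- array(0, c(Tn, M, D))
  Dpost <- array(0, c(Tn, M, D))
  Tpost <- array(0, c(Tn, M, M))
  for (i in seq_len(nrow(codes))) {
    md <- t(vapply(as.integer(codes[i, ]), dec, numeric(2)))
    p <- pi[md[1, 1]] * P[md[1, 1], md[1, 2]]
    ok <- TRUE
    if (Tn > 1) for (t in 2:Tn) {
      m0 <- md[t - 1, 1]; d0 <- md[t - 1, 2]
      m1 <- md[t, 1]; d1 <- md[t, 2]
      if (d0 > 1) {
        if (m1 != m0 || d1 != d0 - 1) { ok <- FALSE; break }
      } else p <- p * A[m0, m1] * P[m1, d1]
    }
    if (!ok || p == 0) next
    for (t in seq_len(Tn)) p <- p * B[t, md[t, 1]]
    lik <- lik + p
    for (t in seq_len(Tn)) {
      post[t, md[t, 1], md[t, 2]] <- post[t, md[t, 1], md[t, 2]] + p
      if (t == 1 || md[t - 1, 2] == 1)
        Dpost[t, md[t, 1], md[t, 2]] <- Dpost[t, md[t, 1], md[t, 2]] + p
      if (t > 1 && md[t - 1, 2] == 1)
        Tpost[t, md[t - 1, 1], md[t, 1]] <- Tpost[t, md[t - 1, 1], md[t, 1]] + p
    }
  }
  list(lik = lik, post = post / lik, D = Dpost / lik, TT = Tpost / lik)
}

# textbook HMM forward algorithm (log-likelihood only, scaled)
hmmForwardLogLik <- function(y, z, pi, A, bern, mu, sigma,
                             useLatency = TRUE) {
  Tn <- length(y)
  B <- oracleEmissions(y, z, bern, mu, sigma)
  if (!useLatency)
    B <- matrix(ifelse(rep(y, ncol(A)) == 1, rep(bern, each = Tn),
                       rep(1 - bern, each = Tn)), Tn)
  a <- pi * B[1, ]
  ll <- log(sum(a))
  a <- a / sum(a)
  if (Tn > 1) for (t in 2:Tn) {
    a <- as.vector(t(A) %*% a) * B[t, ]
    ll <- ll + log(sum(a))
    a <- a / sum(a)
  }
  ll
}

# textbook Baum-Welch for the mixed-emission HMM, from a given start
hmmBaumWelch <- function(y, z, init, tol = 1e-5, maxIter = 500) {
  Tn <- length(y)
  M <- length(init$pi)
  th <- init
  lz <- log(z)
  prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    B <- oracleEmissions(y, z, th$bern, th$mu, th$sigma)
    # scaled forward/backward
    alpha <- matrix(0, Tn, M); cvec <- numeric(Tn)
    a <- th$pi * B[1, ]; cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:Tn) {
      a <- as.vector(t(th$A) %*% alpha[t - 1, ]) * B[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    beta <- matrix(0, Tn, M); beta[Tn, ] <- 1
    for (t in (Tn - 1):1)
      beta[t, ] <- as.vector(th$A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    xi <- matrix(0, M, M)
    for (t in 2:Tn)
      xi <- xi + (alpha[t - 1, ] %o% (B[t, ] * beta[t, ])) * th$A / cvec[t]
    ll <- sum(log(cvec))
    trace <- c(trace, ll)
    if (abs(ll - prev) < tol) break
    prev <- ll
    tot <- colSums(gam)
    w <- sweep(gam, 2, tot, "/")
    muHat <- colSums(w * lz)
    s2 <- vapply(seq_len(M), function(m)
      sum(w[, m] * (lz - muHat[m])^2) / (1 - sum(w[, m]^2)), numeric(1))
    th <- list(pi = gam[1, ] / sum(gam[1, ]),
               A = xi / rowSums(xi),
               bern = colSums(gam * (y == 1)) / tot,
               mu = muHat,
               sigma = pmax(sqrt(pmax(s2, 0)), 0.01))
  }
  list(logLik = ll, theta = th, trace = trace)
}

# small, well-conditioned fixture parameters for oracle comparisons
toyParams <- function(dMaxVal = 2) {
  Pd <- if (dMaxVal == 2) rbind(c(0.4, 0.6), c(0.25, 0.75))
        else matrix(rep(1 / dMaxVal, 2 * dMaxVal), 2, byrow = TRUE)
  HSMMParameters(pi = c(0.6, 0.4),
                 A = rbind(c(0.3, 0.7), c(0.15, 0.85)),
                 Pdur = Pd,
                 bern = c(0.7, 0.05), mu = c(6, 5), sigma = c(0.5, 0.2),
                 dMax = dMaxVal)
}
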