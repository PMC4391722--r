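# attentionHSMM

Estimation of latent binary attentional states from simultaneous binary
trial outcomes and continuous response latencies, using a two-state
explicit-duration hidden semi-Markov model (HSMM).

## The problem

In trial-based behavioral experiments (e.g. a rodent visual detection
task), every trial yields a binary outcome `y` (correct/incorrect) and a
latency `z` (cue onset to response).  Neither observable equals the
underlying attentional state: correct choices occur by chance during
unattended exploration, and attended trials can still end in errors.
`attentionHSMM` is for experimenters who need principled per-trial
estimates of the latent state — for instance to relate attention to
simultaneous neurophysiology — rather than the naive assignment
`state := outcome`.

## The model

The latent chain `S_t ∈ {0, 1}` (0 = unattended, 1 = attended) is a hidden
semi-Markov chain: on entering state `m` it draws a sojourn duration
`d ∈ {1, …, d_max}` from an explicit distribution `p_m(d)` and transitions
only when the sojourn ends, by a row-stochastic matrix `A` (with
`d_max = 1` the model is a standard HMM; a truncated geometric duration
law is also available).  Emissions mix both measures, conditionally
independent given the state:

    b_m(y, z) = Pr(y | S = m) · logn(z | μ_m, σ_m)

Inference is maximum likelihood via a forward-backward EM algorithm on the
joint posterior of state and remaining sojourn time, `α_{t|t−1}(m, d)`,
using self-normalizing per-trial recursions (`ρ`, `r_t⁻¹`); the data
log-likelihood is `Σ_t log r_t⁻¹`.  States are decoded per trial by the
MAP rule `(Ŝ_t, τ̂_t) = argmax_{m,d} α_{t|T}(m, d)`.  Decoding quality is
scored against the naive estimator by the relative improvement percentage

    RIP = (err0 − err) / err0,   err = Σ (Ŝ_t − S_t)²,  err0 = Σ (y_t − S_t)²

The package also provides model-order selection for `d_max` (AIC/BIC and
predictive log-likelihood on a chronological 80/20 split), a
latency-distribution overlap measure, a generative simulator with
nonstationary and Markov variants, and a Monte-Carlo evaluation driver.

## Worked example

Simulate a 100-trial session from the canonical study parameters
(attended state: 95% correct, fast lognormal(5, 0.2) latencies; unattended:
30% correct, slow lognormal(6, 0.5); sojourn-end transitions conditioned
on leaving the state), fit by EM, and decode:

```r
library(attentionHSMM)

p   <- studyParameters()
gen <- HSMMParameters(pi = p@pi, A = conditionOnChange(p@A), Pdur = p@Pdur,
                      bern = p@bern, mu = p@mu, sigma = p@sigma, dMax = 4L)
sim <- simulateHSMM(gen, nTrials = 100, seed = 7)
sim$path
#> LatentPath with 100 trials, 37 segments (55.0% attended)

fit <- alignStates(fitHSMM(sim$trials, dMaxVal = 4, seed = 7))
fit
#> HSMMFit: logLik -616.1292 after 28 EM iterations (converged), 10 restart(s)
#> HSMMParameters: 2 states, dMax = 4, explicit durations
#>   bern: 0.346 0.942 | mu: 5.936 5.041 | sigma: 0.414 0.185

dec <- mapDecode(fit)
head(dec, 4)
#>   trial state tau    pAttended
#> 1     1     0   2 0.000000e+00
#> 2     2     0   1 2.535742e-15
#> 3     3     1   3 9.926788e-01
#> 4     4     1   2 1.000000e+00

ripMetrics(dec$state, states(sim$path), outcomes(sim$trials))
#> EvalMetrics: err = 1, err0 = 19, RIP = 0.9474
```

The fitted emission parameters sit close to the generative truth
(`bern ≈ (0.30, 0.95)`, `μ ≈ (6, 5)`, `σ ≈ (0.5, 0.2)`), and decoding
misassigns 1 trial where the raw outcomes misassign 19 — a relative
improvement of 0.95 for this session.  How separable the two states are
from latency alone is quantified by the overlap of the two densities:

```r
latencyOverlap(6, 0.5, 5, 0.2)
#> [1] 0.1358
```

A command-line wrapper with `simulate`, `fit`, `decode`, `select` and
`benchmark` subcommands is installed under `exec/attention-hsmm`.

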