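# Report every failure rather than terminating the run early: the
# study-scale reproduction file runs first alphabetically and its Monte-Carlo
# comparisons must not mask the unit suites that follow.
options(testthat.progress.max_fails = 500L)
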