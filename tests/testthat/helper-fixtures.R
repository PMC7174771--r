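# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

# A participant whose planted responses are 10x the white-noise floor,
# plus the full pipeline report on it. Built once per test run.
high_snr_config <- function(seed = 101L) {
  simulation_config(seed = seed, response_amplitude_hbo = 1.0)
}

get_high_snr_participant <- function() {
  if (is.null(.fixtures$participant)) {
    .fixtures$participant <- simulate_participant(high_snr_config())
  }
  .fixtures$participant
}

get_high_snr_report <- function() {
  if (is.null(.fixtures$report)) {
    .fixtures$report <- run_pipeline(get_high_snr_participant())
  }
  .fixtures$report
}

# Small hemo_ts from a matrix replicated into both chromophores.
matrix_hemo <- function(m, fs = 12.5) hemo_ts(as.matrix(m), fs)

# Direct normal-equation OLS + contrast t (independent oracle for the
# GLM path).
oracle_ols_t <- function(X, y, contrast) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  eff <- drop(t(contrast) %*% beta)
  se <- sqrt(s2 * drop(t(contrast) %*% solve(XtX, contrast)))
  list(beta = drop(beta), t = eff / se)
}
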