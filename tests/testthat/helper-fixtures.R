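# Fixtures built in code: tiny FCN stacks with known structure.

# FCN stack that alternates between the given correlation matrices
# according to `labels` (0-based).
fcn_from_states <- function(states, labels, tr_ms = 2500) {
  R <- nrow(states[[1]])
  arr <- array(NA_real_, c(length(labels), R, R))
  for (t in seq_along(labels)) arr[t, , ] <- states[[labels[t] + 1L]]
  fcn_sequence(arr, tr_ms = tr_ms)
}

# A valid correlation matrix with constant off-diagonal rho.
constant_correlation <- function(R, rho) {
  m <- matrix(rho, R, R)
  diag(m) <- 1
  m
}

# Small two-state noise-free test stack: 2 clearly different states.
two_state_fcn <- function(Tn = 20, R = 5) {
  states <- list(constant_correlation(R, 0.8), constant_correlation(R, 0.1))
  fcn_from_states(states, rep(c(0L, 1L), length.out = Tn))
}
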