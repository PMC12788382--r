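test_that("state correlation sets are valid correlation matrices", {
  cs <- make_state_correlation_set(K = 3, R = 8, separation = 0.7, seed = 11)
  expect_length(cs, 3)
  for (C in cs) {
    expect_equal(diag(C), rep(1, 8))
    expect_lte(max(abs(C)), 1)
    expect_equal(C, t(C))
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  one <- make_state_correlation_set(K = 1, R = 3, separation = 0.5, seed = 2)
  expect_equal(diag(one[[1]]), rep(1, 3))
})

test_that("between-state distance grows with separation and is deterministic", {
  lo <- make_state_correlation_set(K = 2, R = 10, separation = 0.1, seed = 7)
  hi <- make_state_correlation_set(K = 2, R = 10, separation = 1.0, seed = 7)
  frob <- function(s) sqrt(sum((s[[1]] - s[[2]])^2))
  expect_gt(frob(hi), frob(lo))
  again <- make_state_correlation_set(K = 3, R = 20, separation = 0.8,
                                      seed = 42)
  expect_identical(make_state_correlation_set(3, 20, 0.8, seed = 42), again)
})

test_that("state label sequences follow the latent trajectory", {
  expect_identical(simulate_state_labels(60, 10, K = 1, tr = 645, seed = 5),
                   rep(0L, floor(60000 / 645)))
  expect_length(simulate_state_labels(60, 10, K = 3, tr = 2500, seed = 5), 24)
  # same latent trajectory at two TRs: labels agree at coincident times
  fine <- simulate_state_labels(100, 8, K = 3, tr = 1250, seed = 9)
  coarse <- simulate_state_labels(100, 8, K = 3, tr = 2500, seed = 9)
  expect_identical(coarse, fine[seq(1, length(fine), by = 2)][seq_along(coarse)])
  expect_error(simulate_state_labels(10, 5, K = 2, tr = 20000, seed = 1),
               "exceeds")
})

test_that("empirical mean dwell time matches the configured rate", {
  lab <- simulate_state_labels(600, 10, K = 3, tr = 645, seed = 1)
  runs <- rle(lab)$lengths
  # drop the truncated final visit
  emp <- mean(head(runs, -1)) * 0.645
  expect_lt(abs(emp - 10) / 10, 0.3)
})

test_that("noise-free FCN sequences reproduce the planted states exactly", {
  cfg <- synthetic_config(n_regions = 6, n_states = 2, tr_list = c(2500),
                          total_duration = 60, mean_dwell = 8,
                          noise_sigma = 0, seed = 3)
  sim <- simulate_fcn_sequence(cfg)
  lab <- sim$ground_truth$labels[[1]]
  expect_gte(length(unique(lab)), 2)
  for (t in seq_along(lab)) {
    expect_identical(sim$cohorts[[1]]$matrices[t, , ],
                     sim$ground_truth$state_correlations[[lab[t] + 1L]])
  }
  # distinct matrices in the stack == states visited
  flat <- apply(sim$cohorts[[1]]$matrices, 1, paste, collapse = ",")
  expect_equal(length(unique(flat)), length(unique(lab)))
})

test_that("cohorts of one config share the latent trajectory and planted k", {
  cfg <- synthetic_config(n_regions = 5, n_states = 3,
                          tr_list = c(1250, 2500), total_duration = 80,
                          mean_dwell = 10, seed = 21)
  sim <- simulate_fcn_sequence(cfg)
  expect_equal(sim$ground_truth$planted_k, 3)
  fine <- sim$ground_truth$labels$tr1250
  coarse <- sim$ground_truth$labels$tr2500
  expect_identical(coarse, fine[seq(1, by = 2, length.out = length(coarse))])
  expect_identical(simulate_fcn_sequence(cfg)$cohorts, sim$cohorts)
})

test_that("correlation repair is idempotent on valid inputs", {
  for (s in 1:5) {
    C <- make_state_correlation_set(1, 7, 0.9, seed = s)[[1]]
    expect_lt(max(abs(tempoph:::repair_correlation(C) - C)), 1e-12)
  }
  # and actually repairs an invalid perturbation
  set.seed(1)
  M <- constant_correlation(5, 0.9) + matrix(rnorm(25, sd = 0.4), 5, 5)
  M <- (M + t(M)) / 2
  rep1 <- tempoph:::repair_correlation(M)
  expect_gte(min(eigen(rep1, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(diag(rep1), rep(1, 5))
})

test_that("simulated ROI time series carry the planted covariance", {
  cfg <- synthetic_config(n_regions = 4, n_states = 1, tr_list = c(100),
                          total_duration = 500, mean_dwell = 50,
                          seed = 8, mode = "signal")
  sim <- simulate_roi_timeseries(cfg)
  X <- sim$cohorts[[1]]$values
  expect_gte(nrow(X), 5000)
  expect_lt(max(abs(cor(X) - sim$ground_truth$state_correlations[[1]])), 0.1)
  expect_identical(simulate_roi_timeseries(cfg)$cohorts, sim$cohorts)
})

test_that("config validation rejects degenerate designs", {
  expect_error(synthetic_config(n_regions = 1), "n_regions")
  expect_error(synthetic_config(tr_list = c(645, -5)), "positive")
  expect_error(synthetic_config(total_duration = 4, tr_list = 2500), ">= 3")
  expect_error(synthetic_config(noise_sigma = -0.1), "noise_sigma")
  expect_error(synthetic_config(state_separation = 1.5), "state_separation")
})
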