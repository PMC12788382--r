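test_that("sliding-window Pearson handles perfect (anti)correlation", {
  base <- cumsum(rnorm(30)) + seq_len(30)
  ts <- roi_timeseries(cbind(base, base + 2, -base), tr_ms = 1400)
  fcn <- sliding_window_pearson(ts, window = 5)
  for (t in 5:30) {
    expect_equal(fcn$matrices[t, 1, 2], 1)
    expect_equal(fcn$matrices[t, 1, 3], -1)
  }
  expect_equal(dim(fcn$matrices), c(30, 3, 3))
})

test_that("trailing 3-sample window reproduces the hand-computed Pearson r", {
  ts <- roi_timeseries(cbind(c(1, 2, 3), c(1, 2, 4)), tr_ms = 1400)
  fcn <- sliding_window_pearson(ts, window = 3)
  # 3-sample Pearson of (1,2,3) vs (1,2,4): 7/sqrt(2 * 2 * 14/2... ) = 0.98198
  expect_equal(fcn$matrices[3, 1, 2], cor(c(1, 2, 3), c(1, 2, 4)))
  expect_lt(abs(fcn$matrices[3, 1, 2] - 0.98198), 1e-4)
})

test_that("constant series give flagged zero correlation, never NaN", {
  ts <- roi_timeseries(cbind(rep(1, 10), rnorm(10)), tr_ms = 1400)
  fcn <- sliding_window_pearson(ts, window = 4)
  expect_false(anyNA(fcn$matrices))
  expect_equal(fcn$matrices[8, 1, 2], 0)
  expect_true(all(attr(fcn, "degenerate")))
})

test_that("full-width window equals the static correlation", {
  set.seed(4)
  X <- matrix(rnorm(40 * 4), 40, 4)
  ts <- roi_timeseries(X, tr_ms = 645)
  fcn <- sliding_window_pearson(ts, window = 40)
  expect_equal(fcn$matrices[40, , ], unname(cor(X)), tolerance = 1e-12)
})

test_that("correlation-to-distance maps the anchor points correctly", {
  p <- c(-1, 0, 1)
  arr <- array(NA_real_, c(3, 2, 2))
  for (t in 1:3) arr[t, , ] <- matrix(c(1, p[t], p[t], 1), 2, 2)
  fcn <- fcn_sequence(arr, tr_ms = 2500)
  ds <- correlation_to_distance(fcn, "sqrt_half")
  expect_equal(ds$matrices[, 1, 2], c(1, sqrt(0.5), 0))
  expect_lt(abs(ds$matrices[2, 1, 2] - 0.70711), 1e-5)
  dh <- correlation_to_distance(fcn, "half")
  expect_equal(dh$matrices[, 1, 2], c(1, 0.5, 0))
  expect_error(correlation_to_distance(fcn, "exp"), "arg")
})

test_that("distances lie in [0,1], are antitone in correlation, zero-diagonal", {
  set.seed(9)
  for (rep in 1:20) {
    C <- tempoph:::repair_correlation(matrix(runif(36, -1, 1), 6, 6))
    arr <- array(C, c(1, 6, 6))
    for (f in c("sqrt_half", "half")) {
      d <- correlation_to_distance(fcn_sequence(arr, 1400), f)$matrices[1, , ]
      expect_true(all(d >= 0 & d <= 1))
      expect_equal(diag(d), rep(0, 6))
      ord_c <- order(C[upper.tri(C)])
      ord_d <- order(-d[upper.tri(d)])
      expect_equal(ord_c, ord_d)
    }
  }
})

test_that("ADF window ladder separates stationary from unit-root series", {
  set.seed(12)
  # independent white-noise replicates: the smallest width should win for
  # the majority of draws (the 90%-of-ROIs rule demands a joint rejection,
  # which caps the attainable rate well below 1 at 20-sample windows)
  hits <- replicate(40, {
    ts <- roi_timeseries(matrix(rnorm(60 * 4), 60, 4), tr_ms = 645)
    as.integer(adf_window_width(ts, 60, min_w = 20))
  })
  expect_gte(mean(hits == 20), 0.45)
  expect_equal(sort(unique(hits))[1], 20L)

  # unit-root series: escalate to max_w and come back flagged
  walks <- replicate(20, {
    ts <- roi_timeseries(apply(matrix(rnorm(60 * 4), 60, 4), 2, cumsum),
                         tr_ms = 645)
    res <- adf_window_width(ts, 60, min_w = 20, max_w = 50)
    as.integer(res) * ifelse(attr(res, "flagged"), -1L, 1L)
  })
  expect_gte(mean(walks == -50L), 0.7)

  fixed <- adf_window_width(roi_timeseries(matrix(rnorm(400), 100, 4), 645),
                            100, min_w = 30, max_w = 30)
  expect_equal(as.integer(fixed), 30)
})

test_that("adf-driven windows plug into sliding_window_pearson", {
  set.seed(3)
  ts <- roi_timeseries(matrix(rnorm(60 * 3), 60, 3), tr_ms = 645)
  fcn <- sliding_window_pearson(ts, window = "adf", adf_min = 10)
  expect_length(fcn$window_widths, 60)
  expect_true(all(fcn$window_widths >= 10))
})

test_that("input validation catches malformed series and windows", {
  expect_error(roi_timeseries(matrix(1:4, 2, 2), 1400), "3 timepoints")
  expect_error(roi_timeseries(matrix(c(1, NA, 3, 4, 5, 6), 3, 2), 1400), "NA")
  ts <- roi_timeseries(matrix(rnorm(30), 10, 3), tr_ms = 645)
  expect_error(sliding_window_pearson(ts, window = 2), "integer >= 3")
  expect_error(sliding_window_pearson(ts, window = 11), "exceeds")
})
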