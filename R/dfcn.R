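# Construction of per-timepoint functional connectivity networks (FCNs)
# from ROI time series, and the correlation-to-distance transform feeding
# the Vietoris-Rips filtration.

#' ROI time-series container
#'
#' @param values `T x R` numeric matrix: `T` timepoints of `R` regional mean
#'   signals (arbitrary BOLD units).
#' @param tr_ms Sampling period in milliseconds.
#' @param subject_id Subject identifier.
#' @return A `tempoph_ts` object.
#' @export
roi_timeseries <- function(values, tr_ms, subject_id = "subject") {
  values <- as.matrix(values)
  if (nrow(values) < 3L) stop_param("need at least 3 timepoints")
  if (ncol(values) < 2L) stop_param("need at least 2 regions")
  if (anyNA(values)) stop_param("time series contains NA/NaN")
  tr_ms <- check_scalar(tr_ms, "tr_ms", min = 0, strict_min = TRUE)
  structure(list(values = values, tr_ms = tr_ms, subject_id = subject_id),
            class = "tempoph_ts")
}

#' FCN sequence container
#'
#' Validates a `T x R x R` stack of per-timepoint correlation matrices:
#' symmetric, unit diagonal, entries in `[-1, 1]` (all within numerical
#' tolerance).
#'
#' @param matrices `T x R x R` numeric array.
#' @param tr_ms Sampling period in milliseconds.
#' @param window_widths Optional integer vector of per-timepoint window
#'   widths (samples) used to build the stack.
#' @return A `tempoph_fcn` object.
#' @export
fcn_sequence <- function(matrices, tr_ms, window_widths = NULL) {
  stopifnot(is.array(matrices), length(dim(matrices)) == 3L)
  d <- dim(matrices)
  if (d[2] != d[3]) stop_param("matrices must be square (got %d x %d)",
                               d[2], d[3])
  if (anyNA(matrices)) stop_param("FCN stack contains NA/NaN")
  for (t in seq_len(d[1])) {
    m <- matrices[t, , ]
    if (max_asymmetry(m) > 1e-8)
      stop_param("FCN at timepoint %d is not symmetric", t - 1L)
    if (max(abs(diag(m) - 1)) > 1e-6)
      stop_param("FCN at timepoint %d does not have unit diagonal", t - 1L)
    if (max(abs(m)) > 1 + 1e-9)
      stop_param("FCN at timepoint %d has entries outside [-1, 1]", t - 1L)
  }
  matrices[matrices > 1] <- 1
  matrices[matrices < -1] <- -1
  structure(list(matrices = matrices, tr_ms = tr_ms,
                 window_widths = window_widths),
            class = "tempoph_fcn")
}

#' Sliding-window Pearson correlation
#'
#' Computes, for every timepoint `t`, the pairwise Pearson correlation of
#' the ROI signals over a trailing window ending at `t` (truncated at the
#' series start), yielding one FCN per timepoint. Window widths may be a
#' single fixed width, a per-timepoint vector, or `"adf"` to determine the
#' width at each timepoint by stationarity ([adf_window_width()]).
#'
#' Pairs that are constant within a window get correlation 0 (flagged via
#' the `degenerate` attribute), never `NaN`.
#'
#' @param ts A [roi_timeseries()].
#' @param window Single width, length-`T` integer vector, or `"adf"`.
#' @param adf_min,adf_max,adf_alpha ADF ladder parameters when
#'   `window = "adf"` (`adf_max = NULL` means the full series length).
#' @return A `tempoph_fcn` with `T` matrices and the per-timepoint widths.
#' @export
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(200), 50, 4), tr_ms = 1400)
#' fcn <- sliding_window_pearson(ts, window = 10)
sliding_window_pearson <- function(ts, window,
                                   adf_min = 20, adf_max = NULL,
                                   adf_alpha = 0.05) {
  stopifnot(inherits(ts, "tempoph_ts"))
  X <- ts$values
  Tn <- nrow(X)
  R <- ncol(X)
  if (identical(window, "adf")) {
    adf_max <- adf_max %||% Tn
    widths <- vapply(seq_len(Tn), function(t) {
      adf_window_width(ts, t, min_w = adf_min, max_w = adf_max,
                       alpha = adf_alpha)
    }, numeric(1))
  } else if (length(window) == 1L) {
    widths <- rep(check_count(window, "window", min = 3L), Tn)
  } else {
    if (length(window) != Tn)
      stop_param("per-timepoint window spec must have length T = %d", Tn)
    widths <- vapply(window, check_count, integer(1), name = "window",
                     min = 3L)
  }
  if (any(widths > Tn))
    stop_param("window width exceeds series length T = %d", Tn)
  arr <- array(NA_real_, c(Tn, R, R))
  degenerate <- logical(Tn)
  for (t in seq_len(Tn)) {
    idx <- max(1L, t - widths[t] + 1L):t
    W <- X[idx, , drop = FALSE]
    if (nrow(W) < 2L) {
      C <- matrix(0, R, R)
      degenerate[t] <- TRUE
    } else {
      C <- suppressWarnings(cor(W))
      if (anyNA(C)) {        # zero-variance columns
        degenerate[t] <- TRUE
        C[is.na(C)] <- 0
      }
    }
    diag(C) <- 1
    C[C > 1] <- 1
    C[C < -1] <- -1
    arr[t, , ] <- (C + t(C)) / 2
  }
  out <- fcn_sequence(arr, tr_ms = ts$tr_ms, window_widths = as.integer(widths))
  attr(out, "degenerate") <- degenerate
  out
}

# Design matrix and response for the ADF regression with `lags` lagged
# differences, optionally trimmed to start at `offset` (so fits with
# different lag orders can share a common sample for AIC comparison):
# diff(y) ~ intercept + lag(y) + lagged diffs.
adf_design <- function(y, lags, offset = lags) {
  n <- length(y)
  dy <- diff(y)
  nd <- length(dy)
  rows <- (offset + 1):nd
  Xr <- cbind(intercept = 1, level = y[rows])
  if (lags > 0) {
    lagged <- vapply(seq_len(lags), function(j) dy[rows - j], numeric(length(rows)))
    Xr <- cbind(Xr, lagged)
  }
  list(X = Xr, yr = dy[rows])
}

adf_tstat_fit <- function(X, yr) {
  if (nrow(X) <= ncol(X) + 1L) return(NA_real_)
  fit <- lm.fit(X, yr)
  if (fit$rank < ncol(X)) return(NA_real_)  # collinear window
  rss <- sum(fit$residuals^2)
  dfree <- nrow(X) - fit$rank
  if (dfree <= 0 || rss <= 0) return(NA_real_)
  s2 <- rss / dfree
  vc <- tryCatch(s2 * solve(crossprod(X)), error = function(e) NULL)
  if (is.null(vc)) return(NA_real_)
  as.numeric(fit$coefficients["level"] / sqrt(vc["level", "level"]))
}

# Augmented Dickey-Fuller t-statistic for the unit-root null, with constant
# and no trend. The number of lagged differences is chosen by AIC over
# 0..maxlag (Schwert bound) on a common trimmed sample, then the test is
# refit on the full available sample — mirroring standard adfuller
# implementations.
adf_statistic <- function(y, lags = NULL) {
  n <- length(y)
  if (is.null(lags)) {
    maxlag <- max(0L, min(trunc((n - 1)^(1 / 3)), n %/% 2L - 3L))
    if (maxlag > 0L) {
      aic <- vapply(0:maxlag, function(p) {
        d <- adf_design(y, p, offset = maxlag)
        if (nrow(d$X) <= ncol(d$X) + 1L) return(Inf)
        fit <- lm.fit(d$X, d$yr)
        rss <- sum(fit$residuals^2)
        if (rss <= 0 || fit$rank < ncol(d$X)) return(Inf)
        nobs <- nrow(d$X)
        nobs * log(rss / nobs) + 2 * (fit$rank + 1)
      }, numeric(1))
      lags <- if (all(is.infinite(aic))) 0L else (0:maxlag)[which.min(aic)]
    } else lags <- 0L
  }
  lags <- max(0L, min(as.integer(lags), n - 4L))
  d <- adf_design(y, lags)
  adf_tstat_fit(d$X, d$yr)
}

# MacKinnon finite-sample critical values for the ADF test, constant/no
# trend, at the three conventional levels. `n` is the number of regression
# observations.
adf_critical_value <- function(alpha, n) {
  tab <- list(
    `0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
    `0.05` = c(-2.86154, -2.8903, -4.234, -40.040),
    `0.1`  = c(-2.56677, -1.5384, -2.809, 0)
  )
  key <- as.character(alpha)
  if (!key %in% names(tab))
    stop_param("alpha must be one of 0.01, 0.05, 0.1")
  b <- tab[[key]]
  b[1] + b[2] / n + b[3] / n^2 + b[4] / n^3
}

#' Stationarity-adaptive window width via the ADF test
#'
#' Walks a doubling ladder of candidate widths from `min_w` to `max_w` and
#' returns the smallest width for which at least a fraction `frac` of the
#' (non-degenerate) ROI series in the trailing window ending at `t` reject
#' the ADF unit-root null at level `alpha`. If no width qualifies, returns
#' `max_w` with attribute `flagged = TRUE`.
#'
#' @param ts A [roi_timeseries()].
#' @param t Timepoint (1-based) at which the window ends.
#' @param min_w,max_w Smallest/largest candidate width in samples.
#' @param alpha Test level (0.01, 0.05 or 0.1).
#' @param frac Required fraction of stationary ROI series (default 0.9).
#' @return Integer width with logical attribute `flagged`.
#' @export
adf_window_width <- function(ts, t, min_w = 20, max_w = nrow(ts$values),
                             alpha = 0.05, frac = 0.9) {
  stopifnot(inherits(ts, "tempoph_ts"))
  Tn <- nrow(ts$values)
  min_w <- check_count(min_w, "min_w", min = 3L)
  max_w <- check_count(max_w, "max_w", min = min_w)
  if (max_w > Tn) stop_param("max_w exceeds series length T = %d", Tn)
  t <- check_count(t, "t", min = 1L)
  ladder <- min_w
  while (ladder[length(ladder)] * 2L < max_w)
    ladder <- c(ladder, ladder[length(ladder)] * 2L)
  if (ladder[length(ladder)] < max_w) ladder <- c(ladder, max_w)
  for (w in ladder) {
    idx <- max(1L, t - w + 1L):t
    W <- ts$values[idx, , drop = FALSE]
    stats <- apply(W, 2, function(y) {
      if (length(y) < 8L || stats::sd(y) == 0) return(NA_real_)
      adf_statistic(y)
    })
    usable <- !is.na(stats)
    if (!any(usable)) next
    cv <- adf_critical_value(alpha, length(idx) - 1L)
    if (mean(stats[usable] < cv) >= frac)
      return(structure(as.integer(w), flagged = FALSE))
  }
  structure(as.integer(max_w), flagged = TRUE)
}

#' Transform correlations to filtration distances
#'
#' Maps each FCN's Pearson correlations to nonnegative distances so the
#' stack can enter a Vietoris-Rips filtration: `sqrt_half` uses
#' `d = sqrt((1 - pcc) / 2)` (the chord distance of standardized signals, a
#' true metric); `half` uses `d = (1 - pcc) / 2`. Both map correlation 1 to
#' distance 0 and correlation -1 to distance 1, strictly decreasing in the
#' correlation; diagonals are forced to 0.
#'
#' @param fcn A `tempoph_fcn`.
#' @param formula `"sqrt_half"` (default) or `"half"`.
#' @return A `tempoph_distseq`: list with `matrices` (`T x R x R`),
#'   `formula`, `tr_ms`.
#' @export
#' @examples
#' arr <- array(rep(diag(3), 2), c(3, 3, 2))
#' fcn <- fcn_sequence(aperm(arr, c(3, 1, 2)), tr_ms = 2500)
#' d <- correlation_to_distance(fcn)
correlation_to_distance <- function(fcn, formula = c("sqrt_half", "half")) {
  stopifnot(inherits(fcn, "tempoph_fcn"))
  formula <- match.arg(formula)
  p <- fcn$matrices
  p[p > 1] <- 1
  p[p < -1] <- -1
  d <- if (formula == "sqrt_half") sqrt((1 - p) / 2) else (1 - p) / 2
  for (t in seq_len(dim(d)[1])) diag(d[t, , ]) <- 0
  structure(list(matrices = d, formula = formula, tr_ms = fcn$tr_ms),
            class = "tempoph_distseq")
}
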