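#' RR interval series
#'
#' Ordered intervals between consecutive ventricular beats (ms) with a
#' per-interval validity mask; intervals adjacent to ectopic beats are marked
#' invalid and excluded from all characteristics.
#'
#' @param intervals RR intervals (ms), all > 0.
#' @param valid logical mask, same length as `intervals`.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, valid = rep(TRUE, length(intervals))) {
  stopifnot(is.numeric(intervals), length(valid) == length(intervals),
            is.logical(valid))
  if (any(intervals <= 0)) stop("RR intervals must be positive")
  structure(list(intervals = as.numeric(intervals), valid = valid),
            class = "rr_series")
}

as_rr <- function(x) {
  if (inherits(x, "rr_series")) x else rr_series(x)
}

#' Mask intervals adjacent to ectopic beats
#'
#' The intervals immediately preceding and following each flagged beat are
#' marked invalid.  Beats are indexed 1..(N+1) for N intervals: beat `b`
#' bounds intervals `b - 1` and `b`.
#'
#' @param rr an `rr_series` (or numeric intervals).
#' @param ectopic_beats logical vector over beats (length N+1), or integer
#'   beat indices.
#' @return The `rr_series` with an updated validity mask.
#' @export
mask_ectopic <- function(rr, ectopic_beats) {
  rr <- as_rr(rr)
  n <- length(rr$intervals)
  if (is.logical(ectopic_beats)) {
    stopifnot(length(ectopic_beats) == n + 1L)
    idx <- which(ectopic_beats)
  } else {
    idx <- as.integer(ectopic_beats)
    stopifnot(all(idx >= 1L), all(idx <= n + 1L))
  }
  bad <- unique(c(idx - 1L, idx))
  bad <- bad[bad >= 1L & bad <= n]
  rr$valid[bad] <- FALSE
  rr
}

#' Mean RR interval
#'
#' Arithmetic mean over the valid intervals (ms); the heart-rate
#' characteristic.
#'
#' @param rr an `rr_series` or numeric vector of intervals (ms).
#' @return Mean RR (ms).
#' @export
rr_mean <- function(rr) {
  rr <- as_rr(rr)
  x <- rr$intervals[rr$valid]
  if (length(x) < 1L) stop("no valid RR intervals")
  mean(x)
}

#' RMSSD of the RR series
#'
#' Root mean square of successive RR interval differences (ms); the
#' variability characteristic.  Differences spanning an excluded interval are
#' omitted.
#'
#' @inheritParams rr_mean
#' @return RMSSD (ms).
#' @export
rr_rmssd <- function(rr) {
  rr <- as_rr(rr)
  x <- rr$intervals
  n <- length(x)
  if (n < 2L) stop("need at least two intervals")
  keep <- rr$valid[-n] & rr$valid[-1L]
  if (!any(keep)) stop("no valid successive RR interval pair")
  sqrt(mean(diff(x)[keep]^2))
}

#' Sample entropy of the RR series
#'
#' The irregularity characteristic: \eqn{-\ln(B_{m+1}/B_m)}, where \eqn{B_l}
#' counts ordered template pairs (length `l`, start indices 1..N-m, i != j)
#' whose Chebyshev distance is strictly below `r` times the sample standard
#' deviation of the series.  Templates containing an excluded interval are
#' omitted from both counts.
#'
#' @inheritParams rr_mean
#' @param m template length (default 2).
#' @param r tolerance factor (default 0.2), applied to the valid-interval
#'   sample standard deviation (n-1 denominator).
#' @return Sample entropy (dimensionless).
#' @export
rr_sample_entropy <- function(rr, m = 2, r = 0.2) {
  rr <- as_rr(rr)
  stopifnot(m >= 1, r > 0)
  x <- rr$intervals
  if (length(x) < m + 2L) stop("need at least m + 2 intervals")
  s <- sd(x[rr$valid])
  if (!is.finite(s) || s <= 0)
    stop("sample entropy undefined: series standard deviation is zero")
  cnt <- cpp_sampen_counts(x, rr$valid, as.integer(m), r * s)
  if (cnt[1] == 0)
    stop("sample entropy undefined: no template matches at length m")
  if (cnt[2] == 0)
    stop("sample entropy undefined: no template matches at length m + 1")
  -log(cnt[2] / cnt[1])
}

#' Metric configuration
#'
#' Template length and tolerance for the sample entropy, and the sliding
#' window lengths used for trends: `window_mean` beats for the mean RR trend
#' (shorter for temporal resolution) and `window_var` beats for the
#' variability and irregularity trends (longer for estimation accuracy).
#'
#' @param m template length, >= 1.
#' @param r tolerance factor, > 0.
#' @param window_mean,window_var sliding window lengths (beats), >= m + 2.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(m = 2, r = 0.2, window_mean = 100, window_var = 200) {
  stopifnot(m >= 1, r > 0, window_mean >= m + 2, window_var >= m + 2)
  structure(list(m = m, r = r, window_mean = window_mean,
                 window_var = window_var), class = "metric_config")
}

#' Sliding-window metric trend
#'
#' Evaluates a characteristic on each trailing window of `N` intervals,
#' advanced one beat at a time, timestamped at the window's last beat.  The
#' windowed sample entropy uses each window's own standard deviation for the
#' tolerance.  Windows on which a metric is undefined (e.g. zero variance or
#' no template matches) yield `NA`.
#'
#' @param rr an `rr_series` or numeric intervals (ms).
#' @param beat_times_s times (s) of the beat ending each interval (same
#'   length as the intervals).
#' @param metric one of `"mean"`, `"rmssd"`, `"sampen"`.
#' @param N window length in intervals, `N <= length(rr)`.
#' @param m,r sample-entropy settings (used for `metric = "sampen"`).
#' @return A data frame of class `trend_series` with `time_s` and `value`
#'   (L - N + 1 rows).
#' @export
sliding_trend <- function(rr, beat_times_s, metric = c("mean", "rmssd", "sampen"),
                          N, m = 2, r = 0.2) {
  rr <- as_rr(rr)
  metric <- match.arg(metric)
  x <- rr$intervals
  v <- rr$valid
  L <- length(x)
  stopifnot(length(beat_times_s) == L)
  if (N > L) stop("window length N exceeds the series length")
  val <- switch(metric,
    mean = {
      cs <- cumsum(c(0, x * v))
      cn <- cumsum(c(0, as.numeric(v)))
      s <- cs[(N + 1):(L + 1)] - cs[1:(L - N + 1)]
      k <- cn[(N + 1):(L + 1)] - cn[1:(L - N + 1)]
      ifelse(k > 0, s / k, NA_real_)
    },
    rmssd = {
      dv <- v[-L] & v[-1L]
      d2 <- diff(x)^2 * dv
      cs <- cumsum(c(0, d2))
      cn <- cumsum(c(0, as.numeric(dv)))
      # window s..s+N-1 uses differences s..s+N-2
      s <- cs[N:L] - cs[1:(L - N + 1)]
      k <- cn[N:L] - cn[1:(L - N + 1)]
      ifelse(k > 0, sqrt(s / k), NA_real_)
    },
    sampen = cpp_sampen_trend(x, v, as.integer(m), r, as.integer(N))
  )
  structure(data.frame(time_s = beat_times_s[N:L], value = val),
            class = c("trend_series", "data.frame"))
}
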