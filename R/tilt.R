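#' Tilt-test protocol
#'
#' Segment structure of the simulated tilt test: supine, head-down tilt (HDT)
#' and head-up tilt (HUT), each with a duration and a pair of autonomic-tone
#' scales that stay constant within the position.  Supine is the reference
#' state and must have `a_r = a_d = 1`.  The defaults are the best-fit
#' extension scales: HDT `(1, 0.9)` (10% shorter conduction delay) and HUT
#' `(0.95, 0.9)` (5% shorter refractory period, 10% shorter delay).
#'
#' @param durations_s segment durations in seconds.
#' @param a_r,a_d per-segment tone scales (length 3, supine first).
#' @return An object of class `tilt_protocol`.
#' @export
tilt_protocol <- function(durations_s = c(300, 300, 300),
                          a_r = c(1, 1, 0.95), a_d = c(1, 0.9, 0.9)) {
  stopifnot(length(durations_s) == 3, all(durations_s > 0),
            length(a_r) == 3, length(a_d) == 3,
            all(a_r > 0), all(a_d > 0))
  if (a_r[1] != 1 || a_d[1] != 1)
    stop("supine scales must be a_r = a_d = 1 (reference position)")
  structure(list(labels = c("supine", "hdt", "hut"),
                 durations_s = durations_s, a_r = a_r, a_d = a_d),
            class = "tilt_protocol")
}

protocol_schedule <- function(protocol, extended = TRUE) {
  starts_ms <- c(0, cumsum(protocol$durations_s)[-3]) * 1000
  if (!extended)
    return(list(a_r = 1, a_d = 1))
  list(a_r = list(breaks = starts_ms, values = protocol$a_r),
       a_d = list(breaks = starts_ms, values = protocol$a_d))
}

#' Synthesize an atrial fibrillatory rate trend
#'
#' Stand-in for a clinically estimated AFR trend (synthetic; the package does
#' not process ECG).  Produces a trend at 0.02 s resolution that holds each
#' segment at its anchor rate with smooth cosine transitions at the position
#' changes, an optional zero-mean within-segment sinusoidal drift, and
#' seeded AR(1) noise (de-meaned per segment so segment means hit the anchors
#' exactly).  The default noise level maps, through `1000/AFR`, to an AA
#' interval standard deviation of roughly 20 ms.
#'
#' @param anchors per-segment mean AFR (Hz), supine/HDT/HUT.
#' @param durations_s segment durations (s).
#' @param resolution_s trend resolution (default 0.02 s).
#' @param noise_sd marginal sd of the AR(1) noise (Hz).
#' @param noise_tau_s correlation time of the noise (s).
#' @param drift_amp amplitude (Hz) of a one-period sinusoidal drift per
#'   segment.
#' @param transition_s width of the smooth transition at each boundary (s).
#' @param seed optional RNG seed.
#' @return An object of class `afr_trend` (data frame with `time_s`,
#'   `afr_hz`).
#' @export
synth_afr_trend <- function(anchors = c(6.78, 6.62, 6.84),
                            durations_s = c(300, 300, 300),
                            resolution_s = 0.02, noise_sd = 0.9,
                            noise_tau_s = 1, drift_amp = 0.1,
                            transition_s = 30, seed = NULL) {
  stopifnot(length(anchors) == 3, all(anchors > 0), all(durations_s > 0),
            noise_sd >= 0, drift_amp >= 0)
  total <- sum(durations_s)
  t <- seq(0, total - resolution_s, by = resolution_s)
  n <- length(t)
  bounds <- cumsum(durations_s)
  seg <- findInterval(t, c(0, bounds[1:2]), rightmost.closed = FALSE)
  base <- rep(anchors[1], n)
  h <- transition_s / 2
  for (k in 1:2) { # cosine smoothstep across each position change
    s <- pmin(pmax((t - (bounds[k] - h)) / (2 * h), 0), 1)
    base <- base + (anchors[k + 1] - anchors[k]) * (1 - cos(pi * s)) / 2
  }
  with_seed(seed, {
    noise <- numeric(n)
    if (noise_sd > 0) {
      phi <- exp(-resolution_s / noise_tau_s)
      e <- rnorm(n, 0, noise_sd * sqrt(1 - phi^2))
      e[1] <- rnorm(1, 0, noise_sd)
      noise <- as.numeric(stats::filter(e, phi, method = "recursive"))
    }
    drift <- drift_amp * sin(2 * pi * (t - c(0, bounds)[seg]) /
                               durations_s[seg])
    for (k in 1:3) { # exact segment means at the anchors
      i <- seg == k
      noise[i] <- noise[i] - mean(noise[i])
      drift[i] <- drift[i] - mean(drift[i])
    }
    afr <- base + noise + drift
    if (any(afr <= 0)) stop("synthesized AFR fell below zero; reduce noise_sd")
    structure(data.frame(time_s = t, afr_hz = afr),
              class = c("afr_trend", "data.frame"))
  })
}

#' Estimate AA distribution parameters from an AFR trend
#'
#' The AA-interval mean and standard deviation trends are the mean and sample
#' standard deviation of `1000/AFR` (ms) over a trailing sliding window
#' (default 1 min), one output sample per input sample once the window is
#' full.
#'
#' @param afr an `afr_trend` (uniformly sampled).
#' @param window_s sliding window length (s).
#' @return An `aa_param_trend` with `time_s`, `mu_ms`, `sigma_ms`.
#' @export
estimate_aa_params_from_afr <- function(afr, window_s = 60) {
  stopifnot(inherits(afr, "afr_trend"))
  dt <- diff(afr$time_s)
  if (max(abs(dt - dt[1])) > 1e-9) stop("AFR trend must be uniformly sampled")
  w <- as.integer(round(window_s / dt[1]))
  n <- nrow(afr)
  if (w > n) stop("window_s is longer than the AFR trend")
  x <- 1000 / afr$afr_hz
  x0 <- x - mean(x) # centering keeps the rolling variance numerically stable
  s1 <- data.table::frollsum(x0, w)
  s2 <- data.table::frollsum(x0^2, w)
  mu <- s1 / w + mean(x)
  sg <- sqrt(pmax((s2 - s1^2 / w) / (w - 1), 0))
  keep <- w:n
  if (any(sg[keep] <= 1e-6))
    stop("sigma(t) is zero within a window; the AA generator requires sigma > 0")
  aa_param_trend(afr$time_s[keep], mu[keep], sg[keep])
}

#' Population-averaged AA parameter trend
#'
#' Emulates the clinical trend pipeline: one synthetic AFR trend per patient
#' (population anchors shifted by a patient-level baseline offset plus small
#' position-specific jitter), per-patient estimation of `mu(t)`, `sigma(t)`
#' via [estimate_aa_params_from_afr()], then averaging across patients.
#' Averaging smooths the within-segment noise of individual trends, so the
#' segment-level contrast of the averaged `mu(t)` reflects the anchor
#' differences, as in a population-averaged clinical trend.
#'
#' @param n_patients number of synthetic patients.
#' @param seed RNG seed.
#' @param anchors per-segment mean AFR (Hz).
#' @param anchor_sd sd (Hz) of the shared patient baseline offset.
#' @param position_jitter_sd sd (Hz) of per-position anchor jitter.
#' @param durations_s segment durations (s).
#' @param window_s estimation window (s).
#' @param ... further arguments to [synth_afr_trend()].
#' @return An `aa_param_trend`.
#' @export
population_aa_trend <- function(n_patients = 24, seed = NULL,
                                anchors = c(6.78, 6.62, 6.84),
                                anchor_sd = 0.6, position_jitter_sd = 0.1,
                                durations_s = c(300, 300, 300),
                                window_s = 60, ...) {
  stopifnot(n_patients >= 1)
  with_seed(seed, {
    mu_acc <- sg_acc <- NULL
    tt <- NULL
    for (p in seq_len(n_patients)) {
      a_p <- anchors + rnorm(1, 0, anchor_sd) + rnorm(3, 0, position_jitter_sd)
      a_p <- pmax(a_p, 3) # keep the baseline physiological
      afr <- synth_afr_trend(anchors = a_p, durations_s = durations_s, ...)
      est <- estimate_aa_params_from_afr(afr, window_s = window_s)
      if (is.null(mu_acc)) {
        tt <- est$time_s
        mu_acc <- est$mu_ms
        sg_acc <- est$sigma_ms
      } else {
        mu_acc <- mu_acc + est$mu_ms
        sg_acc <- sg_acc + est$sigma_ms
      }
    }
    aa_param_trend(tt, mu_acc / n_patients, sg_acc / n_patients)
  })
}

#' Draw a stand-in tilt parameter ensemble
#'
#' Draws AV node parameter sets from Gaussians matching the fitted-ensemble
#' means and standard deviations ([tilt_ensemble_stats()]), truncated to the
#' sensitivity-analysis sampling box, and keeps only sets passing the
#' pathway-ordering criterion of [physiological_filter()].  This is a
#' synthetic stand-in for parameter sets fitted to patients.
#'
#' @param n ensemble size.
#' @param seed optional RNG seed.
#' @param max_tries draw budget before giving up.
#' @return List of `n` `model_params`.
#' @export
generate_tilt_ensemble <- function(n = 24, seed = NULL, max_tries = 400 * n) {
  st <- tilt_ensemble_stats()
  box <- parameter_space()
  lo <- setNames(box$low, box$parameter)
  hi <- setNames(box$high, box$parameter)
  with_seed(seed, {
    out <- vector("list", n)
    got <- 0L
    for (k in seq_len(max_tries)) {
      draw <- function(tab, prefix) {
        v <- rnorm(6, tab$mean, tab$sd)
        nm <- paste0(prefix, "_", tab$param)
        pmin(pmax(v, lo[nm]), hi[nm])
      }
      x <- c(setNames(draw(st$sp, "sp"), paste0("sp_", st$sp$param)),
             setNames(draw(st$fp, "fp"), paste0("fp_", st$fp$param)))
      mp <- params_from_row(x)
      if (physiological_filter(mp)$accept) {
        got <- got + 1L
        out[[got]] <- mp
        if (got == n) return(out)
      }
    }
    stop("could not draw ", n, " admissible parameter sets in ", max_tries,
         " tries")
  })
}

interp_to_grid <- function(trend, grid) {
  approx(trend$time_s, trend$value, xout = grid, rule = 1)$y
}

#' Run a tilt-test simulation experiment
#'
#' For every (parameter set, AA realization) pair: generates a Pearson Type
#' IV atrial series over the protocol duration from the time-varying
#' `(mu(t), sigma(t))` trend, simulates the network with the protocol's
#' per-segment tone scales (all 1 when `extended = FALSE`, i.e. the original
#' model), computes the sliding-window characteristic trends (mean at
#' `window_mean` beats; RMSSD and sample entropy at `window_var` beats), and
#' averages the trends across runs on a common time grid.  AA seeds depend
#' only on (set, realization), so original and extended runs with the same
#' master seed see identical atrial series.
#'
#' @param ensemble list of `model_params`.
#' @param trend an `aa_param_trend` spanning the protocol (endpoints held
#'   constant outside its range).
#' @param protocol a `tilt_protocol`.
#' @param realizations AA realizations per parameter set.
#' @param seed master seed.
#' @param extended use the protocol's tone scales (`TRUE`) or the original
#'   unscaled model (`FALSE`).
#' @param cfg a `metric_config`.
#' @param grid_dt_s common averaging grid step (s).
#' @param warmup_s pre-protocol warm-up (s) simulated at the supine state and
#'   trend boundary values before time zero.  The network starts from fully
#'   recovered nodes and needs roughly two minutes of bombardment to reach
#'   its dynamic steady state; clinically, fibrillation is ongoing long
#'   before the recording starts, so protocol time zero should see a
#'   steady-state node, not a fresh one.  Warm-up beats fill the leading
#'   trend windows but carry negative timestamps and do not enter the
#'   position averages.
#' @param keep_runs also return the per-run trends.
#' @return An object of class `tilt_result` with `averaged` (data frame
#'   `time_s`, `rr_mean_ms`, `rr_v_ms`, `rr_i`), `n_runs`, `protocol`, and
#'   optionally `runs`.
#' @export
run_tilt_experiment <- function(ensemble, trend, protocol = tilt_protocol(),
                                realizations = 3, seed = 1, extended = TRUE,
                                cfg = metric_config(), grid_dt_s = 1,
                                warmup_s = 150, keep_runs = FALSE) {
  stopifnot(length(ensemble) >= 1, realizations >= 1, warmup_s >= 0,
            inherits(protocol, "tilt_protocol"))
  if (length(ensemble) == 0L) stop("ensemble must not be empty")
  duration <- sum(protocol$durations_s)
  sched <- protocol_schedule(protocol, extended)
  if (extended && warmup_s > 0) { # warm-up runs at the supine (unit) scales
    sched$a_r$breaks <- sched$a_r$breaks + warmup_s * 1000
    sched$a_d$breaks <- sched$a_d$breaks + warmup_s * 1000
  }
  shifted <- trend
  shifted$time_s <- shifted$time_s + warmup_s # boundary values held in warm-up
  grid <- seq(0, duration, by = grid_dt_s)
  n_runs <- length(ensemble) * realizations
  acc <- list(rr_mean_ms = matrix(NA_real_, n_runs, length(grid)),
              rr_v_ms = matrix(NA_real_, n_runs, length(grid)),
              rr_i = matrix(NA_real_, n_runs, length(grid)))
  runs <- if (keep_runs) vector("list", n_runs) else NULL
  run <- 0L
  for (si in seq_along(ensemble)) {
    for (ri in seq_len(realizations)) {
      run <- run + 1L
      aa <- generate_aa_series(shifted, duration + warmup_s,
                               seed = derive_seed(seed, (si - 1L) * 1000L + ri))
      mp <- ensemble[[si]]
      mp$a_r <- sched$a_r
      mp$a_d <- sched$a_d
      v <- simulate_av(aa, mp)
      if (length(v) < cfg$window_var + 2L)
        stop("run ", run, " produced too few beats for the trend windows")
      rr <- rr_series(diff(v))
      bt <- v[-1L] / 1000 - warmup_s
      tr_m <- sliding_trend(rr, bt, "mean", cfg$window_mean)
      tr_v <- sliding_trend(rr, bt, "rmssd", cfg$window_var)
      tr_i <- sliding_trend(rr, bt, "sampen", cfg$window_var,
                            m = cfg$m, r = cfg$r)
      acc$rr_mean_ms[run, ] <- interp_to_grid(tr_m, grid)
      acc$rr_v_ms[run, ] <- interp_to_grid(tr_v, grid)
      acc$rr_i[run, ] <- interp_to_grid(tr_i, grid)
      if (keep_runs)
        runs[[run]] <- list(set = si, realization = ri,
                            mean = tr_m, rmssd = tr_v, sampen = tr_i)
    }
  }
  averaged <- data.frame(
    time_s = grid,
    rr_mean_ms = colMeans(acc$rr_mean_ms, na.rm = TRUE),
    rr_v_ms = colMeans(acc$rr_v_ms, na.rm = TRUE),
    rr_i = colMeans(acc$rr_i, na.rm = TRUE))
  structure(list(averaged = averaged, n_runs = n_runs, protocol = protocol,
                 extended = extended, seed = seed, runs = runs),
            class = "tilt_result")
}

#' Per-position characteristic means
#'
#' Mean of each population-averaged characteristic trend within each tilt
#' position's time window.
#'
#' @param result a `tilt_result` (or its `averaged` data frame).
#' @param protocol the protocol defining the segment windows.
#' @return A 3-row data frame (`position`, `rr_mean_ms`, `rr_v_ms`, `rr_i`).
#' @export
compare_positions <- function(result, protocol = tilt_protocol()) {
  av <- if (inherits(result, "tilt_result")) result$averaged else result
  bounds <- c(0, cumsum(protocol$durations_s))
  out <- lapply(1:3, function(k) {
    i <- av$time_s >= bounds[k] & av$time_s < bounds[k + 1]
    data.frame(position = protocol$labels[k],
               rr_mean_ms = mean(av$rr_mean_ms[i], na.rm = TRUE),
               rr_v_ms = mean(av$rr_v_ms[i], na.rm = TRUE),
               rr_i = mean(av$rr_i[i], na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Select parameter sets by characteristic matching
#'
#' Ranks candidate parameter sets by Euclidean distance, in standardized
#' (mean RR, RMSSD, sample entropy) space, to a target triplet, and returns
#' the closest `n_select`.  A stand-in for fitting parameter sets to observed
#' supine RR characteristics.
#'
#' @param candidates list of `model_params`.
#' @param targets numeric length-3 target `(rr_mean, rr_v, rr_i)`.
#' @param n_select number of sets to return (<= number of candidates).
#' @param characteristics optional precomputed matrix (rows = candidates,
#'   columns = the three characteristics); if `NULL`, each candidate is
#'   simulated under a stationary AA series.
#' @param mu,sigma stationary AA parameters (ms) used when simulating.
#' @param n_rr RR intervals per candidate evaluation.
#' @param seed RNG seed for the evaluation series.
#' @return The selected `model_params` list, with attributes `order` and
#'   `distances`.
#' @export
select_parameter_sets <- function(candidates, targets, n_select,
                                  characteristics = NULL, mu = 150,
                                  sigma = 20, n_rr = 500, seed = 1) {
  stopifnot(length(targets) == 3)
  if (n_select > length(candidates))
    stop("n_select exceeds the number of candidates")
  if (is.null(characteristics)) {
    aa_p <- aa_params(mu, sigma)
    n_aa <- ceiling((n_rr + 50) * 1100 / mu)
    characteristics <- t(vapply(seq_along(candidates), function(i) {
      aa <- cumsum(sample_intervals(aa_p, n_aa, seed = derive_seed(seed, i)))
      v <- simulate_av(aa, candidates[[i]])
      if (length(v) < n_rr + 1L) return(c(NA_real_, NA_real_, NA_real_))
      rr <- diff(v[seq_len(n_rr + 1L)])
      c(mean(rr), rr_rmssd(rr),
        tryCatch(rr_sample_entropy(rr), error = function(e) NA_real_))
    }, numeric(3)))
  }
  stopifnot(nrow(characteristics) == length(candidates))
  sds <- apply(characteristics, 2L, sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  z <- sweep(characteristics, 2L, sds, "/")
  zt <- targets / sds
  d <- sqrt(rowSums(sweep(z, 2L, zt, "-")^2))
  ord <- order(d)
  sel <- ord[seq_len(n_select)]
  structure(candidates[sel], order = ord, distances = d,
            characteristics = characteristics)
}
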