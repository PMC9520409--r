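#' Sampling space for the sensitivity analysis
#'
#' Per-parameter uniform bounds for the 14-dimensional input
#' \eqn{x = [\theta^{SP}, \theta^{FP}, \mu, \sigma]}: the twelve pathway
#' parameters (ms) plus the AA-interval mean and standard deviation (ms).
#' The coupling node is held fixed at [cn_default()].
#'
#' @param mu_bounds,sigma_bounds bounds (ms) for the AA interval mean and sd.
#' @return A data frame of class `parameter_space` with `parameter`, `low`,
#'   `high`.
#' @export
parameter_space <- function(mu_bounds = c(100, 250), sigma_bounds = c(15, 30)) {
  path_lo <- c(r_min = 250, delta_r = 0, tau_r = 50,
               d_min = 0, delta_d = 0, tau_d = 50)
  path_hi <- c(r_min = 600, delta_r = 600, tau_r = 300,
               d_min = 30, delta_d = 75, tau_d = 300)
  sp <- data.frame(parameter = paste0("sp_", names(path_lo)),
                   low = unname(path_lo), high = unname(path_hi))
  fp <- data.frame(parameter = paste0("fp_", names(path_lo)),
                   low = unname(path_lo), high = unname(path_hi))
  aa <- data.frame(parameter = c("mu", "sigma"),
                   low = c(mu_bounds[1], sigma_bounds[1]),
                   high = c(mu_bounds[2], sigma_bounds[2]))
  out <- rbind(sp, fp, aa)
  stopifnot(all(is.finite(out$low)), all(is.finite(out$high)),
            all(out$low < out$high))
  structure(out, class = c("parameter_space", "data.frame"))
}

#' Draw parameter sets from a sampling space
#'
#' @param space a `parameter_space`.
#' @param K number of sets, >= 1.
#' @param seed optional RNG seed.
#' @return A `K x nrow(space)` matrix with one uniform column per parameter.
#' @export
sample_parameter_sets <- function(space, K, seed = NULL) {
  stopifnot(inherits(space, "parameter_space"), K >= 1)
  with_seed(seed, {
    X <- vapply(seq_len(nrow(space)),
                function(j) runif(K, space$low[j], space$high[j]),
                numeric(K))
    if (K == 1L) X <- matrix(X, nrow = 1L)
    colnames(X) <- space$parameter
    X
  })
}

#' Model parameters from a sampled row
#'
#' @param x named numeric vector with the twelve `sp_*`/`fp_*` entries.
#' @param cn coupling-node parameters.
#' @return A `model_params` (with `a_r = a_d = 1`).
#' @export
params_from_row <- function(x, cn = cn_default()) {
  pp <- function(prefix) do.call(pathway_params, as.list(unname(
    x[paste0(prefix, c("_r_min", "_delta_r", "_tau_r",
                       "_d_min", "_delta_d", "_tau_d"))])))
  model_params(sp = pp("sp"), fp = pp("fp"), cn = cn)
}

#' Physiological selection criteria
#'
#' A parameter set is physiological iff (i) the slow pathway has a strictly
#' lower refractory period and a strictly higher conduction delay than the
#' fast pathway for every excitation gap, and (ii) the resulting mean RR lies
#' in 300--1000 ms (heart rates 60--200 bpm; slower rates would engage the
#' nodal pacemaker, which the model does not include, and faster ones exceed
#' bundle-branch refractoriness).  Criterion (i) is checked on a dense gap
#' grid over `[0, 10 max(tau)]` plus the asymptote, because exponential
#' recovery curves with different time constants can cross between endpoints.
#'
#' @param mp a `model_params`.
#' @param rr_mean mean RR (ms) of the simulated series, or `NULL` to check
#'   only criterion (i).
#' @param rr_range admissible mean RR range (ms).
#' @param grid_step gap grid step (ms).
#' @return List with `accept` (logical) and `reason` (`NA` if accepted, else
#'   one of `"refractory_ordering"`, `"delay_ordering"`,
#'   `"rr_mean_out_of_range"`).
#' @export
physiological_filter <- function(mp, rr_mean = NULL, rr_range = c(300, 1000),
                                 grid_step = 1) {
  stopifnot(inherits(mp, "model_params"))
  tau_max <- max(mp$sp$tau_r, mp$sp$tau_d, mp$fp$tau_r, mp$fp$tau_d)
  gap <- c(seq(0, 10 * tau_max, by = grid_step), Inf)
  if (!all(refractory_period(mp$sp, gap) < refractory_period(mp$fp, gap)))
    return(list(accept = FALSE, reason = "refractory_ordering"))
  if (!all(conduction_delay(mp$sp, gap) > conduction_delay(mp$fp, gap)))
    return(list(accept = FALSE, reason = "delay_ordering"))
  if (!is.null(rr_mean) &&
      (rr_mean < rr_range[1] || rr_mean > rr_range[2]))
    return(list(accept = FALSE, reason = "rr_mean_out_of_range"))
  list(accept = TRUE, reason = NA_character_)
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Maximum absolute difference between the two empirical CDFs, evaluated over
#' the pooled sample points; lies in `[0, 1]`.
#'
#' @param a,b non-empty numeric samples.
#' @return The KS distance.
#' @examples
#' ks_distance(c(1, 2), c(1, 3)) # 0.5
#' @export
ks_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  cpp_ks(as.numeric(a), as.numeric(b))
}

# D bootstrap replicates of the unconditional CDF: each column holds
# floor(K/C) points resampled with replacement from all outputs; returned
# column-sorted.
boot_cdf_matrix <- function(y, C, D) {
  n_b <- max(1L, length(y) %/% C)
  cpp_sort_cols(matrix(y[sample.int(length(y), n_b * D, replace = TRUE)],
                       nrow = n_b, ncol = D))
}

# C x D matrix of KS distances between each conditioning interval's
# conditional CDF and each bootstrap unconditional CDF (NA rows for empty
# intervals).
pawn_ks_matrix <- function(x, y, C, boots_sorted) {
  br <- seq(min(x), max(x), length.out = C + 1)
  idx <- if (br[1] == br[C + 1]) rep(1L, length(x))
         else findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  kmat <- matrix(NA_real_, nrow = C, ncol = ncol(boots_sorted))
  empty <- 0L
  for (cc in seq_len(C)) {
    yc <- y[idx == cc]
    if (length(yc) == 0L) { empty <- empty + 1L; next }
    kmat[cc, ] <- cpp_ks_vs_cols(sort(yc), boots_sorted)
  }
  if (empty > 0L)
    warning(empty, " empty conditioning interval(s) skipped")
  kmat
}

#' Distribution-based sensitivity coefficient
#'
#' PAWN-style coefficient of one input on one output: the input's observed
#' range is split into `C` equal-width conditioning intervals; for each
#' interval the KS distance between its conditional output CDF and each of
#' `D` bootstrap replicates of the unconditional CDF (each of `floor(K/C)`
#' points resampled with replacement from all outputs) is taken; the
#' coefficient is the median over intervals of the median over replicates.
#' The spread is the 2.5/97.5 percentile interval, over bootstrap replicates,
#' of the median across intervals.
#'
#' @param x_col input sample.
#' @param y_col output sample (same length).
#' @param C number of conditioning intervals.
#' @param D number of bootstrap replicates.
#' @param seed optional RNG seed for the bootstrap.
#' @return List with `s` (coefficient), `ci` (length-2 spread), and
#'   `n_per_interval`.
#' @export
sensitivity_coefficient <- function(x_col, y_col, C = 15, D = 1000,
                                    seed = NULL) {
  stopifnot(length(x_col) == length(y_col), length(y_col) >= C)
  with_seed(seed, {
    boots <- boot_cdf_matrix(y_col, C, D)
    kmat <- pawn_ks_matrix(x_col, y_col, C, boots)
    per_c <- apply(kmat, 1L, median)
    t_d <- apply(kmat, 2L, median, na.rm = TRUE)
    list(s = median(per_c, na.rm = TRUE),
         ci = unname(quantile(t_d, c(0.025, 0.975))),
         n_per_interval = as.integer(table(factor(
           findInterval(x_col, seq(min(x_col), max(x_col), length.out = C + 1),
                        rightmost.closed = TRUE, all.inside = TRUE),
           levels = seq_len(C)))))
  })
}

#' Dummy-parameter significance threshold
#'
#' Noise floor of the sensitivity coefficient: the median, over bootstrap
#' replicates d = 2..D, of the KS distance between the d-th and the first
#' bootstrap unconditional CDF.  An input is deemed influential iff its
#' coefficient exceeds this threshold; the threshold depends on the sample
#' size and is recomputed per output and per study.
#'
#' @inheritParams sensitivity_coefficient
#' @return The threshold (dimensionless, in `[0, 1]`).
#' @export
dummy_threshold <- function(y_col, C = 15, D = 1000, seed = NULL) {
  stopifnot(D >= 2)
  with_seed(seed, {
    boots <- boot_cdf_matrix(y_col, C, D)
    median(cpp_ks_vs_cols(boots[, 1L], boots[, -1L, drop = FALSE]))
  })
}

#' Run the full distribution-based sensitivity study
#'
#' Draws `K` parameter sets, applies the physiological pre-filter, simulates
#' each admissible set with a stationary Pearson Type IV atrial series of
#' `n_aa` intervals, computes the three characteristics (mean, RMSSD, sample
#' entropy) on the first `n_rr` RR intervals, applies the mean-RR filter, and
#' evaluates the sensitivity coefficient and dummy threshold for every
#' (parameter, characteristic) cell.
#'
#' @param space a `parameter_space`.
#' @param K number of sampled parameter sets (desk-scale default 5000).
#' @param n_aa atrial impulses per simulation.
#' @param n_rr RR intervals used for the characteristics; sets whose series
#'   yields fewer RR intervals are excluded (reason `"insufficient_rr"`).
#' @param C,D conditioning intervals and bootstrap replicates.
#' @param seed master seed; per-simulation seeds are derived by a counter
#'   scheme.
#' @param min_accepted abort if fewer sets pass all criteria.
#' @param m,r sample-entropy settings.
#' @return An object of class `sensitivity_result`: `coefficients` (one row
#'   per parameter with `s_*`, `ci_*`, `influential_*` per characteristic),
#'   `dummy` (per-characteristic thresholds), `dataset` (accepted `X`, `Y`),
#'   and `log` (rejection counts and acceptance rate).
#' @export
run_sensitivity_study <- function(space = parameter_space(), K = 5000,
                                  n_aa = 60000, n_rr = 4000, C = 15, D = 1000,
                                  seed = 1, min_accepted = 50, m = 2, r = 0.2) {
  stopifnot(K >= 1, n_aa >= n_rr + 1)
  X <- sample_parameter_sets(space, K, seed = derive_seed(seed, 0))
  reasons <- character(K)
  Y <- matrix(NA_real_, nrow = K, ncol = 3,
              dimnames = list(NULL, c("rr_mean", "rr_v", "rr_i")))
  for (i in seq_len(K)) {
    mp <- params_from_row(X[i, ])
    chk <- physiological_filter(mp)
    if (!chk$accept) { reasons[i] <- chk$reason; next }
    aa_p <- aa_params(X[i, "mu"], X[i, "sigma"])
    aa <- cumsum(sample_intervals(aa_p, n_aa, seed = derive_seed(seed, i)))
    v <- simulate_av(aa, mp)
    if (length(v) < n_rr + 1L) { reasons[i] <- "insufficient_rr"; next }
    rr <- diff(v[seq_len(n_rr + 1L)])
    chk <- physiological_filter(mp, rr_mean = mean(rr))
    if (!chk$accept) { reasons[i] <- chk$reason; next }
    rri <- tryCatch(rr_sample_entropy(rr, m = m, r = r),
                    error = function(e) NA_real_)
    if (!is.finite(rri)) { reasons[i] <- "sampen_undefined"; next }
    Y[i, ] <- c(mean(rr), rr_rmssd(rr), rri)
  }
  acc <- which(reasons == "" & is.finite(Y[, 1L]))
  if (length(acc) < min_accepted)
    stop("only ", length(acc), " of ", K, " parameter sets accepted ",
         "(minimum ", min_accepted, "); rejection reasons: ",
         paste(names(table(reasons[reasons != ""])),
               table(reasons[reasons != ""]), collapse = ", "))
  Xa <- X[acc, , drop = FALSE]
  Ya <- Y[acc, , drop = FALSE]
  P <- ncol(Xa)
  S <- matrix(NA_real_, P, 3, dimnames = list(colnames(Xa), colnames(Ya)))
  ci_lo <- ci_hi <- S
  dummy <- setNames(numeric(3), colnames(Ya))
  for (mm in 1:3) {
    set.seed(as.integer(derive_seed(seed, 1e6 + mm)))
    boots <- boot_cdf_matrix(Ya[, mm], C, D)
    dummy[mm] <- median(cpp_ks_vs_cols(boots[, 1L], boots[, -1L, drop = FALSE]))
    for (j in seq_len(P)) {
      kmat <- pawn_ks_matrix(Xa[, j], Ya[, mm], C, boots)
      S[j, mm] <- median(apply(kmat, 1L, median), na.rm = TRUE)
      t_d <- apply(kmat, 2L, median, na.rm = TRUE)
      ci_lo[j, mm] <- quantile(t_d, 0.025)
      ci_hi[j, mm] <- quantile(t_d, 0.975)
    }
  }
  coefficients <- data.frame(
    parameter = colnames(Xa),
    s_mean = S[, 1], s_rmssd = S[, 2], s_sampen = S[, 3],
    ci_lo_mean = ci_lo[, 1], ci_hi_mean = ci_hi[, 1],
    ci_lo_rmssd = ci_lo[, 2], ci_hi_rmssd = ci_hi[, 2],
    ci_lo_sampen = ci_lo[, 3], ci_hi_sampen = ci_hi[, 3],
    influential_mean = S[, 1] > dummy[1],
    influential_rmssd = S[, 2] > dummy[2],
    influential_sampen = S[, 3] > dummy[3],
    row.names = NULL)
  tab <- table(reasons[reasons != ""])
  structure(list(
    coefficients = coefficients,
    dummy = c(dummy_mean = unname(dummy[1]), dummy_rmssd = unname(dummy[2]),
              dummy_sampen = unname(dummy[3])),
    dataset = list(X = Xa, Y = Ya),
    log = list(K = K, accepted = length(acc),
               acceptance_rate = length(acc) / K,
               rejections = as.list(tab), seed = seed)),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Distribution-based sensitivity study: %d/%d sets accepted (%.1f%%)\n",
              x$log$accepted, x$log$K, 100 * x$log$acceptance_rate))
  cat(sprintf("Dummy thresholds: mean %.4f, rmssd %.4f, sampen %.4f\n",
              x$dummy[1], x$dummy[2], x$dummy[3]))
  df <- x$coefficients[order(-x$coefficients$s_mean),
                       c("parameter", "s_mean", "s_rmssd", "s_sampen")]
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}
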