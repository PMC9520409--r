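#' Pathway parameters
#'
#' The six parameters governing one pathway's recovery dynamics: the
#' refractory period after conducting with excitation gap \eqn{\Delta t} is
#' \eqn{R(\Delta t) = R_{min} + \Delta R (1 - e^{-\Delta t/\tau_R})} and the
#' conduction delay is
#' \eqn{D(\Delta t) = D_{min} + \Delta D\, e^{-\Delta t/\tau_D}}.
#' All values are in milliseconds.
#'
#' @param r_min minimum refractory period (ms), > 0.
#' @param delta_r maximal refractory prolongation (ms), >= 0.
#' @param tau_r refractory recovery time constant (ms), > 0.
#' @param d_min minimum conduction delay (ms), >= 0.
#' @param delta_d maximal delay prolongation (ms), >= 0.
#' @param tau_d delay recovery time constant (ms), > 0.
#' @return An object of class `pathway_params`.
#' @examples
#' pathway_params(300, 300, 100, 20, 39, 171)
#' @export
pathway_params <- function(r_min, delta_r, tau_r, d_min, delta_d, tau_d) {
  p <- list(r_min = r_min, delta_r = delta_r, tau_r = tau_r,
            d_min = d_min, delta_d = delta_d, tau_d = tau_d)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("pathway parameter '", nm, "' must be a finite scalar")
  }
  if (p$r_min <= 0) stop("r_min must be > 0")
  if (p$delta_r < 0) stop("delta_r must be >= 0")
  if (p$tau_r <= 0) stop("tau_r must be > 0")
  if (p$d_min < 0) stop("d_min must be >= 0")
  if (p$delta_d < 0) stop("delta_d must be >= 0")
  if (p$tau_d <= 0) stop("tau_d must be > 0")
  structure(p, class = "pathway_params")
}

#' Coupling-node default parameters
#'
#' The coupling node merges the two pathway wavefronts into a single
#' ventricular activation.  Its refractory period is fixed at 250 ms (the
#' lower bound of the pathway \eqn{R_{min}} sampling range) and its delay at
#' 0 ms; the time constants are inert when the Delta terms are zero but are
#' retained for interface uniformity.
#'
#' @return A `pathway_params` object.
#' @export
cn_default <- function() {
  pathway_params(r_min = 250, delta_r = 0, tau_r = 1,
                 d_min = 0, delta_d = 0, tau_d = 1)
}

#' Full model parameterization
#'
#' Bundles the slow-pathway, fast-pathway and coupling-node parameter vectors
#' with the autonomic-tone scales.  `a_r = a_d = 1` reproduces the unscaled
#' model exactly.
#'
#' @param sp,fp,cn `pathway_params` for the slow pathway, fast pathway and
#'   coupling node.
#' @param a_r,a_d dimensionless autonomic-tone scales on refractory period and
#'   conduction delay, > 0; shared by all three pathways.
#' @return An object of class `model_params`.
#' @export
model_params <- function(sp, fp, cn = cn_default(), a_r = 1, a_d = 1) {
  stopifnot(inherits(sp, "pathway_params"), inherits(fp, "pathway_params"),
            inherits(cn, "pathway_params"))
  if (!is.numeric(a_r) || length(a_r) != 1L || a_r <= 0) stop("a_r must be > 0")
  if (!is.numeric(a_d) || length(a_d) != 1L || a_d <= 0) stop("a_d must be > 0")
  structure(list(sp = sp, fp = fp, cn = cn, a_r = a_r, a_d = a_d),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  fmt <- function(p) sprintf(
    "Rmin=%g dR=%g tauR=%g Dmin=%g dD=%g tauD=%g", p$r_min, p$delta_r,
    p$tau_r, p$d_min, p$delta_d, p$tau_d)
  cat("AV node model parameters (ms):\n")
  cat("  SP:", fmt(x$sp), "\n  FP:", fmt(x$fp), "\n  CN:", fmt(x$cn), "\n")
  cat(sprintf("  scales: a_r=%g a_d=%g\n", x$a_r, x$a_d))
  invisible(x)
}

#' Recovery-dependent refractory period
#'
#' \eqn{A_R \cdot (R_{min} + \Delta R (1 - e^{-\Delta t/\tau_R}))}, where
#' \eqn{\Delta t} is the excitation gap at the preceding conduction.  A gap of
#' `Inf` means "fully recovered" (a node that has never conducted) and yields
#' the asymptote \eqn{A_R (R_{min} + \Delta R)}.
#'
#' @param p a `pathway_params`.
#' @param gap excitation gap in ms (vectorized); `Inf` = fully recovered.
#'   Gaps stem from conducted impulses and must be positive.
#' @param a_r autonomic-tone scale, > 0.
#' @return Refractory period(s) in ms.
#' @export
refractory_period <- function(p, gap, a_r = 1) {
  stopifnot(inherits(p, "pathway_params"), a_r > 0)
  if (any(gap < 0, na.rm = TRUE)) stop("excitation gap must be positive")
  a_r * (p$r_min + p$delta_r * (1 - exp(-gap / p$tau_r)))
}

#' Recovery-dependent conduction delay
#'
#' \eqn{A_D \cdot (D_{min} + \Delta D\, e^{-\Delta t/\tau_D})}; `Inf` (fully
#' recovered) yields \eqn{A_D D_{min}}.
#'
#' @inheritParams refractory_period
#' @param a_d autonomic-tone scale, > 0.
#' @return Conduction delay(s) in ms.
#' @export
conduction_delay <- function(p, gap, a_d = 1) {
  stopifnot(inherits(p, "pathway_params"), a_d > 0)
  if (any(gap < 0, na.rm = TRUE)) stop("excitation gap must be positive")
  a_d * (p$d_min + p$delta_d * exp(-gap / p$tau_d))
}

#' Ensemble parameter statistics for tilt simulations
#'
#' Means and standard deviations (ms) of the pathway parameters across the
#' fitted ensemble used for tilt illustration; the coupling node is fixed.
#' Used by [generate_tilt_ensemble()] to draw stand-in parameter sets.
#'
#' @return A list with `sp` and `fp` data frames (`mean`, `sd` per parameter).
#' @export
tilt_ensemble_stats <- function() {
  nms <- c("r_min", "delta_r", "tau_r", "d_min", "delta_d", "tau_d")
  list(
    sp = data.frame(param = nms, mean = c(339, 232, 160, 20, 39, 171),
                    sd = c(77, 112, 77, 7, 20, 71)),
    fp = data.frame(param = nms, mean = c(493, 369, 162, 7, 23, 163),
                    sd = c(82, 161, 72, 6, 16, 70))
  )
}
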