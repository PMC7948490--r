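# Actin-activated steady-state ATPase analysis and duty ratios.

#' Simulate an actin-activated ATPase curve
#'
#' Evaluates the steady-state ATPase flux of the cycle over a grid of
#' actin concentrations at fixed ATP. The scheme has no actin-free
#' turnover path (there is no M + ATP binding step), so the flux at zero
#' actin is exactly zero; basal activity is handled as an additive offset
#' at the fitting stage only.
#'
#' @param rates a \code{\link{rate_constant_set}}.
#' @param atp_uM clamped ATP concentration (uM).
#' @param actin_grid actin concentrations (uM), non-negative.
#' @return data.frame with \code{actin_uM} and \code{rate_per_s}.
#' @export
simulate_atpase_curve <- function(rates, atp_uM, actin_grid) {
  stopifnot(all(actin_grid >= 0))
  flux <- vapply(actin_grid, function(a) {
    if (a == 0) return(0)
    steady_state_flux(rates, ligand_conditions(atp_uM = atp_uM,
                                               actin_uM = a))
  }, numeric(1))
  data.frame(actin_uM = actin_grid, rate_per_s = flux)
}

#' Michaelis-Menten fit of an ATPase curve
#'
#' Fits \eqn{v = k_{basal} + k_{cat} [A] / (K_{app} + [A])}. The plateau
#' estimates \eqn{k_{cat}}, the half-saturation \eqn{K_{app.actin}}, and
#' the initial slope the apparent second-order actin constant
#' \eqn{k_{cat}/K_{app.actin}}.
#'
#' @param points data.frame/list with \code{actin_uM} and
#'   \code{rate_per_s} (at least 5 points).
#' @param with_basal_offset fit an additive basal rate (default TRUE when
#'   the zero-actin rate is non-zero).
#' @return Object of class \code{mm_fit}: \code{k_basal}, \code{k_cat},
#'   \code{K_app_actin}, \code{coupling_efficiency}
#'   (\eqn{k_{cat}/K_{app}}), \code{flags}.
#' @export
fit_michaelis_menten <- function(points, with_basal_offset = NULL) {
  x <- points$actin_uM
  y <- points$rate_per_s
  if (length(x) < 5) stop("need at least 5 (actin, rate) points")
  if (is.null(with_basal_offset)) {
    with_basal_offset <- any(x == 0 & y > 0)
  }
  flags <- character()
  if (all(abs(y) < 1e-15)) {
    return(structure(list(k_basal = 0, k_cat = 0, K_app_actin = NA_real_,
                          coupling_efficiency = NA_real_,
                          flags = "all_zero"), class = "mm_fit"))
  }
  ymax <- max(y)
  xh <- x[which.min(abs(y - ymax / 2))]
  fit <- if (with_basal_offset) {
    minpack.lm::nlsLM(y ~ k0 + kcat * x / (K + x),
                      start = list(k0 = min(y), kcat = ymax,
                                   K = max(xh, 1e-3)),
                      lower = c(0, 0, 0))
  } else {
    minpack.lm::nlsLM(y ~ kcat * x / (K + x),
                      start = list(kcat = ymax, K = max(xh, 1e-3)),
                      lower = c(0, 0))
  }
  co <- as.list(coef(fit))
  if (co$K > 2 * max(x)) flags <- c(flags, "no_curvature")
  structure(list(
    k_basal = if (with_basal_offset) co$k0 else 0,
    k_cat = co$kcat,
    K_app_actin = co$K,
    coupling_efficiency = co$kcat / co$K,
    flags = flags
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(paste0("Michaelis-Menten fit: k_cat %.4g /s, K_app.actin ",
                     "%.4g uM, k_cat/K_app %.4g /uM/s, k_basal %.4g /s\n"),
              x$k_cat, x$K_app_actin, x$coupling_efficiency, x$k_basal))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Duty ratio from the gating rate constants
#'
#' Phosphate release (\eqn{k_{+4}}) gates entry into the strongly bound
#' states and ADP release (\eqn{k_{+5}}) gates exit, so the fraction of
#' the cycle spent strongly bound is approximately
#' \eqn{k_{+4}/(k_{+4} + k_{+5})}.
#'
#' @param k_plus4 phosphate release rate (s^-1), > 0.
#' @param k_plus5 ADP release rate (s^-1), >= 0.
#' @return Duty ratio in (0, 1].
#' @export
duty_ratio <- function(k_plus4, k_plus5) {
  stopifnot(k_plus4 > 0, k_plus5 >= 0)
  k_plus4 / (k_plus4 + k_plus5)
}

#' Occupancy-based duty ratio
#'
#' Fraction of steady-state occupancy in the strongly actin-bound states
#' (AM'D, AM, AM' and the post-Pi-release entry state AM'DPi is excluded;
#' strong binding begins after phosphate release). Provided as an
#' alternative to the two-rate formula, whose printed values are not
#' mutually consistent for the truncated constructs.
#'
#' @inheritParams steady_state_occupancy
#' @param strong character vector of strongly bound species.
#' @return Fraction in [0, 1].
#' @export
duty_ratio_occupancy <- function(rates, ligands,
                                 strong = c("AMpD", "AM", "AMp")) {
  occ <- steady_state_occupancy(rates, ligands)
  sum(occ[strong])
}
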