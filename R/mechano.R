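# Frictional-loading mechanics: resistive force generated by
# surface-attached alpha-actinin, Bell-type force-velocity relation of the
# motor ensemble, logistic velocity-decay fits, and force-power curves.

#' Frictional-loading model parameters
#'
#' Parameters of the resistive-force relation for gliding filaments over
#' a lawn of surface-attached alpha-actinin crosslinkers. Only the elastic
#' stiffness range (0.2-0.5 pN/nm) and the maximum interaction distance
#' (61 nm) are experimentally anchored; the surface-concentration
#' constants set the absolute force calibration and default to values
#' that place the single-motor stall near 5 pN for a 120-motor filament
#' (see the methods vignette).
#'
#' @param kappa elastic stiffness of the acto-myosin linkage (pN/nm),
#'   typically 0.2-0.5.
#' @param kA_fric second-order rate of acto-alpha-actinin attachment
#'   (\eqn{\mu M^{-1} s^{-1}}).
#' @param kD_fric acto-alpha-actinin detachment rate (s^-1).
#' @param L mean actin filament length (nm).
#' @param r maximum distance for strong interaction between a
#'   surface-attached alpha-actinin and the filament (nm).
#' @param zeta,chi surface-concentration constants of the crosslinker
#'   lawn (dimensionless calibration factors).
#' @param v filament sliding velocity (nm/s).
#' @return Object of class \code{friction_params}.
#' @export
friction_params <- function(kappa = 0.35, kA_fric = 10, kD_fric = 10,
                            L = 1000, r = 61, zeta = 40, chi = 1.1,
                            v = 52) {
  x <- list(kappa = kappa, kA_fric = kA_fric, kD_fric = kD_fric,
            L = L, r = r, zeta = zeta, chi = chi, v = v)
  bad <- vapply(x, function(p) !is.numeric(p) || length(p) != 1 ||
                  is.na(p) || p <= 0, logical(1))
  if (any(bad)) stop("friction parameters must be positive scalars; ",
                     "offending: ", paste(names(x)[bad], collapse = ", "))
  structure(x, class = "friction_params")
}

#' Resistive force from surface-attached alpha-actinin
#'
#' Stall-force relation
#' \deqn{F = (\kappa/k_D)\, v\, \zeta L r\,
#'   \frac{k_A \chi [\alpha]^{5/2}}{k_A \chi [\alpha]^{3/2} + k_D}}
#' per filament. The low-concentration limit grows as
#' \eqn{[\alpha]^{5/2}}, the high-concentration limit linearly in
#' \eqn{[\alpha]}; the force is proportional to the sliding velocity (a
#' protein-friction load), the linkage stiffness, the filament length and
#' the interaction reach.
#'
#' @param alpha_uM alpha-actinin concentration(s) in uM, >= 0
#'   (vectorised).
#' @param params a \code{\link{friction_params}}; \code{params$v} is the
#'   filament velocity used.
#' @return Force in pN per filament.
#' @export
friction_force <- function(alpha_uM, params) {
  stopifnot(inherits(params, "friction_params"))
  if (any(alpha_uM < 0)) stop("alpha-actinin concentration must be >= 0")
  with(unclass(params), {
    kappa / kD_fric * v * zeta * L * r *
      (kA_fric * chi * alpha_uM^2.5) /
      (kA_fric * chi * alpha_uM^1.5 + kD_fric)
  })
}

#' Bell-type detachment parameters of the motor
#'
#' @param w working-stroke displacement (nm).
#' @param k_i force-independent detachment rate (s^-1).
#' @param k_f0 force-dependent detachment rate at zero load (s^-1).
#' @param d distance parameter of the force-dependent transition (nm).
#' @param kBT thermal energy (pN nm); default 4.28 at 37 C, the motility
#'   assay temperature.
#' @return Object of class \code{bell_params}.
#' @export
bell_params <- function(w, k_i, k_f0, d = 5, kBT = 4.28) {
  x <- list(w = w, k_i = k_i, k_f0 = k_f0, d = d, kBT = kBT)
  bad <- vapply(x, function(p) !is.numeric(p) || length(p) != 1 ||
                  is.na(p) || p <= 0, logical(1))
  if (any(bad)) stop("Bell parameters must be positive scalars; ",
                     "offending: ", paste(names(x)[bad], collapse = ", "))
  structure(x, class = "bell_params")
}

#' Packaged Bell-parameter presets for the truncated isoform constructs
#'
#' Frictional-load fit values at 37 C: working stroke 7.8 nm (no
#' N-terminal extension) or 3.7 nm (35-residue extension),
#' force-independent rates 8.0 / 3.7 s^-1, zero-load force-dependent
#' rates 70.3 / 68.2 s^-1. The distance parameter is not experimentally
#' determined for these constructs and defaults to 5 nm.
#'
#' @param isoform \code{"myo1c0"} or \code{"myo1c35"}.
#' @param d distance parameter (nm).
#' @return A \code{\link{bell_params}}.
#' @export
myo1c_bell <- function(isoform = c("myo1c0", "myo1c35"), d = 5) {
  isoform <- match.arg(isoform)
  if (isoform == "myo1c0") {
    bell_params(w = 7.8, k_i = 8.0, k_f0 = 70.3, d = d)
  } else {
    bell_params(w = 3.7, k_i = 3.7, k_f0 = 68.2, d = d)
  }
}

#' Force-velocity relation of the two-step detachment model
#'
#' Detachment is the sequence of a force-independent transition
#' (\eqn{k_i}) and a Bell-type force-dependent transition
#' (\eqn{k_f(F) = k_{f0} e^{-F d / k_B T}}); sliding velocity is the
#' detachment-limited rate times the working stroke:
#' \deqn{v(F) = \frac{w}{1/k_i + e^{F d/(k_B T)}/k_{f0}}}
#' Strictly decreasing in F, with unloaded velocity
#' \eqn{w/(1/k_i + 1/k_{f0})}.
#'
#' @param F resistive force per motor (pN), >= 0 (vectorised).
#' @param p a \code{\link{bell_params}}.
#' @return Velocity in nm/s.
#' @export
velocity_vs_force <- function(F, p) {
  stopifnot(inherits(p, "bell_params"))
  if (any(F < 0)) stop("force must be >= 0")
  p$w / (1 / p$k_i + exp(F * p$d / p$kBT) / p$k_f0)
}

#' Fit the two-step detachment model to force-velocity data
#'
#' Recovers \eqn{(k_i, k_{f0}, d)} with the working stroke fixed (the
#' stroke cannot be separated from the absolute rate scale in ensemble
#' gliding data, so it is supplied from structural/kinetic evidence).
#'
#' @param points data.frame/list with \code{F} (pN) and \code{v} (nm/s),
#'   at least 6 points spanning low and high force.
#' @param w fixed working stroke (nm).
#' @param kBT thermal energy (pN nm).
#' @param d optional fixed distance parameter; when NULL (default) it is
#'   fitted.
#' @return A \code{\link{bell_params}} with attributes \code{"flags"}
#'   (contains \code{"narrow_force_range"} when the data cannot separate
#'   the two rates) and \code{"rss"}.
#' @export
fit_force_velocity <- function(points, w, kBT = 4.28, d = NULL) {
  F <- points$F
  v <- points$v
  if (length(F) < 6) stop("need at least 6 (F, v) points")
  flags <- character()
  if (diff(range(F)) < 0.5 * kBT / (if (is.null(d)) 5 else d)) {
    flags <- c(flags, "narrow_force_range")
  }
  v0 <- max(v)
  k_tot <- v0 / w  # 1/(1/ki + 1/kf0)
  if (is.null(d)) {
    fit <- minpack.lm::nlsLM(
      v ~ w / (1 / k_i + exp(F * dd / kBT) / k_f0),
      start = list(k_i = 1.5 * k_tot, k_f0 = 10 * k_tot, dd = 5),
      lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- as.list(coef(fit))
    out <- bell_params(w = w, k_i = co$k_i, k_f0 = co$k_f0, d = co$dd,
                       kBT = kBT)
  } else {
    dd <- d
    fit <- minpack.lm::nlsLM(
      v ~ w / (1 / k_i + exp(F * dd / kBT) / k_f0),
      start = list(k_i = 1.5 * k_tot, k_f0 = 10 * k_tot),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- as.list(coef(fit))
    out <- bell_params(w = w, k_i = co$k_i, k_f0 = co$k_f0, d = dd,
                       kBT = kBT)
  }
  # anti-correlation diagnostic: at low force only the harmonic sum of the
  # two rates is determined
  if (max(F) * out$d / kBT < 0.5) {
    flags <- c(flags, "rates_anticorrelated")
  }
  attr(out, "flags") <- flags
  attr(out, "rss") <- sum(residuals(fit)^2)
  out
}

#' Four-parameter logistic fit of velocity against crosslinker load
#'
#' Fits \eqn{y = A_2 + (A_1 - A_2)/(1 + e^{(x - x_0)/dx})}: velocity
#' decays from the unloaded plateau \eqn{A_1} to \eqn{A_2} with midpoint
#' \eqn{x_0} and steepness \eqn{dx}. By symmetry of the form,
#' \eqn{y(x_0) = (A_1 + A_2)/2}.
#'
#' @param points data.frame/list with \code{x} (crosslinker
#'   concentration) and \code{v} (velocity), at least 5 points.
#' @return List of class \code{logistic_fit} with \code{A1}, \code{A2},
#'   \code{x0}, \code{dx}.
#' @export
fit_logistic_velocity <- function(points) {
  x <- points$x
  v <- points$v
  if (length(x) < 5) stop("need at least 5 (x, v) points")
  x0_start <- x[which.min(abs(v - mean(range(v))))]
  fit <- minpack.lm::nlsLM(
    v ~ A2 + (A1 - A2) / (1 + exp((x - x0) / dx)),
    start = list(A1 = max(v), A2 = min(v),
                 x0 = max(x0_start, 1e-9),
                 dx = max(diff(range(x)) / 5, 1e-9)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  structure(as.list(coef(fit)), class = "logistic_fit")
}

#' Force-power curve of the motor
#'
#' Power output against resistive force,
#' \eqn{P(F) = F \cdot v(F) / n_{motors}}, in attowatts (1 pN nm/s =
#' 0.001 aW). The division by the ensemble size converts filament-level
#' power to a per-motor scale when \code{F} and \code{v} describe a
#' multi-motor filament. The curve is bell-shaped: zero at zero force
#' (no work against no load) and zero at stall, with a single interior
#' maximum located by golden-section refinement of the dense-grid argmax.
#'
#' @param p a \code{\link{bell_params}}.
#' @param F_grid force grid (pN), at least 200 points recommended.
#' @param n_motors ensemble size for per-motor conversion (default 1).
#' @return Object of class \code{power_curve}: data.frame-like list with
#'   \code{F_pN}, \code{v_nm_s}, \code{P_aW}, and scalars \code{F_Pmax},
#'   \code{P_max}, \code{n_motors}.
#' @export
power_curve <- function(p, F_grid = seq(0, 10, length.out = 500),
                        n_motors = 1) {
  stopifnot(inherits(p, "bell_params"), n_motors >= 1)
  if (length(F_grid) < 10) stop("F_grid too coarse to localise the maximum")
  F_grid <- sort(F_grid)
  v <- velocity_vs_force(F_grid, p)
  P <- F_grid * v * 1e-3 / n_motors
  i <- which.max(P)
  lo <- F_grid[max(i - 1, 1)]
  hi <- F_grid[min(i + 1, length(F_grid))]
  opt <- optimize(function(f) f * velocity_vs_force(f, p) * 1e-3 / n_motors,
                  interval = c(lo, hi), maximum = TRUE)
  structure(list(F_pN = F_grid, v_nm_s = v, P_aW = P,
                 F_Pmax = opt$maximum, P_max = opt$objective,
                 n_motors = n_motors, params = p),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Force-power curve (n = %d motors): P_max = %.4g aW at F = %.4g pN\n",
              x$n_motors, x$P_max, x$F_Pmax))
  invisible(x)
}

#' Number of motors interacting per filament
#'
#' @param ensemble_stall_force_pN stall force of the filament ensemble.
#' @param single_motor_stall_pN stall force of one motor.
#' @return Integer count (nearest whole motor).
#' @export
motors_per_filament <- function(ensemble_stall_force_pN,
                                single_motor_stall_pN) {
  stopifnot(ensemble_stall_force_pN >= 0, single_motor_stall_pN > 0)
  round(ensemble_stall_force_pN / single_motor_stall_pN)
}
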