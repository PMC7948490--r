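# Stopped-flow transients: forward simulation on the cycle, exponential
# fitting, and the secondary-plot analyses that yield elementary constants.

.transient_kinds <- c("atp_dissociation", "adp_inhibition", "actin_binding",
                      "actin_chase", "pi_release", "trp_hydrolysis")

# Pyrene fluorescence is quenched in strongly actin-bound states. The
# default bright set is all detached species plus AM'T: after the
# ATP-driven isomerization AMT -> AM'T the head is only weakly attached and
# the pyrene signal is already unquenched, which is what makes the observed
# fast-phase plateau equal k_+2 rather than the slower AM'T -> M'T + A
# dissociation rate.
.default_bright <- list(
  pyrene = c("AMpT", "MpT", "MpDPi", "M")
)

#' Construct a stopped-flow transient
#'
#' @param t time points in seconds, strictly increasing, \code{t[1] >= 0};
#'   at least 10 points.
#' @param signal signal values (arbitrary units), same length as \code{t}.
#' @param experiment_kind one of \code{"atp_dissociation"},
#'   \code{"adp_inhibition"}, \code{"actin_binding"}, \code{"actin_chase"},
#'   \code{"pi_release"}, \code{"trp_hydrolysis"}.
#' @param conditions a \code{\link{ligand_conditions}}.
#' @param signal_convention character vector of species counted as bright,
#'   or a label such as \code{"pyrene"}.
#' @param meta optional list of extra metadata (e.g. ground truth).
#' @return Object of class \code{transient}.
#' @export
transient <- function(t, signal, experiment_kind,
                      conditions = ligand_conditions(),
                      signal_convention = "pyrene", meta = list()) {
  experiment_kind <- match.arg(experiment_kind, .transient_kinds)
  if (length(t) != length(signal) || length(t) < 10) {
    stop("need matched t/signal vectors with at least 10 points")
  }
  if (t[1] < 0 || any(diff(t) <= 0)) {
    stop("t must be strictly increasing with t[1] >= 0")
  }
  structure(list(t = as.numeric(t), signal = as.numeric(signal),
                 experiment_kind = experiment_kind, conditions = conditions,
                 signal_convention = signal_convention, meta = meta),
            class = "transient")
}

#' @export
print.transient <- function(x, ...) {
  cat(sprintf("Stopped-flow transient [%s]: %d points, t = %g..%g s\n",
              x$experiment_kind, length(x$t), x$t[1], max(x$t)))
  print(x$conditions)
  invisible(x)
}

# Initial state for each experiment kind. atp_dissociation and
# adp_inhibition start from the nucleotide-free AM/AM' equilibrium set by
# K_alpha (with ADP pre-equilibrated across AM/AM'/AM'D for the inhibition
# experiment); actin_binding starts from detached myosin; pi_release starts
# from the post-hydrolysis detached state (the ATP pre-mix is assumed
# complete); trp_hydrolysis follows the approach of detached M'T to the
# hydrolysis products.
.initial_state <- function(kind, rates, conditions) {
  # equilibrium weights proportional to the opposing rate constants;
  # a fully frozen isomerization (both rates zero) starts in the open state
  w_open <- rates$kalpha_plus
  w_closed <- rates$kalpha_minus
  if (w_open == 0 && w_closed == 0) {
    w_open <- 1
  }
  switch(kind,
    atp_dissociation = state_vector(AM = w_open, AMp = w_closed),
    adp_inhibition = {
      # AMpD/AM = [ADP]/K_5 with K_5 = k5_plus/k5_minus
      d <- conditions$adp_uM
      state_vector(AM = w_open * rates$k5_plus,
                   AMp = w_closed * rates$k5_plus,
                   AMpD = w_open * d * rates$k5_minus)
    },
    actin_binding = state_vector(M = 1),
    actin_chase = state_vector(AM = 1),
    pi_release = state_vector(MpDPi = 1),
    trp_hydrolysis = state_vector(MpT = 1)
  )
}

#' Simulate a stopped-flow experiment on the cycle
#'
#' Builds the initial condition implied by the experiment kind, integrates
#' the clamped-ligand cycle, and reports the summed occupancy of the bright
#' states as the signal. The actin-chase experiment is modelled as
#' irreversible dissociation of the open rigor complex (excess unlabelled
#' actin suppresses rebinding of the labelled filament, and the closed
#' state is treated as silent on the chase timescale, so the observed rate
#' is the actin off-rate itself). The phosphate-release experiment reports
#' cumulative released phosphate, mimicking a phosphate-sensor signal.
#'
#' @param kind experiment kind, see \code{\link{transient}}.
#' @param rates a \code{\link{rate_constant_set}}.
#' @param conditions a \code{\link{ligand_conditions}} describing the
#'   post-mix solution.
#' @param t_grid strictly increasing times (s).
#' @param signal_convention species counted as bright, or \code{"pyrene"}.
#' @param method integration method passed to \code{\link{integrate_cycle}}.
#' @return A \code{\link{transient}} with the simulated signal.
#' @export
simulate_stopped_flow <- function(kind, rates, conditions, t_grid,
                                  signal_convention = "pyrene",
                                  method = c("eigen", "lsoda")) {
  kind <- match.arg(kind, .transient_kinds)
  method <- match.arg(method)
  if (kind == "atp_dissociation" && conditions$atp_uM <= 0) {
    stop("atp_dissociation requires atp_uM > 0")
  }
  if (kind == "actin_binding" && conditions$actin_uM <= 0) {
    stop("actin_binding requires actin_uM > 0")
  }
  if (kind == "actin_chase" && conditions$actin_uM > 0) {
    stop("actin_chase assumes excess unlabelled actin: set actin_uM = 0 ",
         "(no rebinding of the labelled filament)")
  }
  bright <- if (is.character(signal_convention) &&
                length(signal_convention) == 1 &&
                signal_convention %in% names(.default_bright)) {
    .default_bright[[signal_convention]]
  } else {
    signal_convention
  }
  if (!all(bright %in% cycle_species)) {
    stop("unknown species in signal_convention: ",
         paste(setdiff(bright, cycle_species), collapse = ", "))
  }
  sim_rates <- rates
  if (kind == "actin_chase") {
    # freeze the nucleotide-free isomerization: the chase reports the
    # off-rate of the (rapidly equilibrating) rigor complex directly
    sim_rates <- update_rates(rates, kalpha_plus = 0, kalpha_minus = 0)
  }
  y0 <- .initial_state(kind, rates, conditions)
  if (kind == "pi_release") {
    sig <- .simulate_pi_release(sim_rates, conditions, y0, t_grid)
  } else {
    traj <- integrate_cycle(sim_rates, conditions, y0, t_grid,
                            method = method)
    sig <- if (kind == "trp_hydrolysis") {
      rowSums(traj[, c("MpDPi", "AMpDPi", "AMpD"), drop = FALSE])
    } else {
      rowSums(traj[, bright, drop = FALSE])
    }
  }
  transient(t_grid, sig, kind, conditions, signal_convention,
            meta = list(rates = rates, method = method))
}

# cumulative released phosphate: augment the 9-state system with a tenth
# component integrating the net flux through the Pi-release step
.simulate_pi_release <- function(rates, conditions, y0, t_grid) {
  Q <- build_generator(rates, conditions)
  k4p <- rates$k4_plus
  k4m <- rates$k4_minus * conditions$pi_uM
  rhs <- function(t, y, parms) {
    dy <- as.vector(Q %*% y[1:9])
    dpi <- k4p * y[7] - k4m * y[8]  # AMpDPi, AMpD
    list(c(dy, dpi))
  }
  t_solve <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  sol <- deSolve::ode(y = c(y0, pi_rel = 0), times = t_solve, func = rhs,
                      parms = NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-8)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration failed in pi_release simulation")
  }
  out <- sol[, "pi_rel"]
  if (t_grid[1] > 0) out <- out[-1]
  as.numeric(out)
}

# ---- exponential fitting ---------------------------------------------------

# separable least squares: for fixed rate constants the amplitudes and
# offset are linear, solved by QR; rates are refined on log scale
.exp_design <- function(t, k) {
  cbind(1, vapply(k, function(ki) exp(-ki * t), numeric(length(t))))
}

.exp_rss <- function(logk, t, y) {
  k <- exp(logk)
  X <- .exp_design(t, k)
  fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit)) return(Inf)
  sum(fit$residuals^2)
}

#' Fit a mono- or biexponential model to a transient
#'
#' Model: \code{signal(t) = offset + sum_i A_i exp(-k_i t)} with signed
#' amplitudes (negative for rising phases). Rates are optimised on log
#' scale by multi-start search (amplitudes profiled out by linear least
#' squares at every step), which makes the fit robust to poor starting
#' values; phases are reported fast-first.
#'
#' @param trans a \code{\link{transient}} or a list/data.frame with
#'   \code{t} and \code{signal}.
#' @param n_phases 1 or 2.
#' @param n_starts number of multi-start rate guesses (log-uniform over
#'   the resolvable rate window \code{[0.1/t_max, 10/dt_min]}).
#' @param seed seed for the multi-start draws (deterministic fits).
#' @return Object of class \code{exp_fit} with elements \code{n_phases},
#'   \code{A_fast}, \code{A_slow}, \code{k_fast}, \code{k_slow},
#'   \code{offset}, \code{r_squared}, \code{chisq} (residual sum of
#'   squares) and \code{fitted}.
#' @export
fit_exponentials <- function(trans, n_phases = 2, n_starts = 8, seed = 1) {
  t <- trans$t
  y <- trans$signal
  stopifnot(length(t) == length(y), length(t) >= 5, n_phases %in% 1:2)
  if (diff(range(y)) == 0) stop("signal is constant; nothing to fit")
  k_lo <- 0.1 / max(t)
  k_hi <- 10 / min(diff(t))
  set.seed(seed)
  starts <- replicate(n_starts,
                      sort(exp(runif(n_phases, log(k_lo), log(k_hi))),
                           decreasing = TRUE),
                      simplify = FALSE)
  # deterministic anchors: spread pairs across the window
  anchors <- exp(seq(log(k_lo * 2), log(k_hi / 2), length.out = 4))
  if (n_phases == 2) {
    for (i in seq_len(3)) starts <- c(starts,
                                      list(c(anchors[i + 1], anchors[i])))
  } else {
    starts <- c(starts, as.list(anchors))
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(log(s), .exp_rss, t = t, y = y,
            method = if (n_phases == 1) "Brent" else "Nelder-Mead",
            lower = if (n_phases == 1) log(k_lo / 10) else -Inf,
            upper = if (n_phases == 1) log(k_hi * 10) else Inf,
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    stop("exponential fit failed to converge from any of ",
         length(starts), " starts (seed ", seed, ")")
  }
  k <- sort(exp(best$par), decreasing = TRUE)
  X <- .exp_design(t, k)
  lf <- lm.fit(X, y)
  amps <- lf$coefficients[-1]
  rss <- sum(lf$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    n_phases = n_phases,
    A_fast = unname(amps[1]),
    A_slow = if (n_phases == 2) unname(amps[2]) else NA_real_,
    k_fast = unname(k[1]),
    k_slow = if (n_phases == 2) unname(k[2]) else NA_real_,
    offset = unname(lf$coefficients[1]),
    r_squared = 1 - rss / tss,
    chisq = rss,
    fitted = as.numeric(X %*% lf$coefficients)
  ), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%d-exponential fit: k_fast = %.4g /s (A = %.4g)",
              x$n_phases, x$k_fast, x$A_fast))
  if (x$n_phases == 2) {
    cat(sprintf(", k_slow = %.4g /s (A = %.4g)", x$k_slow, x$A_slow))
  }
  cat(sprintf(", offset = %.4g, R2 = %.5f\n", x$offset, x$r_squared))
  invisible(x)
}

# ---- secondary-plot analyses ----------------------------------------------

.fit_hyperbola <- function(x, y, descending = FALSE) {
  # ascending: y = k_max * x / (K_half + x)
  # descending: y = y_inf + (y0 - y_inf) * K_half / (K_half + x)
  if (descending) {
    st <- list(y_inf = min(y), y0 = max(y),
               K_half = max(x[which.min(abs(y - mean(range(y))))], min(x[x > 0])))
    fit <- minpack.lm::nlsLM(
      y ~ y_inf + (y0 - y_inf) * K_half / (K_half + x),
      start = st, lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    as.list(coef(fit))
  } else {
    ymax <- max(y)
    xhalf <- x[which.min(abs(y - ymax / 2))]
    st <- list(k_max = ymax * 1.2, K_half = max(xhalf, min(x[x > 0]) / 2))
    fit <- minpack.lm::nlsLM(
      y ~ k_max * x / (K_half + x), start = st, lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    as.list(coef(fit))
  }
}

.hyperbolic_result <- function(k_max, K_half, flags = character()) {
  structure(list(k_max = k_max, K_half = K_half,
                 initial_slope = if (is.na(K_half) || K_half == 0) NA_real_
                                 else k_max / K_half,
                 flags = flags),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic fit: plateau %.4g /s, K_half %.4g uM, slope %.4g\n",
              x$k_max, x$K_half, x$initial_slope))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Analyse the fast phase of ATP-induced dissociation
#'
#' Fits \eqn{k_{obs,fast} = K_1 k_{+2} [ATP] / (1 + K_1 [ATP])} to a
#' secondary plot of fast-phase rates against ATP concentration. The
#' plateau estimates \eqn{k_{+2}}, the half-saturation estimates
#' \eqn{1/K_1}, and the initial slope estimates the apparent second-order
#' ATP binding constant \eqn{K_1 k_{+2}}.
#'
#' @param points data.frame or list with columns/elements \code{atp_uM}
#'   and \code{k_obs} (at least 5 points).
#' @return A \code{hyperbolic_fit} with \code{k_max} (\eqn{k_{+2}}),
#'   \code{K_half} (\eqn{1/K_1}) and \code{initial_slope}
#'   (\eqn{K_1 k_{+2}}). When the data do not reach saturation the fit is
#'   flagged \code{"no_saturation"} and the slope is re-estimated from a
#'   straight line through the origin.
#' @export
analyze_fast_phase <- function(points) {
  x <- points$atp_uM
  y <- points$k_obs
  if (length(x) < 5) stop("need at least 5 (atp, k_obs) points")
  co <- tryCatch(.fit_hyperbola(x, y), error = function(e) NULL)
  if (is.null(co) || co$K_half > 2 * max(x)) {
    # no curvature information: slope-only estimate through the origin
    slope <- unname(coef(lm(y ~ x - 1))[1])
    res <- .hyperbolic_result(NA_real_, NA_real_,
                              flags = "no_saturation")
    res$initial_slope <- slope
    return(res)
  }
  flags <- character()
  if (co$K_half > 0.8 * max(x)) flags <- "wide_confidence"
  .hyperbolic_result(co$k_max, co$K_half, flags)
}

#' Analyse the slow phase of ATP-induced dissociation
#'
#' The slow-phase observed rate saturates at the closed-to-open
#' isomerization rate \eqn{k_{+\alpha}} of the nucleotide-free pocket.
#'
#' @inheritParams analyze_fast_phase
#' @return A \code{hyperbolic_fit}; \code{k_max} estimates
#'   \eqn{k_{+\alpha}}. Constant input is returned with \code{K_half = 0}
#'   and flag \code{"no_concentration_dependence"}.
#' @export
analyze_slow_phase_atp <- function(points) {
  x <- points$atp_uM
  y <- points$k_obs
  if (length(x) < 3) stop("need at least 3 (atp, k_obs) points")
  if (diff(range(y)) < 1e-10 * max(abs(y))) {
    return(.hyperbolic_result(mean(y), 0,
                              flags = "no_concentration_dependence"))
  }
  co <- .fit_hyperbola(x, y)
  .hyperbolic_result(co$k_max, co$K_half)
}

#' Pocket isomerization equilibrium from biexponential amplitudes
#'
#' At saturating ATP the fast and slow amplitudes of the dissociation
#' transient report the initial open/closed partitioning, so
#' \eqn{K_\alpha = A_{fast}/A_{slow}}.
#'
#' @param A_fast,A_slow positive phase amplitudes from a saturating-ATP
#'   transient.
#' @param atp_uM optional ATP concentration of the transient; a warning is
#'   given below ~2 mM where the ratio is still ATP-dependent.
#' @param inv_K1_uM half-saturation of ATP binding used for the saturation
#'   check (default 405 uM, the larger of the two isoform values).
#' @return \eqn{K_\alpha}.
#' @export
k_alpha_from_amplitudes <- function(A_fast, A_slow, atp_uM = NULL,
                                    inv_K1_uM = 405) {
  if (!is.numeric(A_fast) || !is.numeric(A_slow) ||
      A_fast <= 0 || A_slow <= 0) {
    stop("amplitudes must be positive (use magnitudes)")
  }
  if (!is.null(atp_uM) && atp_uM < 5 * inv_K1_uM) {
    warning("amplitude ratio is ATP-dependent below saturation (",
            atp_uM, " uM < ~5/K_1); K_alpha may be underestimated")
  }
  A_fast / A_slow
}

#' True ADP affinity from the apparent affinity
#'
#' Only the open state binds ADP-competing ATP, so the apparent ADP
#' affinity measured from slow-phase inhibition is tighter than the true
#' dissociation constant: \eqn{K_5 = K_{app} (1 + 1/K_\alpha)}.
#'
#' @param K_app_uM apparent ADP affinity (uM).
#' @param K_alpha pocket isomerization equilibrium constant.
#' @return \eqn{K_5} in uM.
#' @export
k5_from_apparent <- function(K_app_uM, K_alpha) {
  stopifnot(K_app_uM >= 0, K_alpha > 0)
  K_app_uM * (1 + 1 / K_alpha)
}

#' ADP-inhibition analysis of the slow dissociation phase
#'
#' Combines the two secondary plots of the ADP-inhibition experiment: the
#' descending hyperbola of slow-phase rates (plateau = ADP release rate
#' \eqn{k_{+5}}, half-saturation = apparent affinity \eqn{K_{app}}) and
#' the amplitude-fraction hyperbola
#' \eqn{A_{slow}/A_{total} = [ADP]/(K_5 + [ADP])} (half-saturation = true
#' affinity \eqn{K_5}). The true affinity is also computed from
#' \eqn{K_{app}} via \code{\link{k5_from_apparent}}, and the ADP binding
#' rate as \eqn{k_{-5} = k_{+5}/K_5}.
#'
#' @param slow_rates data.frame/list with \code{adp_uM} and \code{k_obs}.
#' @param amplitude_fractions data.frame/list with \code{adp_uM} and
#'   \code{frac} (\eqn{A_{slow}/A_{total}}, in [0, 1]).
#' @param K_alpha pocket isomerization equilibrium constant.
#' @return List with \code{k_plus5}, \code{K_app_ADP}, \code{K5_amp},
#'   \code{K5_calc}, \code{k_minus5} and \code{flags}.
#' @export
analyze_adp_inhibition <- function(slow_rates, amplitude_fractions,
                                   K_alpha) {
  x <- slow_rates$adp_uM
  y <- slow_rates$k_obs
  flags <- character()
  if (any(diff(y[order(x)]) > 0.05 * diff(range(y)))) {
    flags <- c(flags, "non_monotone_rates")
  }
  co <- .fit_hyperbola(x, y, descending = TRUE)
  k_plus5 <- co$y_inf
  K_app <- co$K_half
  xf <- amplitude_fractions$adp_uM
  f <- amplitude_fractions$frac
  if (any(f < 0 | f > 1)) stop("amplitude fractions must lie in [0, 1]")
  ffit <- minpack.lm::nlsLM(f ~ xf / (K5 + xf),
                            start = list(K5 = max(stats::median(xf), 1e-6)),
                            lower = 0)
  K5_amp <- unname(coef(ffit)[1])
  K5_calc <- k5_from_apparent(K_app, K_alpha)
  ratio <- K5_amp / K5_calc
  if (ratio > 3 || ratio < 1 / 3) {
    flags <- c(flags, "K5_consistency_warning")
  }
  list(k_plus5 = k_plus5, K_app_ADP = K_app, K5_amp = K5_amp,
       K5_calc = K5_calc, k_minus5 = k_plus5 / K5_amp, flags = flags)
}

#' Second-order actin binding rate from a linear secondary plot
#'
#' In the pseudo-first-order regime (0.25-3 uM actin) the observed binding
#' rate is linear in actin concentration; the slope is \eqn{k_{+A}}.
#'
#' @param points data.frame/list with \code{actin_uM} and \code{k_obs}
#'   (at least 4 points).
#' @return List of class \code{linear_fit} with \code{slope}
#'   (\eqn{k_{+A}}, \eqn{\mu M^{-1} s^{-1}}), \code{intercept} (s^-1) and
#'   \code{flags} (\code{"zero_slope"} when no concentration dependence is
#'   detected).
#' @export
analyze_actin_binding <- function(points) {
  x <- points$actin_uM
  y <- points$k_obs
  if (length(x) < 4) stop("need at least 4 (actin, k_obs) points")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  flags <- character()
  if (abs(slope) * diff(range(x)) < 1e-10 * max(abs(y), 1e-300)) {
    slope <- 0
    flags <- "zero_slope"
  }
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 flags = flags), class = "linear_fit")
}

#' Actin off-rate from a chase transient
#'
#' The unlabelled-actin chase transient is monoexponential with observed
#' rate equal to the dissociation rate \eqn{k_{-A}}.
#'
#' @param trans a \code{\link{transient}} (kind \code{actin_chase}).
#' @return \eqn{k_{-A}} in s^-1.
#' @export
analyze_actin_chase <- function(trans) {
  fit <- fit_exponentials(trans, n_phases = 1)
  fit$k_fast
}

#' Rigor actin affinity from the rate constants
#'
#' @param k_minus_A actin off-rate (s^-1).
#' @param k_plus_A actin on-rate (\eqn{\mu M^{-1} s^{-1}}).
#' @return \eqn{K_A = k_{-A}/k_{+A}} in nM.
#' @export
derive_KA <- function(k_minus_A, k_plus_A) {
  stopifnot(k_minus_A >= 0, k_plus_A > 0)
  1000 * k_minus_A / k_plus_A
}
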