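# Synthetic-data generators with embedded ground truth. Every generator is
# a pure function of its arguments and the mandatory seed, and its
# zero-noise output is exactly the corresponding forward model, so the
# analysis pipeline can be validated end-to-end by parameter recovery.
#
# Default noise emulates the order of the experimental error bars:
# absolute Gaussian noise of 1% of the signal span on fluorescence
# transients, and relative Gaussian noise of 5% on rates and velocities.

#' Generate a series of noisy stopped-flow transients
#'
#' Forward-simulates one transient per element of \code{vary} (a titration
#' series, e.g. an ATP series of 0.03-10 mM for the dissociation
#' experiment) and adds seeded Gaussian noise.
#'
#' @param kind experiment kind (see \code{\link{transient}}).
#' @param rates ground-truth \code{\link{rate_constant_set}}.
#' @param vary named list with exactly one element, the ligand to titrate
#'   and its concentrations, e.g. \code{list(atp_uM = c(30, 100, 1000))}.
#' @param t_grid time grid (s) shared by all transients.
#' @param conditions_base base \code{\link{ligand_conditions}} for the
#'   non-titrated ligands.
#' @param noise_sd absolute Gaussian noise, expressed as a fraction of the
#'   signal span (default 0.01). Zero gives the exact forward model.
#' @param seed mandatory RNG seed.
#' @return List of \code{\link{transient}} objects; each carries the
#'   ground truth in \code{meta$truth}.
#' @export
gen_transient_series <- function(kind, rates, vary, t_grid,
                                 conditions_base = ligand_conditions(),
                                 noise_sd = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory for synthetic data")
  stopifnot(length(vary) == 1, !is.null(names(vary)),
            names(vary) %in% c("atp_uM", "adp_uM", "pi_uM", "actin_uM"),
            noise_sd >= 0)
  set.seed(seed)
  lapply(seq_along(vary[[1]]), function(i) {
    conc <- vary[[1]][i]
    cond_args <- unclass(conditions_base)
    cond_args[[names(vary)]] <- conc
    cond <- do.call(ligand_conditions, cond_args)
    tr <- simulate_stopped_flow(kind, rates, cond, t_grid)
    if (noise_sd > 0) {
      span <- diff(range(tr$signal))
      tr$signal <- tr$signal + rnorm(length(tr$signal),
                                     sd = noise_sd * max(span, 1e-12))
    }
    tr$meta$truth <- rates
    tr$meta$seed <- seed
    tr
  })
}

#' Generate a noisy actin-activated ATPase table
#'
#' @param rates ground-truth \code{\link{rate_constant_set}}.
#' @param atp_uM clamped ATP concentration.
#' @param actin_grid actin concentrations (uM), e.g. 0-50 or 0-300.
#' @param noise_sd absolute Gaussian noise on the rate (s^-1); default
#'   0.005, the order of the experimental standard deviations.
#' @param seed mandatory RNG seed.
#' @return data.frame with \code{actin_uM}, \code{rate_per_s},
#'   \code{sd}; attribute \code{"truth"} holds the generating rate set.
#' @export
gen_atpase_table <- function(rates, atp_uM, actin_grid, noise_sd = 0.005,
                             seed) {
  if (missing(seed)) stop("seed is mandatory for synthetic data")
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  tab <- simulate_atpase_curve(rates, atp_uM, actin_grid)
  if (noise_sd > 0) {
    tab$rate_per_s <- tab$rate_per_s + rnorm(nrow(tab), sd = noise_sd)
  }
  tab$sd <- rep(max(noise_sd, 1e-4), nrow(tab))
  attr(tab, "truth") <- rates
  attr(tab, "seed") <- seed
  tab
}

#' Generate a frictional-loading velocity table
#'
#' Composes the resistive-force relation with the Bell force-velocity
#' model: at each crosslinker concentration the steady gliding velocity
#' solves the self-consistency condition
#' \eqn{v = v_{Bell}(F_{fric}(\alpha, v)/n_{motors})} (the frictional force
#' is proportional to the velocity, so the operating point is the fixed
#' point of the two relations). Relative Gaussian noise is added to the
#' velocities.
#'
#' @param bell ground-truth \code{\link{bell_params}}.
#' @param friction a \code{\link{friction_params}} (its \code{v} slot is
#'   ignored; velocity is solved self-consistently).
#' @param alpha_grid_uM alpha-actinin concentrations (uM).
#' @param n_motors motors per filament sharing the frictional load.
#' @param noise_rel relative Gaussian noise on velocity (default 0.05).
#' @param seed mandatory RNG seed.
#' @return data.frame with \code{alpha_uM}, \code{F_pN} (per-motor
#'   force at the operating point), \code{v_true}, \code{v_nm_s} (noisy);
#'   attribute \code{"truth"} holds the Bell parameters.
#' @export
gen_frictional_loading <- function(bell, friction, alpha_grid_uM,
                                   n_motors = 120, noise_rel = 0.05,
                                   seed) {
  if (missing(seed)) stop("seed is mandatory for synthetic data")
  stopifnot(inherits(bell, "bell_params"),
            inherits(friction, "friction_params"),
            all(alpha_grid_uM >= 0), noise_rel >= 0)
  set.seed(seed)
  v0 <- velocity_vs_force(0, bell)
  op <- vapply(alpha_grid_uM, function(a) {
    if (a == 0) return(c(0, v0))
    # F = c(alpha) * v per filament; per-motor share F/n
    cc <- friction_force(a, modifyList(friction, list(v = 1)))
    g <- function(v) v - velocity_vs_force(cc * v / n_motors, bell)
    v <- uniroot(g, c(1e-9, v0), tol = 1e-10)$root
    c(cc * v / n_motors, v)
  }, numeric(2))
  v_true <- op[2, ]
  v_obs <- if (noise_rel > 0) {
    v_true * (1 + rnorm(length(v_true), sd = noise_rel))
  } else {
    v_true
  }
  out <- data.frame(alpha_uM = alpha_grid_uM, F_pN = op[1, ],
                    v_true = v_true, v_nm_s = v_obs)
  attr(out, "truth") <- bell
  attr(out, "seed") <- seed
  out
}
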