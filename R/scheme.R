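# Nine-state reaction scheme of the acto-myosin-1C ATPase cycle.
#
# Species (fractions of total myosin; ligands clamped):
#   AM      nucleotide-free, open pocket, actin-bound
#   AMp     nucleotide-free, closed pocket ("AM'")
#   AMT     ATP-bound, pre-isomerization
#   AMpT    ATP-bound, closed pocket, weak actin affinity
#   MpT     ATP-bound, detached
#   MpDPi   post-hydrolysis, detached
#   AMpDPi  post-hydrolysis, actin-bound (entry into strong binding)
#   AMpD    ADP state, actin-bound
#   M       nucleotide-free, detached

#' Species names of the ATPase cycle state vector
#' @export
cycle_species <- c("AM", "AMp", "AMT", "AMpT", "MpT", "MpDPi",
                   "AMpDPi", "AMpD", "M")

#' Build the pseudo-first-order generator matrix of the cycle
#'
#' Returns the 9 x 9 rate matrix \eqn{Q} of the linear system
#' \eqn{dy/dt = Q y} over the cycle species, with bimolecular steps turned
#' into pseudo-first-order rates by multiplication with the clamped ligand
#' concentration. \code{Q[i, j]} is the rate from species \code{j} to
#' species \code{i}; each diagonal entry is minus its column sum, so the
#' total myosin is conserved under the dynamics.
#'
#' @param rates a \code{\link{rate_constant_set}}.
#' @param ligands a \code{\link{ligand_conditions}}.
#' @return A 9 x 9 matrix with dimnames \code{cycle_species}.
#' @export
build_generator <- function(rates, ligands) {
  stopifnot(inherits(rates, "rate_constant_set"),
            inherits(ligands, "ligand_conditions"))
  n <- length(cycle_species)
  Q <- matrix(0, n, n, dimnames = list(cycle_species, cycle_species))
  add <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
  }
  with(c(unclass(rates), unclass(ligands)), {
    add("AM", "AMT", k1_plus * atp_uM)        # ATP binding
    add("AMT", "AM", k1_minus)
    add("AMT", "AMpT", k2_plus)               # pocket isomerization
    add("AMpT", "AMT", k2_minus)
    add("AMpT", "MpT", k3diss_plus)           # actin dissociation
    add("MpT", "AMpT", k3diss_minus * actin_uM)
    add("MpT", "MpDPi", khyd)                 # hydrolysis (irreversible)
    add("MpDPi", "AMpDPi", k9_plus * actin_uM) # actin re-attachment
    add("AMpDPi", "MpDPi", k9_minus)
    add("AMpDPi", "AMpD", k4_plus)            # Pi release
    add("AMpD", "AMpDPi", k4_minus * pi_uM)
    add("AMpD", "AM", k5_plus)                # ADP release
    add("AM", "AMpD", k5_minus * adp_uM)
    add("M", "AM", kA_plus * actin_uM)        # rigor actin binding
    add("AM", "M", kA_minus)
    add("AMp", "AM", kalpha_plus)             # closed -> open isomerization
    add("AM", "AMp", kalpha_minus)
  })
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Normalised state vector over the cycle species
#'
#' @param ... named occupancies (subset of \code{\link{cycle_species}});
#'   unnamed species are zero. Values are normalised to sum to 1.
#' @return Named numeric vector of length 9.
#' @export
state_vector <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(!names(x) %in% cycle_species)) {
    stop("state_vector() takes named occupancies from: ",
         paste(cycle_species, collapse = ", "))
  }
  if (any(x < 0)) stop("occupancies must be non-negative")
  y <- setNames(numeric(length(cycle_species)), cycle_species)
  y[names(x)] <- x
  s <- sum(y)
  if (s <= 0) stop("state vector must have positive total occupancy")
  y / s
}

# Spectral propagator for the linear clamped-ligand system:
# y(t) = V exp(L t) V^-1 y0. Exact for diagonalisable Q; callers fall back
# to the stiff ODE solver when the eigenbasis is ill-conditioned.
.eigen_propagate <- function(Q, y0, times) {
  e <- eigen(Q)
  V <- e$vectors
  rc <- tryCatch(rcond(abs(V) + diag(1e-300, nrow(V))),
                 error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) return(NULL)
  c0 <- tryCatch(solve(V, as.complex(y0)), error = function(e) NULL)
  if (is.null(c0)) return(NULL)
  out <- vapply(times, function(t) {
    Re(V %*% (exp(e$values * t) * c0))[, 1]
  }, numeric(nrow(Q)))
  t(out)
}

#' Integrate the ATPase cycle over a time grid
#'
#' Solves \eqn{dy/dt = Q y} for the clamped-ligand cycle. The default
#' solver is \code{deSolve::lsoda} with tight tolerances (the rate
#' constants span roughly five orders of magnitude, 0.01 to 4000
#' \eqn{s^{-1}}, so a stiff-capable method is required). The
#' \code{"eigen"} method propagates through the eigenbasis of the
#' generator, which is exact for this linear system and much faster; it
#' falls back to \code{lsoda} when the eigenbasis is ill-conditioned.
#'
#' @param rates a \code{\link{rate_constant_set}}.
#' @param ligands a \code{\link{ligand_conditions}}.
#' @param y0 initial state, a named vector over \code{\link{cycle_species}}
#'   summing to 1 (see \code{\link{state_vector}}).
#' @param t_grid strictly increasing times (s), first element >= 0.
#' @param method \code{"lsoda"} (stiff ODE solver) or \code{"eigen"}
#'   (spectral propagator).
#' @param atol,rtol absolute and relative tolerances for the ODE solver.
#' @return Matrix \code{length(t_grid) x 9} of occupancies, with
#'   \code{attr(, "time")} carrying the grid.
#' @export
integrate_cycle <- function(rates, ligands, y0, t_grid,
                            method = c("lsoda", "eigen"),
                            atol = 1e-10, rtol = 1e-8) {
  method <- match.arg(method)
  if (length(t_grid) < 1 || any(diff(t_grid) <= 0) || t_grid[1] < 0) {
    stop("t_grid must be strictly increasing with t_grid[1] >= 0")
  }
  y0 <- y0[cycle_species]
  if (any(is.na(y0)) || abs(sum(y0) - 1) > 1e-9 || any(y0 < -1e-12)) {
    stop("y0 must be a named non-negative state over cycle_species ",
         "summing to 1")
  }
  Q <- build_generator(rates, ligands)
  traj <- NULL
  if (method == "eigen") {
    traj <- .eigen_propagate(Q, y0, t_grid)
  }
  if (is.null(traj)) {
    rhs <- function(t, y, parms) list(as.vector(Q %*% y))
    # lsoda wants the initial time in the output grid
    t_solve <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
    sol <- deSolve::ode(y = y0, times = t_solve, func = rhs, parms = NULL,
                        method = "lsoda", atol = atol, rtol = rtol)
    if (attr(sol, "istate")[1] < 0) {
      stop("stiff integration failed (lsoda istate ",
           attr(sol, "istate")[1], "); atol = ", atol, ", rtol = ", rtol,
           " - consider loosening tolerances or shortening t_grid")
    }
    traj <- sol[, cycle_species, drop = FALSE]
    if (t_grid[1] > 0) traj <- traj[-1, , drop = FALSE]
  }
  colnames(traj) <- cycle_species
  drift <- max(abs(rowSums(traj) - 1))
  if (drift > 1e-6) {
    stop("myosin conservation violated during integration (max drift ",
         signif(drift, 3), " > 1e-6); atol = ", atol, ", rtol = ", rtol)
  }
  attr(traj, "time") <- t_grid
  traj
}

#' Steady-state occupancy of the cycle
#'
#' Solves the null space of the generator for the stationary distribution.
#' When the clamped conditions leave the scheme with more than one closed
#' class (for example several absorbing species at zero ligand
#' concentrations), the stationary state is not unique; in that case a
#' starting state \code{y0} must be supplied and the long-time limit from
#' that state is returned.
#'
#' @inheritParams integrate_cycle
#' @param y0 optional starting state used to resolve non-unique stationary
#'   distributions.
#' @param tol singular values below \code{tol} count as null modes.
#' @return Named occupancy vector summing to 1.
#' @export
steady_state_occupancy <- function(rates, ligands, y0 = NULL, tol = 1e-9) {
  Q <- build_generator(rates, ligands)
  if (all(Q == 0)) stop("all rates are zero; no dynamics to solve")
  sv <- svd(Q)
  scale <- max(abs(Q))
  nullity <- sum(sv$d < tol * scale)
  if (nullity <= 1) {
    v <- sv$v[, ncol(Q)]
    if (sum(v) < 0) v <- -v
    if (any(v < -1e-8 * max(abs(v)))) {
      stop("null-space solve produced a sign-indefinite stationary vector; ",
           "the scheme is likely disconnected under these conditions")
    }
    v[v < 0] <- 0
    occ <- v / sum(v)
  } else {
    if (is.null(y0)) {
      sinks <- cycle_species[colSums(abs(Q)) - abs(diag(Q)) == 0 |
                               abs(diag(Q)) == 0]
      stop("stationary state not unique (", nullity, " closed classes; ",
           "absorbing species: ", paste(sinks, collapse = ", "),
           "); supply y0 to select the long-time limit")
    }
    # long-time limit: zero out the decaying modes
    slowest <- sort(abs(Re(eigen(Q, only.values = TRUE)$values)))[nullity + 1]
    t_inf <- 50 / max(slowest, 1e-12)
    traj <- integrate_cycle(rates, ligands, y0, c(t_inf), method = "eigen")
    occ <- pmax(traj[1, ], 0)
    occ <- occ / sum(occ)
  }
  resid <- max(abs(Q %*% occ))
  if (nullity <= 1 && resid > 1e-8 * max(scale, 1)) {
    stop("stationary residual ", signif(resid, 3), " too large")
  }
  setNames(as.vector(occ), cycle_species)
}

#' Net fluxes through each cycle step at steady state
#'
#' @inheritParams steady_state_occupancy
#' @return Named vector of net forward fluxes (per myosin head, s^-1) for
#'   every reaction step; at steady state all steps on the single cycle
#'   carry equal net flux.
#' @export
cycle_fluxes <- function(rates, ligands, y0 = NULL) {
  occ <- steady_state_occupancy(rates, ligands, y0 = y0)
  fl <- with(c(unclass(rates), unclass(ligands)), c(
    k1_plus * atp_uM * occ["AM"] - k1_minus * occ["AMT"],
    k2_plus * occ["AMT"] - k2_minus * occ["AMpT"],
    k3diss_plus * occ["AMpT"] - k3diss_minus * actin_uM * occ["MpT"],
    khyd * occ["MpT"],
    k9_plus * actin_uM * occ["MpDPi"] - k9_minus * occ["AMpDPi"],
    k4_plus * occ["AMpDPi"] - k4_minus * pi_uM * occ["AMpD"],
    k5_plus * occ["AMpD"] - k5_minus * adp_uM * occ["AM"]
  ))
  setNames(as.numeric(fl),
           c("atp_binding", "isomerization", "dissociation", "hydrolysis",
             "reattachment", "pi_release", "adp_release"))
}

#' Steady-state ATPase flux per myosin head
#'
#' Net flux through the phosphate-release step at the stationary
#' distribution, \eqn{k_{+4}[AM'DP_i] - k_{-4}[P_i][AM'D]}. At steady
#' state this equals the net flux through every other step of the cycle.
#'
#' @inheritParams steady_state_occupancy
#' @return ATPase rate in \eqn{s^{-1}} per head.
#' @export
steady_state_flux <- function(rates, ligands, y0 = NULL) {
  occ <- steady_state_occupancy(rates, ligands, y0 = y0)
  unname(rates$k4_plus * occ["AMpDPi"] -
           rates$k4_minus * ligands$pi_uM * occ["AMpD"])
}
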