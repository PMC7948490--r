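# Constrained global fitting of heterogeneous kinetic data sets by
# numerical integration of the full cycle (KinTek-style procedure):
# experimentally determined parameters are held as hard constraints,
# the remaining rate constants are optimised on log scale against all
# data sets simultaneously by weighted least squares.

#' Define a global-fit problem
#'
#' @param datasets list of data sets. Each element is a list with a
#'   \code{type} field:
#'   \itemize{
#'     \item \code{type = "transient"}: fields \code{kind},
#'       \code{conditions} (a \code{\link{ligand_conditions}}),
#'       \code{t} (time grid), \code{signal} (observed signal in occupancy
#'       units) and \code{sd} (scalar or per-point standard deviation).
#'     \item \code{type = "atpase"}: fields \code{atp_uM},
#'       \code{actin_uM} (vector), \code{rate_per_s} (vector), \code{sd}.
#'   }
#' @param template a \code{\link{rate_constant_set}} providing the values
#'   of the constrained parameters and the starting values of the free
#'   ones.
#' @param free character vector of rate-constant names to optimise; all
#'   other rate constants are constraints.
#' @param n_starts,seed multi-start settings: number of starts and RNG
#'   seed. The first start is the unperturbed template; the others
#'   perturb the free parameters log-uniformly by a factor in
#'   \code{[1/perturb, perturb]}.
#' @param perturb multiplicative width of the multi-start perturbation.
#' @param bounds_factor free parameters are bounded within
#'   \code{template/bounds_factor} and \code{template * bounds_factor}.
#' @param constraint_mode \code{"hard"} (constrained parameters fixed
#'   exactly) or \code{"soft"} (constrained parameters are optimised under
#'   a log-normal prior of width \code{prior_sd} around the template).
#' @param prior_sd prior width (relative) for soft constraints.
#' @return Object of class \code{fit_problem}.
#' @export
fit_problem <- function(datasets, template, free,
                        n_starts = 8, seed = 1, perturb = 5,
                        bounds_factor = 100,
                        constraint_mode = c("hard", "soft"),
                        prior_sd = 0.05) {
  constraint_mode <- match.arg(constraint_mode)
  stopifnot(inherits(template, "rate_constant_set"))
  unknown <- setdiff(free, .rate_fields)
  if (length(unknown)) {
    stop("free parameters not in the rate set: ",
         paste(unknown, collapse = ", "))
  }
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (!d$type %in% c("transient", "atpase")) {
      stop("dataset ", i, ": unknown type '", d$type, "'")
    }
    if (any(unlist(d$sd) <= 0)) stop("dataset ", i, ": sd must be > 0")
  }
  structure(list(datasets = datasets, template = template, free = free,
                 n_starts = n_starts, seed = seed, perturb = perturb,
                 bounds_factor = bounds_factor,
                 constraint_mode = constraint_mode, prior_sd = prior_sd),
            class = "fit_problem")
}

# predicted values for one dataset under a candidate rate set
.predict_dataset <- function(d, rates) {
  if (d$type == "transient") {
    simulate_stopped_flow(d$kind, rates, d$conditions, d$t,
                          method = "eigen")$signal
  } else {
    simulate_atpase_curve(rates, d$atp_uM, d$actin_uM)$rate_per_s
  }
}

.observed <- function(d) if (d$type == "transient") d$signal else d$rate_per_s

# weighted residual vector over all datasets (+ soft-constraint priors)
.gf_residuals <- function(logp, problem) {
  rates <- tryCatch(
    do.call(update_rates,
            c(list(problem$template),
              as.list(setNames(exp(logp), names(logp))))),
    error = function(e) NULL)
  if (is.null(rates)) return(rep(1e6, 10))
  res <- unlist(lapply(problem$datasets, function(d) {
    pred <- tryCatch(.predict_dataset(d, rates), error = function(e) NULL)
    obs <- .observed(d)
    if (is.null(pred)) return(rep(1e3, length(obs)))
    (pred - obs) / d$sd
  }))
  if (problem$constraint_mode == "soft") {
    tmpl <- unlist(problem$template[names(logp)])
    res <- c(res, (logp - log(tmpl)) / problem$prior_sd)
  }
  res
}

#' Run a constrained global fit
#'
#' Minimises the weighted sum of squared residuals over all data sets
#' with Levenberg-Marquardt (\code{minpack.lm::nls.lm}) on log-scale
#' parameters, repeated from \code{n_starts} perturbed starting points;
#' the best start wins. Deterministic for fixed inputs and seed.
#'
#' @param problem a \code{\link{fit_problem}}.
#' @return Object of class \code{fit_report}: \code{rates} (best-fit
#'   \code{\link{rate_constant_set}}), \code{chisq}, \code{chisq_dataset},
#'   \code{estimates} (named vector of fitted free parameters),
#'   \code{start_chisq} (per-start final objective), \code{trace}
#'   (accepted-iteration objective values of the winning start,
#'   non-increasing), \code{identifiability} (per-parameter flag,
#'   \code{"ok"} or \code{"weak"}), \code{converged}.
#' @export
run_global_fit <- function(problem) {
  stopifnot(inherits(problem, "fit_problem"))
  free <- problem$free
  tmpl_free <- if (problem$constraint_mode == "soft") {
    .rate_fields
  } else {
    free
  }
  p0 <- log(unlist(problem$template[tmpl_free]))
  if (any(!is.finite(p0))) {
    stop("free/soft parameters must be > 0 in the template (log scale); ",
         "offending: ",
         paste(tmpl_free[!is.finite(p0)], collapse = ", "))
  }
  lower <- p0 - log(problem$bounds_factor)
  upper <- p0 + log(problem$bounds_factor)
  set.seed(problem$seed)
  starts <- vector("list", problem$n_starts)
  starts[[1]] <- p0
  for (i in seq_len(problem$n_starts - 1)) {
    pert <- runif(length(free), -log(problem$perturb), log(problem$perturb))
    s <- p0
    s[free] <- s[free] + pert
    starts[[i + 1]] <- pmin(pmax(s, lower), upper)
  }
  runs <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = .gf_residuals, problem = problem,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all multi-start optimisations failed")
  chis <- vapply(runs, function(r) if (is.null(r)) Inf else r$deviance,
                 numeric(1))
  best <- runs[[which.min(chis)]]
  est <- exp(best$par)
  rates <- do.call(update_rates,
                   c(list(problem$template), as.list(est)))
  per_ds <- vapply(problem$datasets, function(d) {
    sum(((.predict_dataset(d, rates) - .observed(d)) / d$sd)^2)
  }, numeric(1))
  # identifiability proxy: curvature of each parameter at the optimum;
  # a near-zero diagonal of the Gauss-Newton Hessian is a flat direction
  jn <- sqrt(abs(diag(best$hessian)))
  ident <- ifelse(jn < 1e-6 * max(jn, 1e-300), "weak", "ok")
  names(ident) <- names(est)
  structure(list(
    rates = rates,
    estimates = est[free],
    chisq = best$deviance,
    chisq_dataset = per_ds,
    start_chisq = chis,
    trace = best$rsstrace,
    identifiability = ident[free],
    converged = best$info %in% 1:4
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Global fit: chi^2 =", signif(x$chisq, 5),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(signif(x$estimates, 4))
  weak <- names(x$identifiability)[x$identifiability == "weak"]
  if (length(weak)) cat("weakly identified:", paste(weak, collapse = ", "),
                        "\n")
  invisible(x)
}

#' Chi-square profile of one free parameter
#'
#' Fixes the named parameter at each grid value and re-optimises all other
#' free parameters, giving a profile-likelihood-style identifiability
#' diagnostic. A flat profile flags a parameter the data do not constrain.
#'
#' @param problem a \code{\link{fit_problem}}.
#' @param name one of \code{problem$free}.
#' @param grid parameter values to profile over.
#' @param n_starts starts per grid point (default 1; the template start).
#' @return data.frame with \code{value}, \code{chisq}, and attribute
#'   \code{"flat"} (TRUE when the profile varies by less than 1\% of its
#'   minimum or by less than an absolute 1e-6).
#' @export
profile_parameter <- function(problem, name, grid, n_starts = 1) {
  stopifnot(name %in% problem$free)
  chis <- vapply(grid, function(v) {
    tmpl <- do.call(update_rates,
                    c(list(problem$template), setNames(list(v), name)))
    sub_free <- setdiff(problem$free, name)
    if (length(sub_free) == 0) {
      sub <- fit_problem(problem$datasets, tmpl, character(0),
                         n_starts = 1, seed = problem$seed,
                         constraint_mode = "hard")
      return(sum(.gf_residuals(setNames(numeric(0), character(0)), sub)^2))
    }
    sub <- fit_problem(problem$datasets, tmpl, sub_free,
                       n_starts = n_starts, seed = problem$seed,
                       perturb = problem$perturb,
                       bounds_factor = problem$bounds_factor,
                       constraint_mode = "hard")
    run_global_fit(sub)$chisq
  }, numeric(1))
  out <- data.frame(value = grid, chisq = chis)
  spread <- diff(range(chis))
  attr(out, "flat") <- spread < max(0.01 * min(chis), 1e-6)
  out
}
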