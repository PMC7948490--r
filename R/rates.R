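# Rate-constant sets for the nine-state acto-myosin-1C ATPase cycle.
#
# Naming follows the study nomenclature: numbered steps refer to the
# actin-attached pathway (ATP binding k1, pocket isomerization k2, hydrolysis
# khyd, Pi release k4, ADP release k5), k9 to actin re-attachment of the
# post-hydrolysis head, k3diss to ATP-induced actin dissociation, kA to
# nucleotide-free actin binding, and kalpha to the AM' <-> AM isomerization
# of the nucleotide-free pocket.

.rate_fields <- c(
  "k1_plus", "k1_minus",       # AM + T <-> AMT        (uM^-1 s^-1, s^-1)
  "k2_plus", "k2_minus",       # AMT <-> AM'T          (s^-1, s^-1)
  "k3diss_plus", "k3diss_minus", # AM'T <-> M'T + A    (s^-1, uM^-1 s^-1)
  "khyd",                      # M'T -> M'DPi, lumped k+3 + k-3 (s^-1)
  "k9_plus", "k9_minus",       # M'DPi + A <-> AM'DPi  (uM^-1 s^-1, s^-1)
  "k4_plus", "k4_minus",       # AM'DPi <-> AM'D + Pi  (s^-1, uM^-1 s^-1)
  "k5_plus", "k5_minus",       # AM'D <-> AM + D       (s^-1, uM^-1 s^-1)
  "kA_plus", "kA_minus",       # M + A <-> AM          (uM^-1 s^-1, s^-1)
  "kalpha_plus", "kalpha_minus" # AM' <-> AM           (s^-1, s^-1)
)

# study-name -> KinTek Explorer numbering used in global-fit software
.kintek_alias <- c(
  k1_plus = "k+1", k1_minus = "k-1",
  k2_plus = "k+2", k2_minus = "k-2",
  k3diss_plus = "k+3", k3diss_minus = "k-3",
  khyd = "k+4",
  k9_plus = "k+5", k9_minus = "k-5",
  k4_plus = "k+6", k4_minus = "k-6",
  k5_plus = "k+7", k5_minus = "k-7",
  kA_plus = "k+8", kA_minus = "k-8",
  kalpha_plus = "k+9", kalpha_minus = "k-9"
)

#' Construct a rate-constant set for the acto-myosin-1C cycle
#'
#' Bundles the forward and backward rate constants of all nine reaction
#' steps of the ATPase cycle. Bimolecular constants are in
#' \eqn{\mu M^{-1} s^{-1}}, unimolecular constants in \eqn{s^{-1}}.
#' Hydrolysis is treated as a single irreversible step at the lumped rate
#' \code{khyd} (the sum of the forward and reverse hydrolysis rates, which
#' is what a tryptophan-fluorescence relaxation measures).
#'
#' @param k1_plus,k1_minus ATP binding to the acto-myosin complex
#'   (AM + T to AMT) and its reversal.
#' @param k2_plus,k2_minus isomerization of the ATP-bound complex
#'   (AMT to AM'T) and its reversal.
#' @param k3diss_plus,k3diss_minus actin dissociation of the ATP-bound head
#'   (AM'T to M'T + A) and rebinding.
#' @param khyd lumped ATP hydrolysis rate (M'T to M'DPi), irreversible.
#' @param k9_plus,k9_minus actin binding of the post-hydrolysis head
#'   (M'DPi + A to AM'DPi) and its reversal.
#' @param k4_plus,k4_minus phosphate release (AM'DPi to AM'D + Pi) and
#'   rebinding.
#' @param k5_plus,k5_minus ADP release (AM'D to AM + D) and rebinding.
#' @param kA_plus,kA_minus nucleotide-free actin binding (M + A to AM) and
#'   dissociation.
#' @param kalpha_plus,kalpha_minus closed-to-open isomerization of the
#'   nucleotide-free pocket (AM' to AM) and its reversal; the equilibrium
#'   constant \eqn{K_\alpha = k_{+\alpha}/k_{-\alpha}}.
#' @param isoform_label free-text label, e.g. \code{"Myo1C0-dTH1"}.
#' @param temperature_C assay temperature in degrees Celsius.
#'
#' @return An object of class \code{rate_constant_set} (a named list).
#' @seealso \code{\link{myo1c_rates}} for the packaged isoform presets,
#'   \code{\link{equilibrium_constants}} for derived equilibria.
#' @export
rate_constant_set <- function(k1_plus, k1_minus, k2_plus, k2_minus,
                              k3diss_plus, k3diss_minus, khyd,
                              k9_plus, k9_minus, k4_plus, k4_minus,
                              k5_plus, k5_minus, kA_plus, kA_minus,
                              kalpha_plus, kalpha_minus,
                              isoform_label = "custom",
                              temperature_C = 20) {
  x <- mget(.rate_fields, envir = environment())
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L ||
                  is.na(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("rate constants must be single non-negative numbers; offending: ",
         paste(names(x)[bad], collapse = ", "))
  }
  structure(c(x, list(isoform_label = isoform_label,
                      temperature_C = temperature_C)),
            class = "rate_constant_set")
}

#' @export
print.rate_constant_set <- function(x, ...) {
  cat("Acto-myosin-1C rate-constant set:", x$isoform_label,
      sprintf("(%g C)\n", x$temperature_C))
  v <- unlist(x[.rate_fields])
  print(round(v, 4))
  eq <- equilibrium_constants(x)
  cat("Derived equilibria: K_alpha =", signif(eq$K_alpha, 3),
      " K_A =", signif(eq$K_A_nM, 4), "nM",
      " K_9 =", signif(eq$K_9, 3), "uM",
      " 1/K_1 =", signif(eq$inv_K_1, 4), "uM\n")
  invisible(x)
}

#' Derived equilibrium constants of a rate set
#'
#' @param rates a \code{\link{rate_constant_set}}.
#' @return List with \code{K_alpha} (= kalpha_plus/kalpha_minus),
#'   \code{K_A_nM} (actin affinity, nM), \code{K_9} (uM), \code{K_2},
#'   \code{inv_K_1} (uM), \code{K_5} (ADP affinity, uM).
#' @export
equilibrium_constants <- function(rates) {
  stopifnot(inherits(rates, "rate_constant_set"))
  list(
    K_alpha = rates$kalpha_plus / rates$kalpha_minus,
    K_A_nM  = 1000 * rates$kA_minus / rates$kA_plus,
    K_9     = rates$k9_minus / rates$k9_plus,
    K_2     = rates$k2_plus / rates$k2_minus,
    inv_K_1 = rates$k1_minus / rates$k1_plus,
    K_5     = rates$k5_plus / rates$k5_minus
  )
}

#' Packaged rate-constant presets for the myosin-1C splice isoforms
#'
#' Global-fit rate constants of the tail-truncated constructs
#' Myo1C0-dTH1 (no N-terminal extension) and Myo1C35-dTH1 (35-residue
#' extension) at 20 C.
#'
#' @param isoform \code{"myo1c0"} or \code{"myo1c35"}.
#' @return A \code{\link{rate_constant_set}}.
#' @export
myo1c_rates <- function(isoform = c("myo1c0", "myo1c35")) {
  isoform <- match.arg(isoform)
  if (isoform == "myo1c0") {
    rate_constant_set(
      k1_plus = 4.0, k1_minus = 621,
      k2_plus = 37.0, k2_minus = 1.0,
      k3diss_plus = 10.1, k3diss_minus = 0.01,
      khyd = 75.0,
      k9_plus = 0.79, k9_minus = 8.53,
      k4_plus = 0.10, k4_minus = 0.08,
      k5_plus = 1.66, k5_minus = 3.94,
      kA_plus = 1.47, kA_minus = 0.019,
      kalpha_plus = 4.2, kalpha_minus = 4.72,
      isoform_label = "Myo1C0-dTH1", temperature_C = 20
    )
  } else {
    rate_constant_set(
      k1_plus = 4.1, k1_minus = 1650,
      k2_plus = 37.0, k2_minus = 6.9,
      k3diss_plus = 10.1, k3diss_minus = 0.01,
      khyd = 75.0,
      k9_plus = 1.2, k9_minus = 26.6,
      k4_plus = 0.10, k4_minus = 0.08,
      k5_plus = 0.86, k5_minus = 3.94,
      kA_plus = 2.27, kA_minus = 0.037,
      kalpha_plus = 3.9, kalpha_minus = 1.05,
      isoform_label = "Myo1C35-dTH1", temperature_C = 20
    )
  }
}

#' Update selected rate constants of a set
#'
#' @param rates a \code{\link{rate_constant_set}}.
#' @param ... named replacement values, e.g. \code{k4_plus = 0.2}.
#' @return The modified set (re-validated).
#' @export
update_rates <- function(rates, ...) {
  stopifnot(inherits(rates, "rate_constant_set"))
  repl <- list(...)
  unknown <- setdiff(names(repl), .rate_fields)
  if (length(unknown)) {
    stop("unknown rate constant(s): ", paste(unknown, collapse = ", "))
  }
  args <- modifyList(unclass(rates), repl)
  do.call(rate_constant_set, args)
}

#' Serialize a rate set to JSON or YAML
#'
#' The file carries the constants under both the study nomenclature and the
#' KinTek Explorer numbering (as aliases), plus the derived equilibrium
#' constants for cross-checking.
#'
#' @param rates a \code{\link{rate_constant_set}}.
#' @param path output file; format chosen by extension (.json or .yaml/.yml).
#' @return \code{path}, invisibly.
#' @export
write_rate_set <- function(rates, path) {
  stopifnot(inherits(rates, "rate_constant_set"))
  v <- unlist(rates[.rate_fields])
  obj <- list(
    isoform_label = rates$isoform_label,
    temperature_C = rates$temperature_C,
    units = list(bimolecular = "uM^-1 s^-1", unimolecular = "s^-1"),
    rates = as.list(v),
    kintek_aliases = as.list(setNames(unname(v), .kintek_alias[.rate_fields])),
    derived = equilibrium_constants(rates)
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a rate set written by \code{\link{write_rate_set}}
#'
#' @param path JSON or YAML file.
#' @return A \code{\link{rate_constant_set}}.
#' @export
read_rate_set <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- as.list(unlist(obj$rates))
  args$isoform_label <- obj$isoform_label
  args$temperature_C <- obj$temperature_C
  do.call(rate_constant_set, args)
}

#' Clamped ligand concentrations
#'
#' Ligand pools are held constant during integration (pseudo-first-order
#' approximation, valid for the excess-ligand stopped-flow and steady-state
#' regimes this package models).
#'
#' @param atp_uM,adp_uM,pi_uM,actin_uM concentrations in micromolar,
#'   all non-negative.
#' @return An object of class \code{ligand_conditions}.
#' @export
ligand_conditions <- function(atp_uM = 0, adp_uM = 0, pi_uM = 0,
                              actin_uM = 0) {
  x <- list(atp_uM = atp_uM, adp_uM = adp_uM, pi_uM = pi_uM,
            actin_uM = actin_uM)
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L ||
                  is.na(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("ligand concentrations must be single non-negative numbers; ",
         "offending: ", paste(names(x)[bad], collapse = ", "))
  }
  structure(x, class = "ligand_conditions")
}

#' @export
print.ligand_conditions <- function(x, ...) {
  cat(sprintf("Ligands (uM, clamped): ATP %g, ADP %g, Pi %g, actin %g\n",
              x$atp_uM, x$adp_uM, x$pi_uM, x$actin_uM))
  invisible(x)
}
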