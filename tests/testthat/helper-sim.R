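# Shared fixtures, built in code.

# random but valid rate set spanning the stiff range of the cycle
random_rate_set <- function(seed) {
  set.seed(seed)
  r <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  rate_constant_set(
    k1_plus = r(0.5, 10), k1_minus = r(100, 5000),
    k2_plus = r(5, 100), k2_minus = r(0.5, 10),
    k3diss_plus = r(1, 50), k3diss_minus = r(0.001, 0.1),
    khyd = r(10, 200),
    k9_plus = r(0.1, 5), k9_minus = r(1, 50),
    k4_plus = r(0.02, 1), k4_minus = r(0.01, 0.5),
    k5_plus = r(0.2, 5), k5_minus = r(0.5, 10),
    kA_plus = r(0.5, 5), kA_minus = r(0.005, 0.1),
    kalpha_plus = r(1, 10), kalpha_minus = r(0.5, 10),
    isoform_label = paste0("random-", seed)
  )
}

# heterogeneous synthetic data collection for global-fit recovery:
# ATP-induced dissociation, ADP inhibition, rigor actin binding,
# phosphate release, and an actin-activated ATPase curve
make_recovery_datasets <- function(rates, noise = 0, seed = 1) {
  set.seed(seed)
  ds <- list()
  grids <- list(
    list(kind = "atp_dissociation",
         cond = ligand_conditions(atp_uM = 3000),
         t = exp(seq(log(2e-3), log(2), length.out = 120))),
    list(kind = "adp_inhibition",
         cond = ligand_conditions(atp_uM = 3000, adp_uM = 2),
         t = exp(seq(log(5e-3), log(6), length.out = 120))),
    list(kind = "actin_binding",
         cond = ligand_conditions(actin_uM = 1.5),
         t = seq(0.005, 1.2, length.out = 120)),
    list(kind = "pi_release",
         cond = ligand_conditions(actin_uM = 5),
         t = seq(1, 150, length.out = 80))
  )
  for (g in grids) {
    tr <- simulate_stopped_flow(g$kind, rates, g$cond, g$t)
    sd <- max(0.02 * diff(range(tr$signal)), 1e-6)
    sig <- if (noise > 0) {
      tr$signal * (1 + rnorm(length(tr$signal), sd = noise))
    } else {
      tr$signal
    }
    ds[[length(ds) + 1]] <- list(type = "transient", kind = g$kind,
                                 conditions = g$cond, t = g$t,
                                 signal = sig, sd = sd)
  }
  at <- simulate_atpase_curve(rates, 1000, c(2, 5, 10, 20, 40, 80, 150, 300))
  rate <- if (noise > 0) {
    at$rate_per_s * (1 + rnorm(nrow(at), sd = noise))
  } else {
    at$rate_per_s
  }
  ds[[length(ds) + 1]] <- list(type = "atpase", atp_uM = 1000,
                               actin_uM = at$actin_uM, rate_per_s = rate,
                               sd = pmax(0.02 * at$rate_per_s, 1e-5))
  ds
}

# free parameters used in the recovery exercises: the constants that are
# not among the experimentally constrained ones and that the data sets
# above can actually determine (reverse rates of pre-equilibrating
# binding steps are only determined through their equilibrium constant,
# so k9_minus stays constrained while k9_plus is fitted)
recovery_free <- c("k4_plus", "k9_plus", "kA_plus", "k5_minus", "k2_minus")
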