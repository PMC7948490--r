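test_that("noiseless biexponentials are recovered exactly", {
  t <- seq(0, 1.5, by = 0.002)
  y <- 1 - 0.7 * exp(-37 * t) - 0.3 * exp(-4 * t)
  f <- fit_exponentials(list(t = t, signal = y), n_phases = 2)
  expect_equal(f$k_fast, 37, tolerance = 1e-6)
  expect_equal(f$k_slow, 4, tolerance = 1e-6)
  expect_equal(f$A_fast, -0.7, tolerance = 1e-6)
  expect_equal(f$A_slow, -0.3, tolerance = 1e-6)
  expect_equal(f$offset, 1, tolerance = 1e-6)
  expect_gte(f$k_fast, f$k_slow)
})

test_that("biexponential rates survive noise within a few percent", {
  t <- seq(0, 1.5, by = 0.002)
  clean <- 1 - 0.7 * exp(-37 * t) - 0.3 * exp(-4 * t)
  for (seed in 1:5) {
    set.seed(seed)
    y <- clean + rnorm(length(t), sd = 0.01)
    f <- fit_exponentials(list(t = t, signal = y), n_phases = 2,
                          seed = seed)
    expect_equal(f$k_fast, 37, tolerance = 0.05)
    expect_equal(f$k_slow, 4, tolerance = 0.05)
  }
})

test_that("a single-path dissociation transient is monoexponential", {
  # freezing the closed state removes the slow phase entirely
  r <- update_rates(myo1c_rates("myo1c0"), kalpha_plus = 0,
                    kalpha_minus = 0)
  tg <- seq(5e-4, 0.5, by = 5e-4)
  tr <- simulate_stopped_flow("atp_dissociation", r,
                              ligand_conditions(atp_uM = 3000), tg)
  f1 <- fit_exponentials(tr, n_phases = 1)
  expect_gt(f1$r_squared, 0.999)
  # no isomerization-limited slow phase survives: any residual second
  # component is fast and tiny compared to the main 36/s rise
  f2 <- fit_exponentials(tr, n_phases = 2)
  expect_true(f2$k_slow > 8 || abs(f2$A_slow) < 0.02)
})

test_that("simulated dissociation transients reproduce the observed rates", {
  r35 <- myo1c_rates("myo1c35")
  tg <- c(seq(1e-3, 0.3, by = 1e-3), seq(0.302, 3, by = 5e-3))
  tr <- simulate_stopped_flow("atp_dissociation", r35,
                              ligand_conditions(atp_uM = 3000), tg)
  f <- fit_exponentials(tr, n_phases = 2)
  # fast phase saturates near k_+2; at 3 mM ATP, K_1[ATP]/(1+K_1[ATP])
  # predicts ~0.88 of the plateau
  expect_equal(f$k_fast, 37 * (3000 / 405) / (1 + 3000 / 405),
               tolerance = 0.25)
  # the slow tail relaxes at the closed-to-open isomerization rate: fit
  # the late window where the fast modes have decayed
  late <- tr$t > 0.4
  fs <- fit_exponentials(list(t = tr$t[late], signal = tr$signal[late]),
                         n_phases = 1)
  expect_equal(fs$k_fast, 3.9, tolerance = 0.05)
})

test_that("amplitude ratio approaches K_alpha as phase separation grows", {
  # the textbook identity A_fast/A_slow = K_alpha assumes the fast phase
  # is infinitely faster than the pocket isomerization; scaling the fast
  # branch up must converge the simulated ratio to K_alpha
  r35 <- myo1c_rates("myo1c35")
  sep <- update_rates(r35, k2_plus = r35$k2_plus * 200,
                      k1_plus = r35$k1_plus * 200,
                      k2_minus = 0,
                      kalpha_minus = r35$kalpha_minus / 50,
                      kalpha_plus = r35$kalpha_plus / 50)
  tg <- c(seq(2e-5, 0.02, by = 2e-5), seq(0.021, 60, by = 0.02))
  tr <- simulate_stopped_flow("atp_dissociation", sep,
                              ligand_conditions(atp_uM = 10000), tg)
  f <- fit_exponentials(tr, n_phases = 2)
  Ka <- sep$kalpha_plus / sep$kalpha_minus
  expect_equal(abs(f$A_fast) / abs(f$A_slow), Ka, tolerance = 0.02)
})

test_that("fast-phase analysis recovers ATP binding parameters", {
  atp <- c(25, 50, 100, 200, 400, 800, 1600, 3200, 6400)
  kobs <- 37.0 * atp / (405 + atp)
  res <- analyze_fast_phase(list(atp_uM = atp, k_obs = kobs))
  expect_equal(res$k_max, 37.0, tolerance = 1e-6)
  expect_equal(res$K_half, 405, tolerance = 1e-6)
  expect_equal(res$initial_slope, 37.0 / 405, tolerance = 1e-6)

  # sub-saturating data: slope-only estimate, flagged
  atp_lo <- c(5, 10, 20, 35, 50)
  res_lo <- analyze_fast_phase(list(atp_uM = atp_lo,
                                    k_obs = 0.068 * atp_lo))
  expect_true("no_saturation" %in% res_lo$flags ||
                "wide_confidence" %in% res_lo$flags)
  expect_equal(res_lo$initial_slope, 0.068, tolerance = 0.02)

  expect_error(analyze_fast_phase(list(atp_uM = c(1, 2),
                                       k_obs = c(0.1, 0.2))),
               "at least 5")
})

test_that("slow-phase plateau estimates the isomerization rate", {
  atp <- c(50, 100, 250, 500, 1000, 2500, 5000, 10000)
  res <- analyze_slow_phase_atp(list(atp_uM = atp,
                                     k_obs = 4.1 * atp / (150 + atp)))
  expect_equal(res$k_max, 4.1, tolerance = 1e-6)

  # simulate-and-fit route: plateau of fitted slow rates for Myo1C35
  r35 <- myo1c_rates("myo1c35")
  atp2 <- c(250, 500, 1000, 3000, 10000)
  kslow <- vapply(atp2, function(a) {
    tg <- c(seq(1e-3, 0.3, by = 2e-3), seq(0.304, 3.5, by = 8e-3))
    tr <- simulate_stopped_flow("atp_dissociation", r35,
                                ligand_conditions(atp_uM = a), tg)
    late <- tr$t > 0.45
    fit_exponentials(list(t = tr$t[late], signal = tr$signal[late]),
                     n_phases = 1)$k_fast
  }, numeric(1))
  res2 <- analyze_slow_phase_atp(list(atp_uM = atp2, k_obs = kslow))
  expect_equal(res2$k_max, 3.9, tolerance = 0.05)

  cst <- analyze_slow_phase_atp(list(atp_uM = c(1, 2, 3, 4),
                                     k_obs = rep(2.5, 4)))
  expect_equal(cst$k_max, 2.5)
  expect_true("no_concentration_dependence" %in% cst$flags)
})

test_that("K_alpha follows from the saturating amplitude ratio", {
  expect_equal(k_alpha_from_amplitudes(0.9, 1.0), 0.90)
  expect_equal(k_alpha_from_amplitudes(3.7, 1.0), 3.70)
  expect_equal(k_alpha_from_amplitudes(0.5, 0.5), 1.0)
  expect_error(k_alpha_from_amplitudes(-1, 1), "positive")
  expect_warning(k_alpha_from_amplitudes(1, 1, atp_uM = 100),
                 "below saturation")
})

test_that("ADP inhibition analysis yields the release and binding constants", {
  adp <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 25)
  K_app <- 0.21
  k_alpha <- 0.90
  kslow <- 0.87 + (4.1 - 0.87) * K_app / (K_app + adp)
  frac <- adp / (0.23 + adp)
  res <- analyze_adp_inhibition(
    list(adp_uM = adp, k_obs = kslow),
    list(adp_uM = adp, frac = frac), k_alpha)
  expect_equal(res$k_plus5, 0.87, tolerance = 1e-4)
  expect_equal(res$K_app_ADP, 0.21, tolerance = 1e-4)
  expect_equal(res$K5_amp, 0.23, tolerance = 1e-4)
  # K_5 = K_app (1 + 1/K_alpha): 0.21 * (1 + 1/0.90) = 0.443
  expect_equal(res$K5_calc, 0.4433, tolerance = 1e-3)
  # k_-5 = k_+5 / K_5 = 0.87 / 0.23
  expect_equal(res$k_minus5, 3.78, tolerance = 0.01)
  # limit: with an always-open pocket the apparent affinity is the true one
  expect_equal(k5_from_apparent(0.21, 1e12), 0.21, tolerance = 1e-9)
})

test_that("actin-binding and chase analyses give the rigor constants", {
  actin <- c(0.25, 0.5, 1, 1.5, 2, 3)
  lf <- analyze_actin_binding(list(actin_uM = actin,
                                   k_obs = 2.22 * actin + 0.037))
  expect_equal(lf$slope, 2.22, tolerance = 1e-8)
  lf0 <- analyze_actin_binding(list(actin_uM = actin,
                                    k_obs = rep(0.5, 6)))
  expect_equal(lf0$slope, 0)
  expect_true("zero_slope" %in% lf0$flags)

  # simulate-fit-regress: pseudo-first-order binding transients recover
  # the input on-rate
  r35 <- myo1c_rates("myo1c35")
  kobs <- vapply(actin, function(a) {
    tg <- seq(0.005, 2.5, by = 0.005)
    tr <- simulate_stopped_flow("actin_binding", r35,
                                ligand_conditions(actin_uM = a), tg)
    fit_exponentials(tr, n_phases = 1)$k_fast
  }, numeric(1))
  lf2 <- analyze_actin_binding(list(actin_uM = actin, k_obs = kobs))
  expect_equal(lf2$slope, r35$kA_plus, tolerance = 0.03)

  expect_equal(derive_KA(0.037, 2.27), 16.30, tolerance = 1e-3)
  expect_equal(derive_KA(0.019, 1.46), 13.01, tolerance = 1e-2)
  expect_equal(derive_KA(0, 1.46), 0)

  # chase transient reports the off-rate directly
  tg <- seq(1, 400, by = 1)
  tr <- simulate_stopped_flow("actin_chase", r35, ligand_conditions(), tg)
  expect_equal(analyze_actin_chase(tr), r35$kA_minus, tolerance = 1e-3)
})

test_that("phosphate release at low actin is slow and single-exponential", {
  r0 <- myo1c_rates("myo1c0")
  tg <- seq(0.2, 250, by = 0.4)
  tr <- simulate_stopped_flow("pi_release", r0,
                              ligand_conditions(actin_uM = 5), tg)
  f <- fit_exponentials(tr, n_phases = 1)
  expect_gt(f$r_squared, 0.999)
  # actin binding at 5 uM only partially saturates the 0.10/s release
  expect_gt(f$k_fast, 0.015)
  expect_lt(f$k_fast, 0.045)
})

test_that("experiment kinds validate their conditions", {
  r0 <- myo1c_rates("myo1c0")
  tg <- seq(0.01, 1, by = 0.01)
  expect_error(simulate_stopped_flow("atp_dissociation", r0,
                                     ligand_conditions(), tg),
               "atp_uM > 0")
  expect_error(simulate_stopped_flow("actin_chase", r0,
                                     ligand_conditions(actin_uM = 5), tg),
               "unlabelled")
  expect_error(simulate_stopped_flow("nope", r0, ligand_conditions(), tg))
  expect_error(simulate_stopped_flow("atp_dissociation", r0,
                                     ligand_conditions(atp_uM = 100), tg,
                                     signal_convention = c("XX")),
               "unknown species")
})
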