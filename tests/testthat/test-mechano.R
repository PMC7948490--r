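test_that("friction force vanishes at zero crosslinker and scales correctly", {
  fp <- friction_params()
  expect_equal(friction_force(0, fp), 0)
  a <- c(0.001, 0.01, 0.05)
  expect_true(all(diff(friction_force(seq(0, 0.2, by = 0.01), fp)) >= 0))
  # proportional to velocity, stiffness, length and reach
  f1 <- friction_force(a, fp)
  expect_equal(friction_force(a, friction_params(v = 104)),
               2 * f1, tolerance = 1e-12)
  expect_equal(friction_force(a, friction_params(kappa = 0.7)),
               2 * f1, tolerance = 1e-12)
  expect_error(friction_force(-1, fp), ">= 0")
})

test_that("friction force limiting exponents are 5/2 and 1", {
  fp <- friction_params()
  # log-log slope in the two regimes
  lo <- c(1e-6, 2e-6)
  hi <- c(1000, 2000)
  slope_lo <- diff(log(friction_force(lo, fp))) / diff(log(lo))
  slope_hi <- diff(log(friction_force(hi, fp))) / diff(log(hi))
  expect_equal(slope_lo, 2.5, tolerance = 1e-3)
  expect_equal(slope_hi, 1.0, tolerance = 1e-2)
  # doubling ratio approaches 2^(5/2) at low and 2 at high concentration
  expect_equal(friction_force(2e-6, fp) / friction_force(1e-6, fp),
               2^2.5, tolerance = 1e-3)
  expect_equal(friction_force(2000, fp) / friction_force(1000, fp),
               2, tolerance = 1e-3)
})

test_that("friction force matches an independently coded expression", {
  # independent oracle: evaluate the published formula term by term
  oracle <- function(a, p) {
    num <- p$kA_fric * p$chi * a^(5 / 2)
    den <- p$kA_fric * p$chi * a^(3 / 2) + p$kD_fric
    prefac <- (p$kappa / p$kD_fric) * p$v * p$zeta * p$L * p$r
    prefac * num / den
  }
  set.seed(99)
  for (i in 1:5) {
    p <- friction_params(kappa = runif(1, 0.2, 0.5),
                         kA_fric = runif(1, 1, 50),
                         kD_fric = runif(1, 1, 50),
                         L = runif(1, 500, 3000),
                         r = 61, zeta = runif(1, 1, 100),
                         chi = runif(1, 0.5, 2), v = runif(1, 5, 60))
    a <- runif(100, 0, 0.5)
    expect_equal(friction_force(a, p), oracle(a, p), tolerance = 1e-12)
  }
})

test_that("the Bell force-velocity relation has the right limits", {
  p0 <- myo1c_bell("myo1c0")
  # unloaded velocity: w / (1/k_i + 1/k_f0) = 7.8 / (1/8 + 1/70.3)
  expect_equal(velocity_vs_force(0, p0), 56.0, tolerance = 1e-2)
  expect_lt(velocity_vs_force(50, p0), 1e-8)
  # no force sensitivity when the distance parameter vanishes
  p_flat <- bell_params(w = 7.8, k_i = 8, k_f0 = 70.3, d = 1e-12)
  expect_equal(velocity_vs_force(c(0, 2, 10), p_flat),
               rep(velocity_vs_force(0, p0), 3), tolerance = 1e-6)
})

test_that("v(F) decreases and P(F) is unimodal over random parameter sets", {
  set.seed(2024)
  Fg <- seq(0, 12, length.out = 400)
  for (i in 1:200) {
    p <- bell_params(w = runif(1, 1, 12), k_i = exp(runif(1, 0, 4)),
                     k_f0 = exp(runif(1, 0, 5)), d = runif(1, 1, 15),
                     kBT = 4.28)
    v <- velocity_vs_force(Fg, p)
    expect_true(all(diff(v) < 0))
    pc <- power_curve(p, Fg)
    expect_equal(pc$P_aW[1], 0)
    # single interior maximum: the sign of dP changes exactly once
    sgn <- sign(diff(pc$P_aW))
    expect_lte(sum(diff(sgn[sgn != 0]) != 0), 1)
    expect_gt(pc$F_Pmax, 0)
  }
})

test_that("power maximum from the root condition matches the grid argmax", {
  # independent oracle: dP/dF = 0 <=> 1 = F (d/kBT) g/(1/k_i + g),
  # g = e^{Fd/kBT}/k_f0; solve by root finding and compare
  p <- myo1c_bell("myo1c0")
  g <- function(F) exp(F * p$d / p$kBT) / p$k_f0
  cond <- function(F) 1 - F * (p$d / p$kBT) * g(F) / (1 / p$k_i + g(F))
  root <- uniroot(cond, c(1e-3, 50))$root
  pc <- power_curve(p, seq(0, 10, length.out = 2000))
  expect_equal(pc$F_Pmax, root, tolerance = 1e-4)
  expect_equal(pc$P_max,
               root * velocity_vs_force(root, p) * 1e-3, tolerance = 1e-6)
})

test_that("noiseless force-velocity fits invert the forward model exactly", {
  truth <- bell_params(w = 7.8, k_i = 8.0, k_f0 = 70.3, d = 5.0)
  F <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6)
  v <- velocity_vs_force(F, truth)
  fit <- fit_force_velocity(list(F = F, v = v), w = 7.8)
  expect_equal(fit$k_i, 8.0, tolerance = 1e-6)
  expect_equal(fit$k_f0, 70.3, tolerance = 1e-6)
  expect_equal(fit$d, 5.0, tolerance = 1e-6)
})

test_that("force-velocity parameters survive 5% noise within 10%", {
  truth <- bell_params(w = 7.8, k_i = 8.0, k_f0 = 70.3, d = 5.0)
  F <- seq(0, 6, length.out = 15)
  v <- velocity_vs_force(F, truth)
  errs <- sapply(1:10, function(seed) {
    set.seed(seed)
    vn <- v * (1 + rnorm(length(v), sd = 0.05))
    fit <- fit_force_velocity(list(F = F, v = vn), w = 7.8, d = 5.0)
    c(abs(fit$k_i / 8.0 - 1), abs(fit$k_f0 / 70.3 - 1))
  })
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("a force range too narrow to separate the rates is flagged", {
  truth <- bell_params(w = 7.8, k_i = 8.0, k_f0 = 70.3, d = 5.0)
  F <- seq(0, 0.05, length.out = 8)
  fit <- fit_force_velocity(list(F = F,
                                 v = velocity_vs_force(F, truth)),
                            w = 7.8, d = 5.0)
  expect_true(any(c("narrow_force_range", "rates_anticorrelated") %in%
                    attr(fit, "flags")))
})

test_that("logistic velocity fits recover parameters and the midpoint identity", {
  x <- seq(0, 100, length.out = 12)
  truth <- c(A1 = 52, A2 = 0, x0 = 25, dx = 18)
  v <- 0 + (52 - 0) / (1 + exp((x - 25) / 18))
  fit <- fit_logistic_velocity(list(x = x, v = v))
  expect_equal(fit$A1, 52, tolerance = 1e-6)
  expect_equal(fit$A2, 0, tolerance = 1e-5)
  expect_equal(fit$x0, 25, tolerance = 1e-5)
  expect_equal(fit$dx, 18, tolerance = 1e-5)
  # v(x0) = (A1 + A2)/2 for any fitted logistic of this form
  vmid <- fit$A2 + (fit$A1 - fit$A2) / 2
  expect_equal(fit$A2 + (fit$A1 - fit$A2) /
                 (1 + exp((fit$x0 - fit$x0) / fit$dx)), vmid)
})

test_that("frictional-loading composition gives a ~25 nM midpoint", {
  fl <- gen_frictional_loading(myo1c_bell("myo1c0"), friction_params(),
                               alpha_grid_uM = seq(0, 0.1, by = 0.005),
                               n_motors = 120, noise_rel = 0, seed = 1)
  fit <- fit_logistic_velocity(list(x = fl$alpha_uM * 1000,
                                    v = fl$v_nm_s))
  expect_gt(fit$x0, 10)
  expect_lt(fit$x0, 45)
})

test_that("motor counting from stall forces", {
  expect_equal(motors_per_filament(600, 5), 120)
  expect_equal(motors_per_filament(5, 5), 1)
  expect_equal(motors_per_filament(0, 5), 0)
})
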