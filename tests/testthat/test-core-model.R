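test_that("Boltzmann factor matches the reference values and its identities", {
  expect_equal(boltzmann_factor(-0.04), 0.2104, tolerance = 5e-4)
  expect_equal(boltzmann_factor(-0.07), 0.0654, tolerance = 5e-4)
  expect_identical(boltzmann_factor(0, 310), 1)
  expect_true(all(boltzmann_factor(c(-0.1, -0.01, 0.05)) > 0))
  expect_error(boltzmann_factor(NaN), class = "clsecretion_invalid_input")
  expect_error(boltzmann_factor(-0.04, -5), class = "clsecretion_invalid_input")
})

test_that("chloride equilibrium concentration nulls the membrane current", {
  expect_equal(cl_equilibrium(127.5, -0.04), 26.8, tolerance = 2e-3)
  expect_identical(cl_equilibrium(127.5, 0), 127.5)
  expect_identical(cl_equilibrium(0, -0.04), 0)
  # zero-current point is exact, not approximate
  cl_eq <- cl_equilibrium(127.5, -0.04)
  expect_identical(membrane_current(39e-6, -0.04, cl_eq, 127.5), 0)
})

test_that("chord current is linear, signed by the driving force, and handles V=0 via the limit", {
  g <- 39e-6; v <- -0.04; clo <- 127.5
  i1 <- membrane_current(g, v, 40, clo)
  expect_equal(membrane_current(2 * g, v, 40, clo), 2 * i1)
  # linear in cl_in: I(a) + I(b) - 2 I((a+b)/2) = 0
  ia <- membrane_current(g, v, 30, clo); ib <- membrane_current(g, v, 50, clo)
  expect_equal(ia + ib, 2 * membrane_current(g, v, 40, clo))
  # above equilibrium, a negative (secretory) current
  expect_lt(membrane_current(g, v, 40, clo), 0)
  expect_error(membrane_current(g, 0, 40, clo),
               class = "clsecretion_invalid_input")
  # V -> 0 limit agreement at +/- 1 uV
  for (v_small in c(1e-6, -1e-6)) {
    lim <- membrane_current_v0_limit(g, 40, clo)
    expect_equal(membrane_current(g, v_small, 40, clo), lim,
                 tolerance = 1e-4)
  }
  expect_identical(membrane_current_v0_limit(0, 40, clo), 0)
  expect_identical(membrane_current_v0_limit(g, clo, clo), 0)
})

test_that("the voltage-step worked example reproduces the reference current", {
  tis <- default_tissue()
  pre <- pathway_state(12.87e-6, 360e-6, -0.04)
  post <- pathway_state(12.87e-6, 360e-6, -0.07)
  i0 <- instantaneous_current(pre, post, tis, i_a0 = 0.08)
  # model-sign value printed in the worked example: -0.5418 uA/cm^2
  expect_equal(secretion_positive(i0), -0.5418, tolerance = 1e-3)
  expect_equal(i0 / 0.08, 6.8, tolerance = 1e-2)
})

test_that("current-to-flux conversion makes secretory currents positive effluxes", {
  expect_equal(current_to_molar_flux(-0.0965), 1.0e-6, tolerance = 1e-3)
  expect_identical(current_to_molar_flux(0), 0)
  expect_gt(current_to_molar_flux(-1e-6), 0)
  # secretion_positive is the involutive sign flip
  expect_identical(secretion_positive(secretion_positive(-2.5)), -2.5)
})

test_that("two-state transporter kinetics follow the closed form and conserve the pool", {
  tp <- transporter_params(ct_total = 3, alpha = 0.02, beta = 0.03,
                           flux_per_unit = 1e-11)
  ct_inf <- 0.02 * 3 / 0.05
  expect_equal(transporter_timecourse(tp, 0.5, Inf), ct_inf)
  # at t = tau2 the pool has moved 1 - 1/e of the way
  tau2 <- 1 / 0.05
  expect_equal(transporter_timecourse(tp, 0.5, tau2),
               ct_inf + (0.5 - ct_inf) / exp(1))
  # pure decay when activation is off
  tp0 <- transporter_params(3, alpha = 0, beta = 0.03, flux_per_unit = 0)
  tt <- c(0, 10, 50, 200)
  expect_equal(transporter_timecourse(tp0, 3, tt), 3 * exp(-0.03 * tt))
  # conservation: the inactive pool follows the mirrored kinetics exactly
  tp_sw <- transporter_params(3, alpha = 0.03, beta = 0.02,
                              flux_per_unit = 1e-11)
  expect_equal(3 - transporter_timecourse(tp, 0.5, tt),
               transporter_timecourse(tp_sw, 3 - 0.5, tt))
  expect_error(transporter_timecourse(tp, 5, 1),
               class = "clsecretion_invalid_input")
  # uptake flux is linear in the active pool
  expect_identical(uptake_flux(tp, 0), 0)
  expect_equal(uptake_flux(tp, 2), 2 * uptake_flux(tp, 1))
})

test_that("tau1 follows the analytic expression and its proportionalities", {
  tis <- default_tissue()
  st <- pathway_state(12.87e-6, 360e-6, -0.04)
  # plug-in oracle: direct arithmetic with the package constants
  f <- physical_constants()$faraday
  expected <- 5e-10 * f * (EU40 - 1) * 127.5 / (-0.04 * 372.87e-6)
  expect_equal(tau_cl(tis, st), expected, tolerance = 1e-12)
  expect_gt(tau_cl(tis, st), 0)
  # positive for depolarized potentials too
  expect_gt(tau_cl(tis, pathway_state(1e-6, 1e-6, 0.03)), 0)
  # proportional to cell volume, inverse in total conductance
  withr::with_seed(7, {
    for (k in 1:20) {
      ga <- runif(1, 1e-6, 1e-4); gb <- runif(1, 1e-6, 1e-3)
      v <- runif(1, -0.09, -0.005)
      cv <- runif(1, 1e-10, 1e-9)
      t1 <- tissue_params(cell_volume = cv)
      t2 <- tissue_params(cell_volume = 2 * cv)
      s1 <- pathway_state(ga, gb, v)
      s2 <- pathway_state(2 * ga, 2 * gb, v)
      expect_equal(tau_cl(t2, s1), 2 * tau_cl(t1, s1))
      expect_equal(tau_cl(t1, s2), tau_cl(t1, s1) / 2)
    }
  })
  expect_error(tau_cl(tis, pathway_state(1e-6, 1e-6, 0)),
               class = "clsecretion_invalid_input")
})

test_that("steady-state chloride balances the fluxes and sits above equilibrium", {
  tis <- default_tissue()
  st <- pathway_state(12.87e-6, 360e-6, -0.04)
  expect_equal(steady_state_cl(tis, st, 0), cl_equilibrium(127.5, -0.04))
  # baseline implied by I_A0 = 0.08 uA/cm^2 over 0.33 cm^2
  j_c0 <- (1 + 360 / 12.87) * current_to_molar_flux(-0.08e-6 * 0.33)
  f_inf <- steady_state_cl(tis, st, j_c0)
  expect_equal(f_inf, 32, tolerance = 2e-2)
  # flux balance at the fixed point
  j_out <- current_to_molar_flux(membrane_current(12.87e-6, -0.04, f_inf, 127.5)) +
    current_to_molar_flux(membrane_current(360e-6, -0.04, f_inf, 127.5))
  expect_equal(j_out, j_c0, tolerance = 1e-10)
  # more basolateral back-flux lowers the steady concentration
  st2 <- pathway_state(12.87e-6, 720e-6, -0.04)
  expect_lt(steady_state_cl(tis, st2, j_c0), f_inf)
  expect_error(steady_state_cl(tis, st, -1e-12),
               class = "clsecretion_invalid_input")
})

test_that("steady-state current ratio reproduces the reference fold-changes", {
  expect_equal(steady_state_current_ratio(20, 1, 30), 12.4)
  expect_equal(steady_state_current_ratio(2.5, 1.5, 30), 77.5 / 47.5)
  expect_equal(steady_state_current_ratio(18, 18, 30), 1)
  expect_equal(steady_state_current_ratio(1, 2, 30), 31 / 61)
  expect_equal(steady_state_current_ratio(1, 1, 30, jc_rel = 2), 2)
  # identity when all relative changes match
  expect_equal(steady_state_current_ratio(3, 3, 12.3), 1)
  expect_error(steady_state_current_ratio(0, 1, 30),
               class = "clsecretion_invalid_input")
})

test_that("instantaneous current tracks the apical conductance only", {
  tis <- default_tissue()
  pre <- pathway_state(12.87e-6, 30 * 12.87e-6, -0.04)
  mk <- function(ga_rel, gb_rel) pathway_state(
    ga_rel * 12.87e-6, gb_rel * 30 * 12.87e-6, -0.04)
  expect_equal(instantaneous_current(pre, mk(20, 1), tis, 0.08), 20 * 0.08)
  expect_equal(instantaneous_current(pre, mk(5, 4), tis, 0.08), 5 * 0.08)
  # invariant to G_B at fixed V (property over draws)
  withr::with_seed(11, {
    for (k in 1:10) {
      ga_rel <- runif(1, 0.5, 40); gb_rel <- runif(1, 0.1, 40)
      expect_equal(instantaneous_current(pre, mk(ga_rel, gb_rel), tis, 0.08),
                   ga_rel * 0.08, tolerance = 1e-12)
    }
  })
  expect_error(instantaneous_current(pre, mk(2, 1), tis, 0),
               class = "clsecretion_invalid_input")
})
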