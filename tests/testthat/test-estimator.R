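test_that("Ohm's-law conductance from pulse deflections", {
  expect_equal(conductance_from_pulse(1) * 1e6, 1000)
  expect_equal(conductance_from_pulse(2) * 1e6, 500)
  # inversion of the measured basal apical conductance
  expect_equal(conductance_from_pulse(1 / 0.01287) * 1e6, 12.87,
               tolerance = 1e-12)
  expect_error(conductance_from_pulse(0), class = "clsecretion_invalid_input")
  expect_error(conductance_from_pulse(-1), class = "clsecretion_invalid_input")
})

test_that("pulse deflections are recovered from synthetic recordings", {
  # noiseless square deflections come back exactly
  rec <- generate_pulse_recording(g_true = 0.5e-3, n_pulses = 5)
  d <- extract_pulse_deflections(rec)
  expect_equal(nrow(d), 5)
  expect_equal(d$delta_pd_mV, rep(2, 5))
  # noisy recording: mean deflection within the analytic standard error
  sigma <- 0.05
  recn <- generate_pulse_recording(g_true = 0.5e-3, n_pulses = 30,
                                   noise_sd = sigma, seed = 21, dt = 0.02)
  dn <- extract_pulse_deflections(recn, baseline_window = 2,
                                  plateau_window = 0.25)
  m_base <- 2 / 0.02          # samples per baseline window
  m_plat <- 0.25 / 0.02       # samples per plateau window
  se <- sigma * sqrt(1 / m_base + 1 / m_plat) / sqrt(30)
  expect_lt(abs(mean(dn$delta_pd_mV) - 2), 3 * se)
  # window validation
  expect_error(extract_pulse_deflections(recn, baseline_window = 11),
               class = "clsecretion_invalid_input")
  expect_error(extract_pulse_deflections(recn, plateau_window = 1),
               class = "clsecretion_invalid_input")
})

test_that("blocker-sensitive conductance differencing", {
  expect_equal(nppb_sensitive_conductance(1000e-6, 640e-6) * 1e6, 360)
  expect_identical(nppb_sensitive_conductance(5e-4, 5e-4), 0)
  expect_error(nppb_sensitive_conductance(500e-6, 600e-6),
               class = "clsecretion_invalid_input")
})

test_that("transporter activation from the reference measurement set", {
  m <- tibble::as_tibble(ussing_measurement_example())
  act <- estimate_quiet(m)$activation
  expect_equal(act, 4.6867, tolerance = 1e-4)
  expect_gt(act, 4.6); expect_lt(act, 4.8)
  # identity measurement returns exactly 1
  ident <- tibble::tibble(i_a0 = 0.08, i_a_inf = 0.08, g_a0 = 12.87,
                          g_b0 = 360, g_a_inf = 12.87, g_b_inf = 360)
  expect_equal(estimate_quiet(ident)$activation, 1)
  # either sign convention gives the same magnitude
  m_neg <- dplyr::mutate(m, i_a0 = -i_a0, i_a_inf = -i_a_inf)
  expect_equal(estimate_quiet(m_neg)$activation, act)
  expect_message(estimate_transporter_activation(m),
                 class = "clsecretion_sign_convention")
  # invariant violations
  expect_error(estimate_quiet(dplyr::mutate(m, g_a0 = 0)),
               class = "clsecretion_invalid_input")
  expect_error(estimate_quiet(dplyr::select(m, -g_b0)),
               class = "clsecretion_invalid_input")
})

test_that("the estimator is the exact inverse of the forward model", {
  tis <- default_tissue()
  # canned scenario with programmed uptake fold-change 3
  m <- scenario_measurement("genistein", tis)
  expect_equal(estimate_quiet(m)$activation, 3, tolerance = 1e-10)
  # conductance-only scenarios invert to exactly 1
  expect_equal(estimate_quiet(scenario_measurement("forskolin_pki", tis))$activation,
               1, tolerance = 1e-10)
  # property: random V-fixed protocols over seeded draws
  withr::with_seed(31, {
    for (k in 1:20) {
      prot <- random_protocol(tis)
      jc_rel <- prot$j_c_inf / prot$j_c0
      f0 <- steady_state_cl(tis, prot$pre_state, prot$j_c0)
      f_inf <- steady_state_cl(tis, prot$post_state, prot$j_c_inf)
      m <- tibble::tibble(
        i_a0 = -membrane_current(prot$pre_state$g_apical,
                                 prot$pre_state$v_membrane, f0, tis$cl_out),
        i_a_inf = -membrane_current(prot$post_state$g_apical,
                                    prot$post_state$v_membrane, f_inf,
                                    tis$cl_out),
        g_a0 = prot$pre_state$g_apical, g_b0 = prot$pre_state$g_basolateral,
        g_a_inf = prot$post_state$g_apical,
        g_b_inf = prot$post_state$g_basolateral)
      expect_equal(estimate_quiet(m)$activation, jc_rel, tolerance = 1e-10)
    }
  })
})

test_that("biexponential fitting recovers programmed components", {
  tis <- default_tissue()
  # single-exponential trace: second component collapses to zero
  tr1 <- analytic_solution(tis, build_scenario("forskolin_pki", tis), n = 300)
  fit1 <- fit_biexponential(tr1)
  cf1 <- coef(fit1)
  expect_true(fit1$converged)
  expect_equal(cf1[["A2"]], 0)
  expect_equal(cf1[["tau1"]], attr(tr1, "tau1"), tolerance = 1e-3)
  expect_equal(cf1[["y_inf"]], attr(tr1, "i_a_inf"), tolerance = 1e-6)
  # biexponential trace with tau2 = 10 tau1: both recovered
  tr2 <- analytic_solution(tis, build_scenario("genistein", tis), n = 600)
  fit2 <- fit_biexponential(tr2)
  cf2 <- coef(fit2)
  expect_equal(fit2$n_components, 2)
  expect_equal(cf2[["tau1"]], attr(tr2, "tau1"), tolerance = 5e-3)
  expect_equal(cf2[["tau2"]], attr(tr2, "tau2"), tolerance = 5e-3)
  expect_lt(cf2[["tau1"]], cf2[["tau2"]])
  # constant trace
  const <- tibble::tibble(time_s = seq(0, 100, length.out = 20),
                          i_apical_uApercm2 = 3.2)
  fitc <- fit_biexponential(const)
  expect_equal(coef(fitc)[["y_inf"]], 3.2)
  expect_identical(coef(fitc)[["A1"]], 0)
  expect_identical(coef(fitc)[["A2"]], 0)
  # interface contracts
  expect_error(fit_biexponential(const[1:5, ]),
               class = "clsecretion_invalid_input")
  expect_named(tidy(fit2), c("term", "estimate"))
  expect_equal(glance(fit2)$n_components, 2)
  expect_true(glance(fit2)$converged)
})
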