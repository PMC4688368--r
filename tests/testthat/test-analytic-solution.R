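test_that("with constant uptake the solution is a single exponential in tau1", {
  tis <- default_tissue()
  prot <- build_scenario("forskolin_pki", tis)
  tau1 <- tau_cl(tis, prot$post_state)
  # sample while the relaxation is still well above rounding noise
  tr <- analytic_solution(tis, prot, t = seq(0, 5 * tau1, length.out = 120))
  post <- tr[tr$epoch == "post", ]
  f_inf <- attr(tr, "cl_inf")
  resid <- post$cl_in_mM - f_inf
  # log-residuals decay linearly with slope -1/tau1
  ratio <- resid[-1] / resid[-nrow(post)]
  dt <- diff(post$time_s)
  expect_equal(ratio, exp(-dt / tau1), tolerance = 1e-9)
  # f(0) is the pre-stimulus steady state
  expect_equal(post$cl_in_mM[1], attr(tr, "cl0"))
})

test_that("the solution starts at the pre-epoch steady state and represents the jump", {
  tis <- default_tissue()
  prot <- build_scenario("daidzein", tis)
  tr <- analytic_solution(tis, prot)
  pre <- tr[tr$epoch == "pre", ]
  post <- tr[tr$epoch == "post", ]
  # 0- and 0+ samples present: same concentration, jumped current
  expect_equal(max(pre$time_s), 0)
  expect_equal(min(post$time_s), 0)
  expect_equal(pre$cl_in_mM[nrow(pre)], post$cl_in_mM[1])
  expect_equal(post$i_apical_uApercm2[1] / pre$i_apical_uApercm2[nrow(pre)],
               18, tolerance = 1e-9)
  # concentrations stay positive and the trace columns are consistent
  expect_true(all(tr$cl_in_mM > 0))
  expect_true(all(diff(post$time_s) > 0))
})

test_that("uptake kinetics make the trace biphasic with the slow rise in tau2", {
  tis <- default_tissue()
  prot <- build_scenario("genistein", tis)
  tr <- analytic_solution(tis, prot, n = 2000)
  post <- tr[tr$epoch == "post", ]
  y <- post$i_apical_uApercm2
  i_min <- which.min(y)
  # jump up, dip, then rise toward the steady level
  expect_gt(i_min, 1)
  expect_lt(i_min, nrow(post))
  expect_lt(y[i_min], y[1])
  expect_gt(tail(y, 1), y[i_min])
  # steady level matches the closed-form ratio (horizon = 20 * max tau)
  summ <- scenario_summary(prot, tis)
  expect_equal(tail(y, 1) / attr(tr, "i_a0"), summ$fold_steady,
               tolerance = 1e-6)
  expect_equal(summ$fold_steady,
               steady_state_current_ratio(5, 4, 30, jc_rel = 3),
               tolerance = 1e-12)
})

test_that("at steady states the conductive currents balance the uptake current", {
  tis <- default_tissue()
  for (nm in c("forskolin_pki", "apigenin", "voltage_step")) {
    tr <- analytic_solution(tis, build_scenario(nm, tis))
    last <- tr[nrow(tr), ]
    expect_equal(last$i_apical_uApercm2 + last$i_basolateral_uApercm2,
                 last$i_uptake_uApercm2, tolerance = 1e-6)
    first <- tr[1, ]   # pre-stimulus steady state
    expect_equal(first$i_apical_uApercm2 + first$i_basolateral_uApercm2,
                 first$i_uptake_uApercm2, tolerance = 1e-10)
  }
})

test_that("the degenerate tau1 = tau2 case switches to the confluent form", {
  tis <- default_tissue()
  pre <- pathway_state(12.87e-6, 386.1e-6, -0.04)
  post <- pathway_state(2 * 12.87e-6, 386.1e-6, -0.04)
  tau1 <- tau_cl(tis, post)
  j_c0 <- 8e-12
  prot_eq <- step_protocol(pre, post, j_c0, j_c_inf = 2 * j_c0,
                           tau2 = tau1, horizon = 20 * tau1)
  expect_message(tr_eq <- analytic_solution(tis, prot_eq, n = 400),
                 class = "clsecretion_confluent")
  # continuity against a barely non-degenerate protocol
  prot_near <- step_protocol(pre, post, j_c0, j_c_inf = 2 * j_c0,
                             tau2 = tau1 * (1 + 1e-7), horizon = 20 * tau1)
  tr_near <- analytic_solution(tis, prot_near, n = 400)
  expect_equal(tr_eq$cl_in_mM, tr_near$cl_in_mM, tolerance = 1e-6)
})

test_that("steady_level extracts settled tails and flags drifting ones", {
  tis <- default_tissue()
  tr <- analytic_solution(tis, build_scenario("apigenin", tis))
  lvl <- steady_level(tr)
  expect_equal(lvl / attr(tr, "i_a0"), 2, tolerance = 1e-3)
  # truncated horizon has not settled: the slope check fires
  prot_short <- build_scenario("apigenin", tis)
  prot_short$horizon <- attr(tr, "tau2")
  tr_short <- analytic_solution(tis, prot_short)
  expect_warning(steady_level(tr_short), "steady")
})
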