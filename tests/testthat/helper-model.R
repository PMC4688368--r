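# Shared fixtures: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

default_tissue <- function() tissue_params()

# reference Boltzmann factors at the default temperature
EU40 <- boltzmann_factor(-0.04)
EU70 <- boltzmann_factor(-0.07)

# a random but valid step protocol (V fixed across the step), for property
# tests; all draws flow from the caller's seed
random_protocol <- function(tissue = default_tissue()) {
  g_a0 <- runif(1, 5e-6, 50e-6)
  r <- runif(1, 5, 50)
  v <- -runif(1, 0.01, 0.08)
  ga_rel <- runif(1, 0.5, 30)
  gb_rel <- runif(1, 0.5, 10)
  jc_rel <- runif(1, 0.5, 5)
  pre <- pathway_state(g_a0, r * g_a0, v)
  post <- pathway_state(ga_rel * g_a0, gb_rel * r * g_a0, v)
  j_c0 <- runif(1, 1e-12, 5e-11)
  tau1 <- tau_cl(tissue, post)
  tau2 <- if (jc_rel == 1) NULL else runif(1, 3, 30) * tau1
  step_protocol(pre, post, j_c0 = j_c0, j_c_inf = jc_rel * j_c0,
                tau2 = tau2, horizon = 20 * max(tau1, tau2 %||% 0))
}

# exact steady-state measurement set implied by a scenario's closed form,
# in the shape the activation estimator consumes
scenario_measurement <- function(name, tissue = default_tissue(), ...) {
  prot <- build_scenario(name, tissue, ...)
  summ <- scenario_summary(prot, tissue)
  tibble::tibble(
    i_a0 = summ$i_a0_uApercm2,
    i_a_inf = summ$i_a_inf_uApercm2,
    g_a0 = prot$pre_state$g_apical * 1e6,
    g_b0 = prot$pre_state$g_basolateral * 1e6,
    g_a_inf = prot$post_state$g_apical * 1e6,
    g_b_inf = prot$post_state$g_basolateral * 1e6)
}

estimate_quiet <- function(...) {
  suppressMessages(estimate_transporter_activation(...))
}
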