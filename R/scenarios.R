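# Canned stimulation scenarios. Fold-changes follow the reference simulation
# conventions: baseline apical conductance 12.87 uS (the measured basal
# value), stylized baseline ratio G_B0 = 30*G_A0 except `forskolin_full`,
# which uses the measured ratio 360.00/12.87, and baseline apical current
# 0.08 uA/cm^2 (secretion positive). The forskolin_full uptake fold-change is
# the value the steady-state inversion returns for the measured conductances
# and currents (about 4.69).
scenario_catalog <- function() {
  meas <- ussing_reference_values()
  act <- with(meas, (i_a_inf * (g_a_inf + g_b_inf) / g_a_inf) /
                (i_a0 * (g_a0 + g_b0) / g_a0))
  tibble(
    name = c("forskolin_pki", "acetylcholine_like", "daidzein",
             "basolateral_only", "voltage_step", "apigenin", "genistein",
             "forskolin_full"),
    ga_rel = c(20, 2.5, 18, 1, 1, 1, 5, 50),
    gb_rel = c(1, 1.5, 18, 2, 1, 1, 4, 1.33),
    jc_rel = c(1, 1, 1, 1, 1, 2, 3, act),
    gb0_over_ga0 = c(30, 30, 30, 30, 30, 30, 30,
                     meas$g_b0 / meas$g_a0),
    v0 = -0.04,
    v = c(-0.04, -0.04, -0.04, -0.04, -0.07, -0.04, -0.04, -0.04),
    description = c(
      "cAMP agonist with PKA inhibited: apical conductance x20 only",
      "cholinergic-like: apical x2.5, basolateral x1.5",
      "both conductances x18: purely transient secretion",
      "basolateral conductance doubles: secretion halves",
      "potential step -40 to -70 mV, conductances and uptake fixed",
      "uptake doubles (transporter activation), conductances fixed",
      "apical x5, basolateral x4, uptake eventually x3: biphasic",
      "full cAMP response: apical x50, basolateral x1.33, uptake x4.7"))
}

# the six reference steady-state measurables (uA/cm^2 and uS) from a
# forskolin-stimulated A6 monolayer; used as the package-wide worked example
ussing_reference_values <- function() {
  list(i_a0 = 0.08, i_a_inf = 6.40,
       g_a0 = 12.87, g_b0 = 360.00, g_a_inf = 689.04, g_b_inf = 480.47)
}

#' List the canned stimulation scenarios
#'
#' @return A tibble with one row per scenario: `name`, the relative
#'   conductance/uptake changes, the baseline conductance ratio, the pre- and
#'   post-step membrane potentials (mV) and a one-line description.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  dplyr::mutate(scenario_catalog(),
                v0_mV = .data$v0 * 1e3, v_mV = .data$v * 1e3,
                v0 = NULL, v = NULL)
}

#' Build a canned stimulation protocol
#'
#' Returns a fully parameterized [step_protocol()] for one of the canned
#' scenarios (see [list_scenarios()]). The baseline is scaled physically:
#' apical conductance `g_a0`, baseline apical current `i_a0` (secretion
#' positive) and the scenario's baseline conductance ratio fix the baseline
#' intracellular chloride and uptake flux; the scenario's fold-changes then
#' define the post-stimulus epoch. Scenarios that change the uptake flux
#' relax it with `tau2`, by default ten times the post-stimulus chloride
#' relaxation time (the model regime has `tau2 >> tau1`).
#'
#' @param name Scenario name; one of `"forskolin_pki"`,
#'   `"acetylcholine_like"`, `"daidzein"`, `"basolateral_only"`,
#'   `"voltage_step"`, `"apigenin"`, `"genistein"`, `"forskolin_full"`.
#' @param tissue A [tissue_params()] object.
#' @param i_a0 Baseline apical current (uA/cm^2, secretion positive).
#' @param g_a0 Baseline apical conductance (S, whole tissue).
#' @param tau2 Transporter relaxation time (s); default `10 * tau1` of the
#'   post-stimulus state for scenarios with uptake kinetics.
#' @param horizon Simulation end time (s); default `20 * max(tau1, tau2)`.
#' @return A [step_protocol()] object.
#' @examples
#' build_scenario("daidzein", tissue_params())
#' @export
build_scenario <- function(name, tissue = tissue_params(), i_a0 = 0.08,
                           g_a0 = 12.87e-6, tau2 = NULL, horizon = NULL) {
  catalog <- scenario_catalog()
  if (!is.character(name) || length(name) != 1L || !name %in% catalog$name) {
    abort_config(sprintf(
      "Unknown scenario %s. Valid names: %s.",
      if (is.character(name) && length(name) == 1L) paste0("'", name, "'")
      else "(non-string)",
      paste(catalog$name, collapse = ", ")))
  }
  sc <- as.list(catalog[catalog$name == name, ])
  check_number(i_a0, "i_a0"); check_number(g_a0, "g_a0")
  if (i_a0 <= 0 || g_a0 <= 0) {
    abort_invalid("`i_a0` and `g_a0` must be > 0.")
  }

  g_b0 <- sc$gb0_over_ga0 * g_a0
  pre <- pathway_state(g_a0, g_b0, sc$v0)
  post <- pathway_state(sc$ga_rel * g_a0, sc$gb_rel * g_b0, sc$v)

  # baseline flux balance: J_C0 = J_A0 + J_B0 = (1 + G_B0/G_A0) * (-I_A0)/F
  i_a0_amp <- secretion_positive(i_a0) * 1e-6 * tissue$area
  j_c0 <- (1 + sc$gb0_over_ga0) * current_to_molar_flux(i_a0_amp)

  tau1_post <- tau_cl(tissue, post)
  if (sc$jc_rel != 1 && is.null(tau2)) tau2 <- 10 * tau1_post
  if (is.null(horizon)) horizon <- 20 * max(tau1_post, tau2 %||% 0)

  step_protocol(pre, post, j_c0 = j_c0, j_c_inf = sc$jc_rel * j_c0,
                tau2 = tau2, horizon = horizon, name = name)
}

#' Summarize a step protocol
#'
#' Deterministic summary of a protocol's closed-form solution: instantaneous
#' and steady-state apical current fold-changes, both time constants, and the
#' initial/steady intracellular chloride and apical currents.
#'
#' @param protocol A [step_protocol()] object.
#' @param tissue A [tissue_params()] object.
#' @return A one-row tibble with columns `name`, `fold_initial`,
#'   `fold_steady`, `tau1_pre_s`, `tau1_post_s`, `tau2_s`, `cl0_mM`,
#'   `cl_inf_mM`, `i_a0_uApercm2`, `i_a_inf_uApercm2`.
#' @examples
#' scenario_summary(build_scenario("forskolin_pki"), tissue_params())
#' @export
scenario_summary <- function(protocol, tissue = tissue_params()) {
  stopifnot(inherits(protocol, "step_protocol"),
            inherits(tissue, "tissue_params"))
  f0 <- steady_state_cl(tissue, protocol$pre_state, protocol$j_c0)
  f_inf <- steady_state_cl(tissue, protocol$post_state, protocol$j_c_inf)
  cur <- function(state, cl) chord_current(
    state$g_apical, state$v_membrane, cl, tissue$cl_out, tissue$temperature)
  per_area <- function(i) secretion_positive(i) / tissue$area * 1e6
  i_a0 <- cur(protocol$pre_state, f0)
  i_inst <- cur(protocol$post_state, f0)   # [Cl-]i continuous at the step
  i_inf <- cur(protocol$post_state, f_inf)
  tibble(
    name = protocol$name %||% NA_character_,
    fold_initial = i_inst / i_a0,
    fold_steady = i_inf / i_a0,
    tau1_pre_s = tau_cl(tissue, protocol$pre_state),
    tau1_post_s = tau_cl(tissue, protocol$post_state),
    tau2_s = protocol$tau2 %||% NA_real_,
    cl0_mM = f0, cl_inf_mM = f_inf,
    i_a0_uApercm2 = per_area(i_a0),
    i_a_inf_uApercm2 = per_area(i_inf))
}
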