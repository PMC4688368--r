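#' Tissue-scale parameters of the secreting epithelium
#'
#' Physical scale of the preparation: the aggregate volume of the secreting
#' cell mass, the tissue area over which whole-tissue conductances were
#' measured, the bath chloride concentration (identical on both sides under
#' short-circuit conditions) and the absolute temperature.
#'
#' Defaults describe a confluent A6 (amphibian renal) monolayer on a 0.33 cm^2
#' permeable support bathed in an amphibian Ringer-type solution at 24-25 C:
#' total cell volume about 5.0e-10 m^3 and bath chloride 127.5 mM.
#'
#' @param cell_volume Volume of the secreting cell mass (m^3). Must be > 0.
#' @param area Tissue area (cm^2) used to express currents per cm^2.
#' @param cl_out Extracellular (bath) chloride concentration (mM, numerically
#'   identical to mol/m^3). Must be > 0.
#' @param temperature Absolute temperature (K); accepted within the
#'   physiological band 270-330 K.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params()
#' @export
tissue_params <- function(cell_volume = 5e-10, area = 0.33,
                          cl_out = .DEFAULT_CL_OUT,
                          temperature = .DEFAULT_TEMPERATURE) {
  check_number(cell_volume, "cell_volume")
  check_number(area, "area")
  check_number(cl_out, "cl_out")
  check_number(temperature, "temperature")
  if (cell_volume <= 0 || area <= 0 || cl_out <= 0 || temperature <= 0) {
    abort_invalid("All tissue parameters must be strictly positive.")
  }
  if (temperature < 270 || temperature > 330) {
    abort_invalid(sprintf(
      "`temperature` = %.1f K is outside the physiological band [270, 330] K.",
      temperature))
  }
  structure(
    list(cell_volume = cell_volume, area = area, cl_out = cl_out,
         temperature = temperature),
    class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>\n")
  cat(sprintf("  cell volume : %.3g m^3\n", x$cell_volume))
  cat(sprintf("  area        : %.3g cm^2\n", x$area))
  cat(sprintf("  bath [Cl-]  : %.4g mM\n", x$cl_out))
  cat(sprintf("  temperature : %.1f K\n", x$temperature))
  invisible(x)
}

#' Conductive pathway state of the two membranes
#'
#' Whole-tissue apical and basolateral chloride conductances together with the
#' membrane potential (intracellular minus extracellular). Under short-circuit
#' conditions, with identical solutions on both sides and the transepithelial
#' potential clamped to zero, a single membrane potential applies to both
#' membranes; it is a protocol parameter here, not solved from charge balance.
#'
#' @param g_apical Apical chloride conductance (S, whole tissue), >= 0.
#' @param g_basolateral Basolateral chloride conductance (S, whole tissue),
#'   >= 0. The two conductances may not both be zero.
#' @param v_membrane Membrane potential (V), negative in a resting epithelium.
#'   A value of exactly zero is admitted at construction; the chord-form
#'   current then goes through its analytic limit ([membrane_current_v0_limit()]).
#' @return An object of class `pathway_state`.
#' @examples
#' pathway_state(g_apical = 12.87e-6, g_basolateral = 360e-6, v_membrane = -0.04)
#' @export
pathway_state <- function(g_apical, g_basolateral, v_membrane) {
  check_number(g_apical, "g_apical")
  check_number(g_basolateral, "g_basolateral")
  check_number(v_membrane, "v_membrane")
  if (g_apical < 0 || g_basolateral < 0) {
    abort_invalid("Conductances must be non-negative.")
  }
  if (g_apical + g_basolateral <= 0) {
    abort_invalid("At least one of `g_apical`, `g_basolateral` must be positive.")
  }
  structure(
    list(g_apical = g_apical, g_basolateral = g_basolateral,
         v_membrane = v_membrane),
    class = "pathway_state")
}

#' @export
print.pathway_state <- function(x, ...) {
  cat("<pathway_state>\n")
  cat(sprintf("  G_apical      : %.4g uS\n", x$g_apical * 1e6))
  cat(sprintf("  G_basolateral : %.4g uS\n", x$g_basolateral * 1e6))
  cat(sprintf("  V_membrane    : %.4g mV\n", x$v_membrane * 1e3))
  invisible(x)
}

#' Two-state kinetics of the electro-neutral chloride transporter
#'
#' The basolateral uptake transporter (NKCC1 archetype) interconverts between
#' an inactive and an active form with first-order rate constants `alpha`
#' (activation) and `beta` (inactivation); each unit of active transporter
#' carries a fixed chloride flux. The model deliberately makes the uptake flux
#' independent of intracellular chloride and of the membrane potential: the
#' transporter is electro-neutral and its dominant driving force (the sodium
#' electrochemical gradient) is treated as constant.
#'
#' @param ct_total Total transporter amount (arbitrary amount unit), > 0.
#' @param alpha Activation rate constant, inactive -> active (s^-1), >= 0.
#' @param beta Inactivation rate constant, active -> inactive (s^-1), >= 0.
#' @param flux_per_unit Chloride uptake flux per unit of active transporter
#'   (mol s^-1 per amount unit), >= 0.
#' @return An object of class `transporter_params`.
#' @examples
#' transporter_params(ct_total = 1, alpha = 0.02, beta = 0.01,
#'                    flux_per_unit = 1e-11)
#' @export
transporter_params <- function(ct_total, alpha, beta, flux_per_unit) {
  check_number(ct_total, "ct_total")
  check_number(alpha, "alpha")
  check_number(beta, "beta")
  check_number(flux_per_unit, "flux_per_unit")
  if (ct_total <= 0) abort_invalid("`ct_total` must be > 0.")
  if (alpha < 0 || beta < 0) abort_invalid("Rate constants must be >= 0.")
  if (flux_per_unit < 0) abort_invalid("`flux_per_unit` must be >= 0.")
  structure(
    list(ct_total = ct_total, alpha = alpha, beta = beta,
         flux_per_unit = flux_per_unit),
    class = "transporter_params")
}

#' Step-stimulation protocol
#'
#' A pre-stimulus epoch at steady state followed, at t = 0, by a step change
#' in the conductive pathway state and (optionally) a relaxation of the
#' electro-neutral uptake flux toward a new level with time constant `tau2`.
#' Uptake is parameterized directly by fluxes: `j_c0` is the pre-stimulus
#' steady uptake (which also sets the uptake at t = 0+, the transporter pool
#' being continuous across the step), and `j_c_inf` the post-stimulus steady
#' uptake approached as `exp(-t/tau2)`. Use [transporter_protocol()] to build
#' the same object from explicit two-state transporter kinetics.
#'
#' @param pre_state,post_state [pathway_state()] objects before and after the
#'   step.
#' @param j_c0 Pre-stimulus steady uptake flux (mol/s), >= 0.
#' @param j_c_inf Post-stimulus steady uptake flux (mol/s); defaults to
#'   `j_c0` (uptake unchanged by the stimulus).
#' @param tau2 Relaxation time constant of the uptake flux (s), equal to
#'   1/(alpha + beta) of the underlying two-state kinetics. Required when
#'   `j_c_inf != j_c0`.
#' @param horizon Simulation end time (s), > 0.
#' @param name Optional label (e.g. the scenario name).
#' @return An object of class `step_protocol`.
#' @examples
#' pre <- pathway_state(12.87e-6, 30 * 12.87e-6, -0.04)
#' post <- pathway_state(20 * 12.87e-6, 30 * 12.87e-6, -0.04)
#' step_protocol(pre, post, j_c0 = 8.5e-12, horizon = 1800)
#' @export
step_protocol <- function(pre_state, post_state, j_c0, j_c_inf = j_c0,
                          tau2 = NULL, horizon, name = NULL) {
  if (!inherits(pre_state, "pathway_state") ||
      !inherits(post_state, "pathway_state")) {
    abort_invalid("`pre_state` and `post_state` must be `pathway_state` objects.")
  }
  check_number(j_c0, "j_c0")
  check_number(j_c_inf, "j_c_inf")
  check_number(horizon, "horizon")
  if (j_c0 < 0 || j_c_inf < 0) abort_invalid("Uptake fluxes must be >= 0.")
  if (horizon <= 0) abort_invalid("`horizon` must be > 0.")
  if (!is.null(tau2)) {
    check_number(tau2, "tau2")
    if (tau2 <= 0) abort_invalid("`tau2` must be > 0.")
  }
  if (j_c_inf != j_c0 && is.null(tau2)) {
    abort_invalid("`tau2` is required when the uptake flux changes (j_c_inf != j_c0).")
  }
  structure(
    list(pre_state = pre_state, post_state = post_state,
         j_c0 = j_c0, j_c_inf = j_c_inf, tau2 = tau2,
         step_time = 0, horizon = horizon, name = name),
    class = "step_protocol")
}

#' Build a step protocol from explicit transporter kinetics
#'
#' The pre-stimulus transporter pool is initialized at its own fixed point
#' `CT_Act(0) = alpha_pre * CT_T / (alpha_pre + beta_pre)`; at t = 0 the rate
#' constants switch to their post-stimulus values and the active pool relaxes
#' toward `alpha_post * CT_T / (alpha_post + beta_post)` with
#' `tau2 = 1/(alpha_post + beta_post)`. The per-unit flux of the post-stimulus
#' kinetics applies from t = 0+.
#'
#' @inheritParams step_protocol
#' @param transporter_pre,transporter_post [transporter_params()] objects
#'   before and after the step (same `ct_total`).
#' @return An object of class `step_protocol`.
#' @export
transporter_protocol <- function(pre_state, post_state, transporter_pre,
                                 transporter_post, horizon, name = NULL) {
  for (tp in list(transporter_pre, transporter_post)) {
    if (!inherits(tp, "transporter_params")) {
      abort_invalid("Transporter arguments must be `transporter_params` objects.")
    }
  }
  if (transporter_pre$alpha + transporter_pre$beta <= 0 ||
      transporter_post$alpha + transporter_post$beta <= 0) {
    abort_invalid("alpha + beta must be > 0 in both epochs to define steady states.")
  }
  ct0 <- with(transporter_pre, alpha * ct_total / (alpha + beta))
  ct_inf <- with(transporter_post, alpha * ct_total / (alpha + beta))
  j <- transporter_post$flux_per_unit
  out <- step_protocol(
    pre_state, post_state,
    j_c0 = transporter_pre$flux_per_unit * ct0,
    j_c_inf = j * ct_inf,
    tau2 = 1 / (transporter_post$alpha + transporter_post$beta),
    horizon = horizon, name = name)
  # uptake at t = 0+ uses the post-step per-unit flux on the continuous pool
  out$j_c_post0 <- j * ct0
  out$transporter_pre <- transporter_pre
  out$transporter_post <- transporter_post
  out
}

#' @export
print.step_protocol <- function(x, ...) {
  cat("<step_protocol>", if (!is.null(x$name)) paste0("  [", x$name, "]"), "\n")
  cat(sprintf("  pre : G_A = %.4g uS, G_B = %.4g uS, V = %.3g mV, J_C0 = %.3g mol/s\n",
              x$pre_state$g_apical * 1e6, x$pre_state$g_basolateral * 1e6,
              x$pre_state$v_membrane * 1e3, x$j_c0))
  cat(sprintf("  post: G_A = %.4g uS, G_B = %.4g uS, V = %.3g mV, J_Cinf = %.3g mol/s\n",
              x$post_state$g_apical * 1e6, x$post_state$g_basolateral * 1e6,
              x$post_state$v_membrane * 1e3, x$j_c_inf))
  if (!is.null(x$tau2)) cat(sprintf("  tau2: %.4g s\n", x$tau2))
  cat(sprintf("  horizon: %.4g s\n", x$horizon))
  invisible(x)
}

#' Numerical solver options
#'
#' Options for the stiff-capable integrator behind [integrate_protocol()].
#'
#' @param rel_tol,abs_tol Relative and absolute tolerances, each in
#'   (0, 1e-2].
#' @param max_step Maximum step size (s); `Inf` leaves it to the solver.
#' @param method Integration method name passed to [deSolve::ode()];
#'   the default `"lsoda"` switches automatically between stiff and
#'   non-stiff regimes.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(rel_tol = 1e-10, abs_tol = 1e-10,
                           max_step = Inf, method = "lsoda") {
  check_number(rel_tol, "rel_tol")
  check_number(abs_tol, "abs_tol")
  if (rel_tol <= 0 || rel_tol > 1e-2 || abs_tol <= 0 || abs_tol > 1e-2) {
    abort_invalid("Tolerances must lie in (0, 1e-2].")
  }
  check_number(max_step, "max_step", finite = FALSE)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 method = method),
            class = "solver_options")
}
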