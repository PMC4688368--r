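#' Boltzmann factor of the membrane potential
#'
#' Computes `exp(F*V/(R*T))`, the factor by which the passive chloride
#' distribution across a membrane at potential `V` deviates from symmetry.
#' At the reference temperature 297.8 K it evaluates to 0.2104 at -40 mV and
#' 0.0654 at -70 mV.
#'
#' @param v_membrane Membrane potential (V), intracellular minus
#'   extracellular. May be a vector.
#' @param temperature Absolute temperature (K), > 0.
#' @return `exp(F*V/(R*T))`, strictly positive; exactly 1 at `V = 0`.
#' @examples
#' boltzmann_factor(-0.04, 297.8)
#' @export
boltzmann_factor <- function(v_membrane, temperature = .DEFAULT_TEMPERATURE) {
  check_number(v_membrane, "v_membrane", allow_vector = TRUE)
  check_number(temperature, "temperature")
  if (temperature <= 0) abort_invalid("`temperature` must be > 0.")
  exp(.FARADAY * v_membrane / (.GAS * temperature))
}

#' Chloride equilibrium concentration
#'
#' The intracellular chloride concentration at which the passive membrane
#' current vanishes: `cl_out * exp(F*V/(R*T))`. Above this concentration a
#' chloride channel carries efflux, below it influx.
#'
#' @param cl_out Bath chloride concentration (mM), >= 0.
#' @inheritParams boltzmann_factor
#' @return Equilibrium intracellular chloride (mM).
#' @examples
#' cl_equilibrium(127.5, -0.04)
#' @export
cl_equilibrium <- function(cl_out, v_membrane,
                           temperature = .DEFAULT_TEMPERATURE) {
  check_number(cl_out, "cl_out", allow_vector = TRUE)
  if (any(cl_out < 0)) abort_invalid("`cl_out` must be >= 0.")
  cl_out * boltzmann_factor(v_membrane, temperature)
}

# Chord-form membrane chloride current (A). Internal: accepts V = 0 by
# switching to the analytic limit, vectorized over cl_in.
chord_current <- function(g, v_membrane, cl_in, cl_out, temperature) {
  if (v_membrane == 0) {
    return(-g * (.GAS * temperature / .FARADAY) * (cl_in - cl_out) / cl_out)
  }
  eu <- exp(.FARADAY * v_membrane / (.GAS * temperature))
  g * v_membrane * (cl_in - cl_out * eu) / (cl_out * (1 - eu))
}

#' Chord-conductance chloride current across one membrane
#'
#' The passive chloride current carried by a membrane of conductance `g` at
#' potential `V`, in the chord form
#' `I = G*V*(cl_in - cl_out*e^u) / (cl_out*(1 - e^u))` with
#' `e^u = exp(F*V/(R*T))`. The conductance multiplies a normalized driving
#' force that vanishes exactly at the chloride equilibrium concentration
#' ([cl_equilibrium()]), so `g` retains its measured (small-signal) value at
#' the reference state. The current follows the internal sign convention of
#' the model: a secretory (efflux) current is negative. User-facing traces
#' flip the sign once, via [secretion_positive()].
#'
#' @param g Membrane chloride conductance (S), >= 0.
#' @param v_membrane Membrane potential (V); must be nonzero — the removable
#'   `V = 0` singularity is served by [membrane_current_v0_limit()].
#' @param cl_in Intracellular chloride (mM), >= 0. May be a vector.
#' @param cl_out Bath chloride (mM), > 0.
#' @param temperature Absolute temperature (K).
#' @return Current in amperes (whole tissue when `g` is whole-tissue).
#' @examples
#' # secretory current at baseline: negative by the internal convention
#' membrane_current(12.87e-6, -0.04, 32, 127.5)
#' @export
membrane_current <- function(g, v_membrane, cl_in, cl_out,
                             temperature = .DEFAULT_TEMPERATURE) {
  check_number(g, "g")
  check_number(v_membrane, "v_membrane")
  check_number(cl_in, "cl_in", allow_vector = TRUE)
  check_number(cl_out, "cl_out")
  check_number(temperature, "temperature")
  if (g < 0) abort_invalid("`g` must be >= 0.")
  if (any(cl_in < 0) || cl_out <= 0) {
    abort_invalid("Concentrations must be non-negative (`cl_out` > 0).")
  }
  if (v_membrane == 0) {
    abort_invalid(paste0(
      "`v_membrane` = 0 is a removable singularity of the chord form; ",
      "use `membrane_current_v0_limit()`."))
  }
  chord_current(g, v_membrane, cl_in, cl_out, temperature)
}

#' Membrane current in the zero-potential limit
#'
#' Analytic `V -> 0` limit of [membrane_current()]:
#' `I = -g*(R*T/F)*(cl_in - cl_out)/cl_out`, a purely diffusive current
#' driven by the concentration asymmetry.
#'
#' @inheritParams membrane_current
#' @return Current in amperes.
#' @export
membrane_current_v0_limit <- function(g, cl_in, cl_out,
                                      temperature = .DEFAULT_TEMPERATURE) {
  check_number(g, "g")
  check_number(cl_in, "cl_in", allow_vector = TRUE)
  check_number(cl_out, "cl_out")
  if (g < 0) abort_invalid("`g` must be >= 0.")
  if (any(cl_in < 0) || cl_out <= 0) {
    abort_invalid("Concentrations must be non-negative (`cl_out` > 0).")
  }
  -g * (.GAS * temperature / .FARADAY) * (cl_in - cl_out) / cl_out
}

#' Convert a chloride current to a molar flux
#'
#' Divides by the Faraday constant and flips the sign so that secretory
#' currents (negative in the internal convention) map to positive effluxes.
#'
#' @param i Current (A); may be a vector.
#' @return Molar chloride flux (mol/s), positive for efflux.
#' @examples
#' current_to_molar_flux(-0.0965)  # ~ 1e-6 mol/s
#' @export
current_to_molar_flux <- function(i) {
  check_number(i, "i", allow_vector = TRUE)
  -i / .FARADAY
}

#' Flip a model-convention current to the display convention
#'
#' The internal model convention makes secretory (efflux) chloride currents
#' negative; figures and reports show secretion as a positive current. This
#' function is the single owner of that sign flip (it is an involution, so it
#' also converts display-convention currents back).
#'
#' @param i Current (any unit); may be a vector.
#' @return `-i`.
#' @export
secretion_positive <- function(i) {
  check_number(i, "i", allow_vector = TRUE)
  -i
}

#' Time course of the active transporter pool
#'
#' Closed-form solution of the two-state kinetics
#' `inactive -> active` (rate `alpha`) and `active -> inactive` (rate
#' `beta`): `CT_Act(t) = CT_inf + (CT_Act(0) - CT_inf) * exp(-(alpha+beta)*t)`
#' with fixed point `CT_inf = alpha*CT_T/(alpha+beta)` and time constant
#' `tau2 = 1/(alpha+beta)`. The total pool `CT_Act + CT_Inact = CT_T` is
#' conserved identically.
#'
#' @param params A [transporter_params()] object with `alpha + beta > 0`.
#' @param ct_act_0 Active amount at t = 0, in `[0, ct_total]`.
#' @param t Times (s); may be a vector.
#' @return Active transporter amount at each `t`.
#' @examples
#' tp <- transporter_params(1, alpha = 0.02, beta = 0.01, flux_per_unit = 1e-11)
#' transporter_timecourse(tp, ct_act_0 = 0.2, t = c(0, 50, Inf))
#' @export
transporter_timecourse <- function(params, ct_act_0, t) {
  if (!inherits(params, "transporter_params")) {
    abort_invalid("`params` must be a `transporter_params` object.")
  }
  check_number(ct_act_0, "ct_act_0")
  check_number(t, "t", finite = FALSE, allow_vector = TRUE)
  if (ct_act_0 < 0 || ct_act_0 > params$ct_total) {
    abort_invalid("`ct_act_0` must lie in [0, ct_total].")
  }
  if (params$alpha + params$beta <= 0) {
    abort_invalid("alpha + beta must be > 0 for a time course.")
  }
  ct_inf <- params$alpha * params$ct_total / (params$alpha + params$beta)
  ct_inf + (ct_act_0 - ct_inf) * exp(-(params$alpha + params$beta) * t)
}

#' Uptake flux carried by the active transporter pool
#'
#' `J_C = j * CT_Act`: the electro-neutral uptake flux is proportional to the
#' active transporter amount and — by deliberate model assumption — does not
#' depend on intracellular chloride or on the membrane potential.
#'
#' @inheritParams transporter_timecourse
#' @param ct_act Active transporter amount, >= 0; may be a vector.
#' @return Uptake flux (mol/s).
#' @export
uptake_flux <- function(params, ct_act) {
  if (!inherits(params, "transporter_params")) {
    abort_invalid("`params` must be a `transporter_params` object.")
  }
  check_number(ct_act, "ct_act", allow_vector = TRUE)
  if (any(ct_act < 0)) abort_invalid("`ct_act` must be >= 0.")
  params$flux_per_unit * ct_act
}

#' Fast relaxation time constant of intracellular chloride
#'
#' `tau1 = Cv*F*(e^u - 1)*cl_out / (V*(G_A + G_B))`, the e-folding time with
#' which intracellular chloride relaxes toward its steady state at fixed
#' conductances and uptake. It is proportional to the cell volume and
#' inversely proportional to the total membrane chloride conductance, and is
#' strictly positive for any nonzero `V`.
#'
#' @param tissue A [tissue_params()] object.
#' @param state A [pathway_state()] object with nonzero total conductance and
#'   `v_membrane != 0`.
#' @return Time constant (s).
#' @examples
#' tau_cl(tissue_params(), pathway_state(12.87e-6, 386.1e-6, -0.04))
#' @export
tau_cl <- function(tissue, state) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(state, "pathway_state"))
  g_tot <- state$g_apical + state$g_basolateral
  if (g_tot <= 0) abort_invalid("Total conductance must be > 0.")
  if (state$v_membrane == 0) {
    abort_invalid("`tau_cl()` requires a nonzero membrane potential.")
  }
  eu <- boltzmann_factor(state$v_membrane, tissue$temperature)
  tissue$cell_volume * .FARADAY * (eu - 1) * tissue$cl_out /
    (state$v_membrane * g_tot)
}

#' Steady-state intracellular chloride
#'
#' The fixed point of the chloride mass balance at constant conductances and
#' uptake: `f(inf) = cl_out*e^u + J_C*tau1/Cv`, equivalently the
#' concentration at which the conductive effluxes exactly balance the uptake
#' (`J_A + J_B = J_C`). With `J_C > 0` it always exceeds the passive
#' equilibrium concentration.
#'
#' @inheritParams tau_cl
#' @param j_c Steady uptake flux (mol/s), >= 0.
#' @return Intracellular chloride (mM).
#' @examples
#' steady_state_cl(tissue_params(), pathway_state(12.87e-6, 360e-6, -0.04),
#'                 j_c = 8.5e-12)
#' @export
steady_state_cl <- function(tissue, state, j_c) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(state, "pathway_state"))
  check_number(j_c, "j_c")
  if (j_c < 0) abort_invalid("`j_c` must be >= 0.")
  eu <- boltzmann_factor(state$v_membrane, tissue$temperature)
  tissue$cl_out * eu + j_c * tau_cl(tissue, state) / tissue$cell_volume
}

#' Steady-state apical current ratio after a step stimulus
#'
#' With the membrane potential unchanged, the steady apical current scales as
#' `I_A(inf)/I_A0 = jc_rel * ga_rel/(ga_rel + gb_rel*rho) * (1 + rho)` where
#' `rho = G_B0/G_A0`. Equal relative changes of the two conductances with
#' unchanged uptake leave the steady secretion unchanged: the apical channel
#' merely competes with the basolateral back-flux for the same uptake flux.
#'
#' @param ga_rel Apical conductance fold-change `G_A/G_A0`, > 0.
#' @param gb_rel Basolateral conductance fold-change `G_B/G_B0`, > 0.
#' @param gb0_over_ga0 Baseline conductance ratio `G_B0/G_A0`, > 0.
#' @param jc_rel Uptake fold-change `J_C(inf)/J_C0`, > 0 (default 1).
#' @return Dimensionless `I_A(inf)/I_A0`.
#' @examples
#' steady_state_current_ratio(20, 1, 30)        # 12.4
#' steady_state_current_ratio(18, 18, 30)       # 1
#' @export
steady_state_current_ratio <- function(ga_rel, gb_rel, gb0_over_ga0,
                                       jc_rel = 1) {
  for (nm in c("ga_rel", "gb_rel", "gb0_over_ga0", "jc_rel")) {
    v <- get(nm)
    check_number(v, nm)
    if (v <= 0) abort_invalid(sprintf("`%s` must be > 0.", nm))
  }
  jc_rel * ga_rel / (ga_rel + gb_rel * gb0_over_ga0) * (1 + gb0_over_ga0)
}

#' Instantaneous apical current just after a step
#'
#' Intracellular chloride is continuous across the step, so the current at
#' t = 0+ is the chord current evaluated at the old concentration under the
#' new conductance and potential. With `V` unchanged this reduces exactly to
#' `I_A(0+)/I_A0 = G_A/G_A0` — the instantaneous response reports the apical
#' conductance change alone, blind to `G_B` and to the uptake pathway. With a
#' changed potential the full chord form applies.
#'
#' @param state_pre Baseline [pathway_state()], assumed at steady state with
#'   apical current `i_a0`.
#' @param state_post [pathway_state()] immediately after the step.
#' @param tissue A [tissue_params()] object.
#' @param i_a0 Baseline apical current (uA/cm^2, display convention:
#'   secretion positive). Must be nonzero.
#' @return `I_A(0+)` in uA/cm^2, display convention (secretion positive).
#' @examples
#' tis <- tissue_params()
#' pre <- pathway_state(12.87e-6, 360e-6, -0.04)
#' post <- pathway_state(12.87e-6, 360e-6, -0.07)
#' instantaneous_current(pre, post, tis, i_a0 = 0.08)
#' @export
instantaneous_current <- function(state_pre, state_post, tissue, i_a0) {
  stopifnot(inherits(state_pre, "pathway_state"),
            inherits(state_post, "pathway_state"),
            inherits(tissue, "tissue_params"))
  check_number(i_a0, "i_a0")
  if (i_a0 == 0) abort_invalid("`i_a0` must be nonzero.")
  if (state_pre$g_apical <= 0) {
    abort_invalid("`state_pre` must have a positive apical conductance.")
  }
  if (state_pre$v_membrane == 0) {
    abort_invalid("The baseline inversion requires `state_pre$v_membrane != 0`.")
  }
  # invert the chord form at baseline for the (continuous) [Cl-]i
  i_a0_int <- secretion_positive(i_a0) * 1e-6 * tissue$area  # A, model sign
  eu0 <- boltzmann_factor(state_pre$v_membrane, tissue$temperature)
  cl0 <- tissue$cl_out * eu0 +
    i_a0_int * tissue$cl_out * (1 - eu0) /
      (state_pre$g_apical * state_pre$v_membrane)
  i_new <- chord_current(state_post$g_apical, state_post$v_membrane, cl0,
                         tissue$cl_out, tissue$temperature)
  secretion_positive(i_new) / tissue$area * 1e6
}
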