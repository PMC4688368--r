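#' Time derivative of intracellular chloride
#'
#' Right-hand side of the chloride mass balance,
#' `d[Cl-]i/dt = (J_C - J_A - J_B)/Cv`, with the conductive effluxes taken
#' from the chord-form currents at the instantaneous concentration. Linear in
#' `cl_in` at fixed pathway state.
#'
#' @param t Time (s); unused by the autonomous balance but kept for solver
#'   compatibility.
#' @param cl_in Intracellular chloride (mM), > 0.
#' @param tissue A [tissue_params()] object.
#' @param state A [pathway_state()] object.
#' @param j_c Instantaneous uptake flux (mol/s).
#' @return `d[Cl-]i/dt` in mM/s.
#' @export
ode_rhs <- function(t, cl_in, tissue, state, j_c) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(state, "pathway_state"))
  check_number(cl_in, "cl_in", allow_vector = TRUE)
  if (any(cl_in < 0)) {
    abort_numeric("Negative intracellular chloride: model breakdown.")
  }
  i_a <- chord_current(state$g_apical, state$v_membrane, cl_in,
                       tissue$cl_out, tissue$temperature)
  i_b <- chord_current(state$g_basolateral, state$v_membrane, cl_in,
                       tissue$cl_out, tissue$temperature)
  (j_c - current_to_molar_flux(i_a) - current_to_molar_flux(i_b)) /
    tissue$cell_volume
}

#' Numerically integrate a step protocol
#'
#' Independent numerical twin of [analytic_solution()]: integrates the
#' coupled system (intracellular chloride; uptake flux relaxing as
#' `dJ_C/dt = (J_C(inf) - J_C)/tau2`) with a stiff-capable adaptive solver.
#' The integration starts exactly at the step time from the pre-stimulus
#' steady state, so the t = 0 discontinuity is never smoothed across.
#'
#' @inheritParams analytic_solution
#' @param opts A [solver_options()] object.
#' @return A `secretion_trace` tibble (see [analytic_solution()]), with
#'   attribute `method = "numeric"`.
#' @examples
#' tis <- tissue_params()
#' prot <- build_scenario("apigenin", tis)
#' tr <- integrate_protocol(tis, prot, n = 100)
#' @export
integrate_protocol <- function(tissue, protocol, t = NULL, n = 600,
                               opts = solver_options()) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "step_protocol"),
            inherits(opts, "solver_options"))
  grid <- split_time_grid(protocol, t, n)
  f0 <- steady_state_cl(tissue, protocol$pre_state, protocol$j_c0)
  jc_post0 <- protocol$j_c_post0 %||% protocol$j_c0

  times <- grid$post
  prepend0 <- length(times) == 0L || times[1] > 0
  if (prepend0) times <- c(0, times)

  has_kinetics <- !is.null(protocol$tau2) && jc_post0 != protocol$j_c_inf
  rhs <- function(tt, y, parms) {
    djc <- if (has_kinetics) (protocol$j_c_inf - y[["jc"]]) / protocol$tau2 else 0
    dcl <- ode_rhs(tt, y[["cl"]], tissue, protocol$post_state, y[["jc"]])
    list(c(dcl, djc))
  }
  y0 <- c(cl = f0, jc = if (has_kinetics) jc_post0 else protocol$j_c_inf)
  sol <- tryCatch(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 method = opts$method, rtol = opts$rel_tol,
                 atol = opts$abs_tol,
                 hmax = if (is.finite(opts$max_step)) opts$max_step else NULL),
    error = function(e) abort_numeric(
      sprintf("ODE integration failed: %s", conditionMessage(e))))
  if (attr(sol, "istate")[1] < 0) {
    abort_numeric("ODE integration did not complete; see deSolve diagnostics.")
  }
  sol <- as.data.frame(sol)
  if (prepend0) sol <- sol[-1, , drop = FALSE]

  df <- assemble_trace(tissue, protocol, grid,
                       cl_pre = rep(f0, length(grid$pre)),
                       cl_post = sol$cl, jc_post = sol$jc)
  new_secretion_trace(df, tissue, protocol, extras = list(
    method = "numeric", tau1 = tau_cl(tissue, protocol$post_state),
    tau2 = protocol$tau2, cl0 = f0,
    cl_inf = steady_state_cl(tissue, protocol$post_state, protocol$j_c_inf)))
}
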