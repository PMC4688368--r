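new_secretion_trace <- function(df, tissue, protocol, extras = list()) {
  out <- as_tibble(df)
  class(out) <- c("secretion_trace", class(out))
  attr(out, "tissue") <- tissue
  attr(out, "protocol") <- protocol
  for (nm in names(extras)) attr(out, nm) <- extras[[nm]]
  out
}

#' @export
print.secretion_trace <- function(x, ...) {
  cat("# Secretion trace")
  if (!is.null(attr(x, "method"))) cat(" (", attr(x, "method"), ")", sep = "")
  if (!is.null(attr(x, "tau1"))) {
    cat(sprintf("  tau1 = %.4g s", attr(x, "tau1")))
    if (!is.null(attr(x, "tau2"))) cat(sprintf(", tau2 = %.4g s", attr(x, "tau2")))
  }
  cat("\n")
  NextMethod()
}

# shared grid: a short pre-stimulus tail (ending at 0-) plus the post epoch
# from 0+ to the horizon, so the instantaneous jump is representable.
default_time_grid <- function(protocol, n = 600) {
  n_pre <- max(2L, round(n * 0.04))
  list(pre = seq(-0.05 * protocol$horizon, 0, length.out = n_pre),
       post = seq(0, protocol$horizon, length.out = n))
}

split_time_grid <- function(protocol, t, n) {
  if (is.null(t)) return(default_time_grid(protocol, n))
  check_number(t, "t", allow_vector = TRUE)
  if (is.unsorted(t, strictly = FALSE)) abort_invalid("`t` must be sorted.")
  if (any(t > protocol$horizon)) {
    abort_invalid("`t` must lie within [-(0.05*horizon), horizon].")
  }
  list(pre = t[t < 0], post = t[t >= 0])
}

# assemble the output tibble from epoch-wise concentrations and uptake fluxes
assemble_trace <- function(tissue, protocol, grid, cl_pre, cl_post,
                           jc_post) {
  per_area <- function(i) secretion_positive(i) / tissue$area * 1e6
  row_block <- function(t, epoch, cl, state, jc) {
    tibble(
      time_s = t, epoch = epoch, cl_in_mM = cl,
      i_apical_uApercm2 = per_area(chord_current(
        state$g_apical, state$v_membrane, cl, tissue$cl_out,
        tissue$temperature)),
      i_basolateral_uApercm2 = per_area(chord_current(
        state$g_basolateral, state$v_membrane, cl, tissue$cl_out,
        tissue$temperature)),
      i_uptake_uApercm2 = .FARADAY * jc / tissue$area * 1e6)
  }
  blocks <- list()
  if (length(grid$pre)) {
    blocks$pre <- row_block(grid$pre, "pre", cl_pre, protocol$pre_state,
                            protocol$j_c0)
  }
  if (length(grid$post)) {
    blocks$post <- row_block(grid$post, "post", cl_post, protocol$post_state,
                             jc_post)
  }
  bind_rows(blocks)
}

# uptake flux over the post epoch
post_uptake <- function(protocol, t) {
  jc0 <- protocol$j_c_post0 %||% protocol$j_c0
  if (is.null(protocol$tau2) || jc0 == protocol$j_c_inf) {
    rep(protocol$j_c_inf, length(t))
  } else {
    protocol$j_c_inf + (jc0 - protocol$j_c_inf) * exp(-t / protocol$tau2)
  }
}

#' Closed-form solution of a step-stimulation protocol
#'
#' Solves the chloride mass balance `Cv * d[Cl-]i/dt = J_C(t) - J_A - J_B`
#' analytically for a step protocol. The solution is the biexponential
#' `f(t) = f(inf) + A1*exp(-t/tau1) + A2*exp(-t/tau2)` where `tau1` is the
#' conductive relaxation time ([tau_cl()]) of the post-stimulus state, `tau2`
#' the transporter relaxation time, `A2 = (dJ_C/Cv)*tau1*tau2/(tau2 - tau1)`
#' with `dJ_C` the step-to-steady uptake difference, and
#' `A1 = f(0) - f(inf) - A2`. `f(0)` is the pre-stimulus steady state. The
#' pathway currents are evaluated pointwise from `f(t)` via the chord form.
#' In the degenerate case `tau1 = tau2` the confluent form
#' `(dJ_C/Cv) * t * exp(-t/tau)` replaces the second exponential (a message
#' reports the switch).
#'
#' @param tissue A [tissue_params()] object.
#' @param protocol A [step_protocol()] (or [transporter_protocol()]) object.
#' @param t Optional sorted vector of sample times (s); negative times sample
#'   the pre-stimulus steady state. Default: a short pre-stimulus tail ending
#'   at 0- plus `n` points from 0 to the horizon.
#' @param n Number of post-stimulus samples for the default grid.
#' @return A `secretion_trace` tibble with columns `time_s`, `epoch`,
#'   `cl_in_mM`, `i_apical_uApercm2`, `i_basolateral_uApercm2`,
#'   `i_uptake_uApercm2` (currents per area, secretion positive), carrying
#'   `tau1`, `tau2`, `cl0`, `cl_inf`, `i_a0` and `i_a_inf` as attributes.
#' @examples
#' tis <- tissue_params()
#' prot <- build_scenario("forskolin_pki", tis)
#' tr <- analytic_solution(tis, prot)
#' head(tr)
#' @export
analytic_solution <- function(tissue, protocol, t = NULL, n = 600) {
  stopifnot(inherits(tissue, "tissue_params"),
            inherits(protocol, "step_protocol"))
  grid <- split_time_grid(protocol, t, n)

  f0 <- steady_state_cl(tissue, protocol$pre_state, protocol$j_c0)
  tau1 <- tau_cl(tissue, protocol$post_state)
  f_inf <- steady_state_cl(tissue, protocol$post_state, protocol$j_c_inf)

  jc_post0 <- protocol$j_c_post0 %||% protocol$j_c0
  dj <- jc_post0 - protocol$j_c_inf
  tp <- grid$post
  if (is.null(protocol$tau2) || dj == 0) {
    cl_post <- f_inf + (f0 - f_inf) * exp(-tp / tau1)
  } else if (abs(1 - tau1 / protocol$tau2) < 1e-10) {
    inform(paste0(
      "tau1 and tau2 coincide; switching to the confluent t*exp(-t/tau) ",
      "solution."), class = "clsecretion_confluent")
    cl_post <- f_inf + (f0 - f_inf) * exp(-tp / tau1) +
      (dj / tissue$cell_volume) * tp * exp(-tp / tau1)
  } else {
    a2 <- (dj / tissue$cell_volume) * tau1 * protocol$tau2 /
      (protocol$tau2 - tau1)
    a1 <- f0 - f_inf - a2
    cl_post <- f_inf + a1 * exp(-tp / tau1) + a2 * exp(-tp / protocol$tau2)
  }

  df <- assemble_trace(tissue, protocol, grid,
                       cl_pre = rep(f0, length(grid$pre)),
                       cl_post = cl_post,
                       jc_post = post_uptake(protocol, tp))
  per_area <- function(i) secretion_positive(i) / tissue$area * 1e6
  new_secretion_trace(df, tissue, protocol, extras = list(
    method = "analytic", tau1 = tau1, tau2 = protocol$tau2,
    cl0 = f0, cl_inf = f_inf,
    i_a0 = per_area(chord_current(
      protocol$pre_state$g_apical, protocol$pre_state$v_membrane, f0,
      tissue$cl_out, tissue$temperature)),
    i_a_inf = per_area(chord_current(
      protocol$post_state$g_apical, protocol$post_state$v_membrane, f_inf,
      tissue$cl_out, tissue$temperature))))
}

#' Steady level of a trace variable
#'
#' Mean of the final fraction of post-stimulus samples, the package's reading
#' of "the level after the current reached a steady value". A least-squares
#' slope over the same window is required to be statistically
#' indistinguishable from zero (t-test at `alpha`); otherwise a warning flags
#' that the trace has not settled.
#'
#' @param data A data frame with a time column and the variable of interest
#'   (typically a `secretion_trace`).
#' @param value Column to average (tidy-eval), default `i_apical_uApercm2`.
#' @param time Time column (tidy-eval), default `time_s`.
#' @param frac Final fraction of samples to use (default 0.1).
#' @param alpha Significance level of the residual-slope check.
#' @return The steady level (scalar).
#' @export
steady_level <- function(data, value = i_apical_uApercm2, time = time_s,
                         frac = 0.1, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if ("epoch" %in% names(data)) data <- data[data$epoch == "post", ]
  y <- dplyr::pull(data, {{ value }})
  tt <- dplyr::pull(data, {{ time }})
  n <- length(y)
  if (n < 3) abort_invalid("Need at least 3 post-stimulus samples.")
  idx <- seq.int(max(1L, n - max(3L, ceiling(frac * n)) + 1L), n)
  yw <- y[idx]; tw <- tt[idx]
  if (sd(yw) > 0 && length(unique(tw)) > 2) {
    fit <- lm(yw ~ tw)
    p <- summary(fit)$coefficients["tw", "Pr(>|t|)"]
    drift <- abs(coef(fit)[["tw"]]) * diff(range(tw))
    if (p < alpha && drift > 1e-6 * max(abs(yw))) {
      warn("Tail window still drifts; the trace may not have reached steady state.")
    }
  }
  mean(yw)
}
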