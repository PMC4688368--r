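#' Conductance from a constant-current pulse
#'
#' Ohm's-law conductance from the transepithelial potential deflection caused
#' by a constant-current pulse: `G = I/dPD`. With the measurement convention
#' used here (a +1 uA pulse applied basolateral-to-apical), the deflection is
#' positive; a non-positive deflection violates the convention and is
#' rejected.
#'
#' @param delta_pd Potential deflection per pulse (mV), > 0. May be a vector.
#' @param pulse_current Pulse amplitude (uA), default 1.
#' @return Conductance in siemens (`uA/mV` = mS, converted to S).
#' @examples
#' conductance_from_pulse(77.7) * 1e6   # ~12.87 uS
#' @export
conductance_from_pulse <- function(delta_pd, pulse_current = 1) {
  check_number(delta_pd, "delta_pd", allow_vector = TRUE)
  check_number(pulse_current, "pulse_current")
  if (any(delta_pd <= 0)) {
    abort_invalid("`delta_pd` must be > 0 (positive-deflection convention).")
  }
  if (pulse_current <= 0) abort_invalid("`pulse_current` must be > 0.")
  pulse_current / delta_pd * 1e-3
}

#' Per-pulse potential deflections from a pulse recording
#'
#' For each pulse onset, the deflection is the mean potential over a plateau
#' window at the end of the pulse minus the mean over a baseline window
#' immediately before the onset.
#'
#' @param rec A pulse recording tibble (columns `time_s`, `pd_mV`) carrying
#'   `pulse_times`, `pulse_width` (s) attributes, as produced by
#'   [generate_pulse_recording()] or [read_pulse_recording()].
#' @param baseline_window Length (s) of the pre-pulse baseline window.
#' @param plateau_window Length (s) of the end-of-pulse plateau window; must
#'   not exceed the pulse width.
#' @return A tibble with columns `pulse`, `onset_s`, `delta_pd_mV` (one row
#'   per pulse; empty for a recording without pulses).
#' @export
extract_pulse_deflections <- function(rec, baseline_window = 2,
                                      plateau_window = 0.25) {
  stopifnot(is.data.frame(rec))
  if (!all(c("time_s", "pd_mV") %in% names(rec))) {
    abort_invalid("`rec` must have columns `time_s` and `pd_mV`.")
  }
  onsets <- attr(rec, "pulse_times")
  width <- attr(rec, "pulse_width")
  if (is.null(onsets) || is.null(width)) {
    abort_invalid("`rec` must carry `pulse_times` and `pulse_width` attributes.")
  }
  if (length(onsets) == 0L) {
    return(tibble(pulse = integer(), onset_s = double(),
                  delta_pd_mV = double()))
  }
  check_number(baseline_window, "baseline_window")
  check_number(plateau_window, "plateau_window")
  if (plateau_window <= 0 || plateau_window > width) {
    abort_invalid("`plateau_window` must lie in (0, pulse_width].")
  }
  gaps <- diff(sort(onsets))
  if (baseline_window <= 0 ||
      (length(gaps) && baseline_window > min(gaps) - width)) {
    abort_invalid("`baseline_window` overlaps the preceding pulse.")
  }
  tt <- rec$time_s; pd <- rec$pd_mV
  delta <- map_dbl(onsets, function(t0) {
    base <- pd[tt >= t0 - baseline_window & tt < t0]
    plat <- pd[tt >= t0 + width - plateau_window & tt < t0 + width]
    if (!length(base) || !length(plat)) {
      abort_invalid("Empty baseline or plateau window; check the sampling rate.")
    }
    mean(plat) - mean(base)
  })
  tibble(pulse = seq_along(onsets), onset_s = as.double(onsets),
         delta_pd_mV = delta)
}

#' Blocker-sensitive conductance
#'
#' Difference between the membrane conductance before and after applying a
#' chloride-channel blocker (e.g. NPPB); the blocker-sensitive component is
#' taken as the membrane's chloride conductance. A conductance that
#' *increases* on blocking is a contradiction (a "blocker paradox") and is
#' rejected rather than clamped.
#'
#' @param g_before,g_after Conductance (S) before/after the blocker;
#'   `g_before >= g_after >= 0`.
#' @return Chloride conductance (S).
#' @examples
#' nppb_sensitive_conductance(1000e-6, 640e-6) * 1e6   # 360 uS
#' @export
nppb_sensitive_conductance <- function(g_before, g_after) {
  check_number(g_before, "g_before", allow_vector = TRUE)
  check_number(g_after, "g_after", allow_vector = TRUE)
  if (any(g_after < 0)) abort_invalid("`g_after` must be >= 0.")
  if (any(g_after > g_before)) {
    abort_invalid(paste0(
      "`g_after` exceeds `g_before`: a blocker-paradox would imply a ",
      "negative chloride conductance."))
  }
  g_before - g_after
}

#' Estimate the fold-activation of the electro-neutral transporter
#'
#' Inverts the steady-state model for the uptake pathway. At steady state the
#' uptake flux equals the summed conductive effluxes, and with the membrane
#' potential unchanged the apical current and the conductance partition give
#' `J_C(inf)/J_C0 = [I_A(inf)*(G_A(inf)+G_B(inf))/G_A(inf)] /
#' [I_A0*(G_A0+G_B0)/G_A0]`, which under the model equals the fold-change of
#' the active transporter pool, `CT_Act(inf)/CT_Act0`. Because the
#' transporter is electro-neutral it is invisible to conductance
#' measurements; this inversion recovers its activity from six conductive
#' measurables alone.
#'
#' Currents may be supplied in either sign convention; magnitudes of the
#' current ratio are used and the detected convention is reported once per
#' call. If relative measurement errors are supplied, a first-order
#' (delta-method) confidence interval is added — an extension beyond the
#' point estimate, computed on the log scale.
#'
#' @param data A data frame with one row per measurement and columns `i_a0`,
#'   `i_a_inf` (apical currents, uA/cm^2), `g_a0`, `g_b0`, `g_a_inf`,
#'   `g_b_inf` (conductances, any common unit). Extra columns pass through.
#' @param current_rel_sd,conductance_rel_sd Optional relative standard
#'   deviations of the current and conductance measurements; when both are
#'   given, `conf.low`/`conf.high`/`se_log` columns are added.
#' @param conf_level Confidence level for the delta-method interval.
#' @return The input tibble with an `activation` column appended (plus
#'   interval columns when requested).
#' @examples
#' m <- tibble::as_tibble(ussing_measurement_example())
#' estimate_transporter_activation(m)$activation   # ~4.69
#' @export
estimate_transporter_activation <- function(data, current_rel_sd = NULL,
                                            conductance_rel_sd = NULL,
                                            conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  need <- c("i_a0", "i_a_inf", "g_a0", "g_b0", "g_a_inf", "g_b_inf")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort_invalid(sprintf("Missing measurement column(s): %s.",
                          paste(missing_cols, collapse = ", ")))
  }
  d <- as_tibble(data)
  with(d, {
    if (any(!is.finite(i_a0) | !is.finite(i_a_inf))) {
      abort_invalid("Currents must be finite.")
    }
    if (any(i_a0 == 0)) abort_invalid("`i_a0` must be nonzero.")
    if (any(c(g_a0, g_b0, g_a_inf, g_b_inf) <= 0)) {
      abort_invalid("All conductances must be > 0.")
    }
  })
  convention <- if (all(d$i_a0 > 0 & d$i_a_inf > 0)) "secretion-positive"
  else "model (secretion-negative)"
  inform(sprintf("Currents interpreted in the %s convention.", convention),
         class = "clsecretion_sign_convention")
  out <- mutate(d, activation =
    (abs(.data$i_a_inf) * (.data$g_a_inf + .data$g_b_inf) / .data$g_a_inf) /
    (abs(.data$i_a0) * (.data$g_a0 + .data$g_b0) / .data$g_a0))
  if (!is.null(current_rel_sd) && !is.null(conductance_rel_sd)) {
    check_number(current_rel_sd, "current_rel_sd")
    check_number(conductance_rel_sd, "conductance_rel_sd")
    z <- qnorm(1 - (1 - conf_level) / 2)
    out <- mutate(out,
      se_log = sqrt(2 * current_rel_sd^2 + 2 * conductance_rel_sd^2 *
        ((.data$g_b_inf / (.data$g_a_inf + .data$g_b_inf))^2 +
         (.data$g_b0 / (.data$g_a0 + .data$g_b0))^2)),
      conf.low = .data$activation * exp(-z * .data$se_log),
      conf.high = .data$activation * exp(z * .data$se_log))
  }
  out
}

#' Reference steady-state measurement set
#'
#' The six measurables of the package's worked example — baseline and
#' forskolin-stimulated apical chloride current (uA/cm^2) and apical/
#' basolateral blocker-sensitive conductances (uS) of an A6 monolayer —
#' in the shape consumed by [estimate_transporter_activation()].
#'
#' @return A named list with elements `i_a0`, `i_a_inf`, `g_a0`, `g_b0`,
#'   `g_a_inf`, `g_b_inf`.
#' @export
ussing_measurement_example <- function() {
  ussing_reference_values()
}
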