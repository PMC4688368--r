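# Trace and measurement files are plain TSV with a '#'-prefixed key=value
# metadata header: greppable, spreadsheet-safe, and round-trips doubles at
# full precision.

# append a header + body with doubles at 17 significant digits, enough to
# reproduce the exact binary value on re-parse
append_tsv_body <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }
  con <- file(path, "a"); on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(map(df, fmt), sep = "\t")), con)
}

format_metadata <- function(meta) {
  vals <- map(meta, function(v) paste(format(v, digits = 17), collapse = ","))
  sprintf("# %s=%s", names(meta), unlist(vals))
}

parse_metadata <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(map(kv, function(x) paste(x[-1], collapse = "=")),
           map(kv, 1))
}

protocol_metadata <- function(tissue, protocol) {
  list(
    package = "clsecretion", version = as.character(packageVersion("clsecretion")),
    cell_volume_m3 = tissue$cell_volume, area_cm2 = tissue$area,
    cl_out_mM = tissue$cl_out, temperature_K = tissue$temperature,
    scenario = protocol$name %||% "custom",
    g_apical_pre_S = protocol$pre_state$g_apical,
    g_basolateral_pre_S = protocol$pre_state$g_basolateral,
    v_pre_V = protocol$pre_state$v_membrane,
    g_apical_post_S = protocol$post_state$g_apical,
    g_basolateral_post_S = protocol$post_state$g_basolateral,
    v_post_V = protocol$post_state$v_membrane,
    j_c0_mol_s = protocol$j_c0, j_c_inf_mol_s = protocol$j_c_inf,
    tau2_s = protocol$tau2 %||% NA_real_, horizon_s = protocol$horizon)
}

#' Write a secretion trace to a TSV file
#'
#' Tab-separated values preceded by a `#`-prefixed `key=value` metadata block
#' recording all tissue/protocol parameters (and, for synthetic traces, the
#' noise settings and seed — the ground truth needed by recovery tests).
#' Values round-trip at full double precision.
#'
#' @param trace A `secretion_trace` tibble.
#' @param path Output file path.
#' @param extra_meta Optional named list of additional metadata.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, extra_meta = list()) {
  stopifnot(is.data.frame(trace))
  tissue <- attr(trace, "tissue"); protocol <- attr(trace, "protocol")
  meta <- c(if (!is.null(tissue) && !is.null(protocol))
              protocol_metadata(tissue, protocol),
            list(method = attr(trace, "method") %||% "unknown"),
            extra_meta)
  writeLines(format_metadata(meta), path)
  append_tsv_body(as.data.frame(trace), path)
  invisible(path)
}

#' Read a secretion trace written by [write_trace()]
#'
#' @param path File path.
#' @return A `secretion_trace` tibble; the parsed metadata is attached as the
#'   `metadata` attribute (named list of strings).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- parse_metadata(lines[startsWith(lines, "#")])
  df <- utils::read.delim(path, comment.char = "#")
  out <- as_tibble(df)
  class(out) <- c("secretion_trace", class(out))
  attr(out, "metadata") <- meta
  attr(out, "method") <- meta$method
  out
}

#' Generate a noisy synthetic secretion trace
#'
#' Samples the closed-form solution of a protocol and applies multiplicative
#' Gaussian noise to the current columns (`x * (1 + N(0, noise))`);
#' intracellular chloride is left noiseless (it is not a measured quantity).
#' All randomness flows from `seed` and the global random state is left
#' untouched; with `noise = 0` the samples equal the analytic trace exactly.
#'
#' @inheritParams analytic_solution
#' @param noise Relative noise amplitude on currents (e.g. 0.01 = 1%).
#' @param seed Integer seed; mandatory whenever `noise > 0`.
#' @return A `secretion_trace` tibble with `noise` and `seed` attributes and
#'   the noiseless truth recorded in attributes `cl0`, `cl_inf`, `i_a0`,
#'   `i_a_inf`.
#' @export
generate_synthetic_trace <- function(tissue, protocol, noise = 0,
                                     seed = NULL, t = NULL, n = 600) {
  check_number(noise, "noise")
  if (noise < 0) abort_invalid("`noise` must be >= 0.")
  if (noise > 0 && is.null(seed)) {
    abort_config("A `seed` is mandatory when `noise` > 0.")
  }
  tr <- analytic_solution(tissue, protocol, t = t, n = n)
  if (noise > 0) {
    cols <- c("i_apical_uApercm2", "i_basolateral_uApercm2",
              "i_uptake_uApercm2")
    withr::with_seed(seed, {
      for (cc in cols) {
        tr[[cc]] <- tr[[cc]] * (1 + rnorm(nrow(tr), 0, noise))
      }
    })
  }
  attr(tr, "noise") <- noise
  attr(tr, "seed") <- seed
  attr(tr, "method") <- "synthetic"
  tr
}

#' Generate a synthetic constant-current pulse recording
#'
#' Emulates the conductance-measurement protocol: a transepithelial potential
#' trace with square deflections `dPD = I_pulse/G` caused by constant-current
#' pulses (default +1 uA for 0.5 s every 10 s), plus additive Gaussian noise.
#' The true conductance is recorded in the attributes for recovery tests.
#'
#' @param g_true True tissue conductance (S), > 0.
#' @param n_pulses Number of pulses, >= 1.
#' @param period Pulse repetition period (s).
#' @param width Pulse duration (s), < `period`.
#' @param pulse_current Pulse amplitude (A), default 1 uA.
#' @param baseline_pd Resting transepithelial potential (mV), default -10.
#' @param noise_sd Additive Gaussian noise on the potential (mV).
#' @param dt Sampling interval (s).
#' @param seed Integer seed; mandatory whenever `noise_sd > 0`.
#' @return A `pulse_recording` tibble with columns `time_s`, `pd_mV` and
#'   attributes `pulse_times`, `pulse_width`, `pulse_current_uA`,
#'   `g_true_S`, `noise_sd`, `seed`.
#' @examples
#' rec <- generate_pulse_recording(1e-3, n_pulses = 3)
#' extract_pulse_deflections(rec)
#' @export
generate_pulse_recording <- function(g_true, n_pulses = 30, period = 10,
                                     width = 0.5, pulse_current = 1e-6,
                                     baseline_pd = -10, noise_sd = 0,
                                     dt = 0.05, seed = NULL) {
  check_number(g_true, "g_true"); check_number(noise_sd, "noise_sd")
  if (g_true <= 0) abort_invalid("`g_true` must be > 0.")
  if (!is.numeric(n_pulses) || n_pulses < 1) {
    abort_invalid("`n_pulses` must be >= 1 (zero-length recordings are not useful).")
  }
  if (width <= 0 || width >= period) {
    abort_invalid("`width` must lie in (0, period).")
  }
  if (noise_sd > 0 && is.null(seed)) {
    abort_config("A `seed` is mandatory when `noise_sd` > 0.")
  }
  onsets <- period * (seq_len(n_pulses) - 1) + period / 2
  tt <- seq(0, period * n_pulses, by = dt)
  in_pulse <- rep(FALSE, length(tt))
  for (t0 in onsets) in_pulse <- in_pulse | (tt >= t0 & tt < t0 + width)
  deflection_mV <- pulse_current / g_true * 1e3
  pd <- baseline_pd + ifelse(in_pulse, deflection_mV, 0)
  if (noise_sd > 0) {
    pd <- withr::with_seed(seed, pd + rnorm(length(pd), 0, noise_sd))
  }
  out <- tibble(time_s = tt, pd_mV = pd)
  class(out) <- c("pulse_recording", class(out))
  attr(out, "pulse_times") <- onsets
  attr(out, "pulse_width") <- width
  attr(out, "pulse_current_uA") <- pulse_current * 1e6
  attr(out, "g_true_S") <- g_true
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

#' Write / read a pulse recording
#'
#' Same TSV-with-metadata format as [write_trace()]; the pulse schedule and
#' the true conductance travel in the metadata header.
#'
#' @param rec A `pulse_recording` tibble.
#' @param path File path.
#' @return `path` (write) or a `pulse_recording` tibble (read).
#' @export
write_pulse_recording <- function(rec, path) {
  stopifnot(is.data.frame(rec))
  meta <- list(
    package = "clsecretion",
    pulse_times_s = attr(rec, "pulse_times"),
    pulse_width_s = attr(rec, "pulse_width"),
    pulse_current_uA = attr(rec, "pulse_current_uA"),
    g_true_S = attr(rec, "g_true_S"),
    noise_sd_mV = attr(rec, "noise_sd") %||% 0,
    seed = attr(rec, "seed") %||% NA)
  writeLines(format_metadata(meta), path)
  append_tsv_body(as.data.frame(rec), path)
  invisible(path)
}

#' @rdname write_pulse_recording
#' @export
read_pulse_recording <- function(path) {
  lines <- readLines(path)
  meta <- parse_metadata(lines[startsWith(lines, "#")])
  df <- utils::read.delim(path, comment.char = "#")
  out <- as_tibble(df)
  class(out) <- c("pulse_recording", class(out))
  attr(out, "pulse_times") <- as.numeric(strsplit(meta$pulse_times_s, ",")[[1]])
  attr(out, "pulse_width") <- as.numeric(meta$pulse_width_s)
  attr(out, "pulse_current_uA") <- as.numeric(meta$pulse_current_uA)
  attr(out, "g_true_S") <- as.numeric(meta$g_true_S)
  attr(out, "metadata") <- meta
  out
}

#' Read a steady-state measurement file
#'
#' Reads a delimited text file with a header of column names (`i_a0`,
#' `i_a_inf`, `g_a0`, `g_b0`, `g_a_inf`, `g_b_inf`), a units row, and one or
#' more rows of values — the shape produced by tabulating Ussing-chamber
#' steady levels.
#'
#' @param path File path.
#' @return A tibble of measurements with the units row attached as the
#'   `units` attribute.
#' @examples
#' f <- system.file("extdata", "forskolin_ussing_measurement.tsv",
#'                  package = "clsecretion")
#' read_ussing_measurement(f)
#' @export
read_ussing_measurement <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) < 3) {
    abort_config("Measurement file needs a header, a units row and data.")
  }
  split_row <- function(x) strsplit(x, "\t|,|;\\s*|\\s{2,}")[[1]]
  header <- trimws(split_row(lines[1]))
  units <- trimws(split_row(lines[2]))
  need <- c("i_a0", "i_a_inf", "g_a0", "g_b0", "g_a_inf", "g_b_inf")
  missing_cols <- setdiff(need, header)
  if (length(missing_cols)) {
    abort_config(sprintf("Measurement file is missing column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  rows <- map(lines[-(1:2)], function(l) as.numeric(split_row(l)))
  if (any(map_dbl(rows, length) != length(header))) {
    abort_config("Measurement rows do not match the header width.")
  }
  df <- as_tibble(setNames(as.data.frame(do.call(rbind, rows)), header))
  attr(df, "units") <- setNames(units, header)
  df
}

#' Write a transporter-activation report
#'
#' Plain-text report combining a human-readable input echo with
#' machine-readable `key=value` lines (one block per measurement row).
#'
#' @param result Output of [estimate_transporter_activation()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_activation_report <- function(result, path) {
  stopifnot(is.data.frame(result), "activation" %in% names(result))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# Electro-neutral transporter activation report", con)
  for (i in seq_len(nrow(result))) {
    r <- result[i, ]
    writeLines(sprintf(
      "measurement %d: I_A0=%g, I_Ainf=%g uA/cm2; G_A0=%g, G_B0=%g, G_Ainf=%g, G_Binf=%g",
      i, r$i_a0, r$i_a_inf, r$g_a0, r$g_b0, r$g_a_inf, r$g_b_inf), con)
    writeLines(sprintf("activation_fold=%.6g", r$activation), con)
    if (!is.null(r$conf.low)) {
      writeLines(sprintf("conf_low=%.6g", r$conf.low), con)
      writeLines(sprintf("conf_high=%.6g", r$conf.high), con)
    }
  }
  invisible(path)
}
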