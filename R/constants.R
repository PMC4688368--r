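#' Physical constants of the secretion model
#'
#' CODATA values of the Faraday and molar gas constants, together with the
#' chloride valence. These are the only physical constants the model uses;
#' they are fixed and shared by every operation in the package.
#'
#' @return A named list with elements `faraday` (C/mol), `gas`
#'   (J mol^-1 K^-1) and `z_cl` (dimensionless, -1).
#' @examples
#' physical_constants()$faraday
#' @export
physical_constants <- function() {
  list(faraday = 96485.33212, gas = 8.31446261815324, z_cl = -1L)
}

# internal shorthands
.FARADAY <- 96485.33212
.GAS <- 8.31446261815324

# Default absolute temperature (K). Chosen inside the experimental 24-25 C
# band so that exp(FV/RT) evaluates to 0.2104 at -40 mV and 0.0654 at -70 mV
# to four decimals, the reference values used throughout the worked examples.
.DEFAULT_TEMPERATURE <- 297.8

# Default bath chloride (mM == mol/m^3): 120 NaCl + 3.5 KCl + 2x1 CaCl2 +
# 2x1 MgCl2 from the amphibian Ringer-type solution.
.DEFAULT_CL_OUT <- 127.5

# error helpers -------------------------------------------------------------

abort_invalid <- function(msg, ...) {
  abort(msg, class = c("clsecretion_invalid_input", "clsecretion_error"), ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = c("clsecretion_config_error", "clsecretion_error"), ...)
}

abort_numeric <- function(msg, ...) {
  abort(msg, class = c("clsecretion_numeric_error", "clsecretion_error"), ...)
}

check_number <- function(x, name, finite = TRUE, allow_vector = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || (!allow_vector && length(x) != 1L)) {
    abort_invalid(sprintf("`%s` must be a numeric %s.", name,
                          if (allow_vector) "vector" else "scalar"))
  }
  if (finite && !all(is.finite(x))) {
    abort_invalid(sprintf("`%s` must be finite.", name))
  }
  invisible(x)
}
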