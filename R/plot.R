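#' Plot a secretion trace
#'
#' Faceted time-course plot of the apical chloride current (secretion
#' positive) and intracellular chloride concentration, with the stimulus at
#' t = 0 marked.
#'
#' @param object A `secretion_trace` tibble.
#' @param vars Which panels to draw: any of `"current"`, `"cl"`, `"uptake"`.
#' @param time_unit `"s"` or `"min"` for the x axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.secretion_trace <- function(object, vars = c("current", "cl"),
                                     time_unit = c("min", "s"), ...) {
  time_unit <- match.arg(time_unit)
  vars <- match.arg(vars, c("current", "cl", "uptake"), several.ok = TRUE)
  panels <- c(current = "i_apical_uApercm2", cl = "cl_in_mM",
              uptake = "i_uptake_uApercm2")[vars]
  labels <- c(i_apical_uApercm2 = "I[A]~(mu*A/cm^2)",
              cl_in_mM = "group('[',Cl^'-',']')[i]~(mM)",
              i_uptake_uApercm2 = "F%.%J[C]~(mu*A/cm^2)")
  div <- if (time_unit == "min") 60 else 1
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("time_s", panels)],
    cols = dplyr::all_of(unname(panels)),
    names_to = "panel", values_to = "value")
  long$panel <- factor(long$panel, levels = panels, labels = labels[panels])
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time_s / div, y = .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = if (time_unit == "min") "time (min)" else "time (s)",
                  y = NULL) +
    ggplot2::theme_bw()
}

#' @export
plot.secretion_trace <- function(x, ...) print(autoplot(x, ...))

#' Plot a biexponential fit over its data
#'
#' @param object A `biexp_fit` object.
#' @param ... Unused.
#' @return A ggplot object showing the samples and the fitted curve.
#' @export
autoplot.biexp_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::labs(x = "time (s)", y = "value",
                  subtitle = sprintf("components: %d, sigma = %.3g",
                                     object$n_components, object$sigma)) +
    ggplot2::theme_bw()
}

#' @export
plot.biexp_fit <- function(x, ...) print(autoplot(x, ...))
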