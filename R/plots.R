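# ggplot2 graphics for simulations, pump curves and protocols.

#' Plot a simulation trace
#'
#' Faceted time-series of selected trace quantities (default: membrane
#' potential in mV, cytosolic Ca2+, active tension and the oxygen
#' consumption rate).
#'
#' @param object a `cardiox_sim`.
#' @param vars trace columns to show.
#' @param window optional `c(start, end)` time restriction (s).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cardiox_sim <- function(object, vars = c("V", "Ca_i", "tension",
                                                  "OCR"),
                                 window = NULL, ...) {
  tr <- object$trace
  if (!is.null(window))
    tr <- tr[tr$time >= window[1] & tr$time <= window[2], ]
  tr <- tr[, c("time", intersect(vars, names(tr)))]
  if ("V" %in% names(tr)) tr$V <- tr$V * 1000 # mV for display
  long <- tidyr::pivot_longer(tr, -"time", names_to = "quantity",
                              values_to = "value")
  long$quantity <- factor(long$quantity, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("protocol:", object$protocol$name)) +
    ggplot2::theme_minimal()
}

#' Plot SERCA pump-rate versus pCa curves
#'
#' @param curves output of [cdx_pca_curve()].
#' @return A ggplot object (pCa axis reversed, one colour per pH).
#' @export
cdx_plot_pca_curve <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$pCa, y = .data$rate,
                                       colour = factor(.data$pH))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "pCa", y = "pump rate (1/s)", colour = "pH") +
    ggplot2::theme_minimal()
}

#' Plot a protocol's scheduled environment
#'
#' @param protocol a `cardiox_protocol`.
#' @param vars modifier columns to display.
#' @param n number of time points.
#' @return A ggplot object.
#' @export
cdx_plot_protocol <- function(protocol, vars = c("K_o", "O2_s", "pH",
                                                 "MgATP", "sc_gKr"),
                              n = 500) {
  env <- cdx_protocol_env(protocol,
                          seq(0, protocol$duration, length.out = n))
  long <- tidyr::pivot_longer(env[, c("time", vars)], -"time",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("protocol:", protocol$name)) +
    ggplot2::theme_minimal()
}
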