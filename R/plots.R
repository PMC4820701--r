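#' Diagnostic plots
#'
#' `autoplot()` methods give quick ggplot2 diagnostics for each result
#' type: current families, activation curves, Boltzmann fits, ratio
#' curves, dose-response fits and partition fits.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name paddletox-autoplot
NULL

#' @rdname paddletox-autoplot
#' @method autoplot trace_set
#' @export
autoplot.trace_set <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$current,
                               group = .data$voltage,
                               colour = .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "current (nA)",
                  colour = "step (mV)") +
    ggplot2::theme_minimal()
}

#' @rdname paddletox-autoplot
#' @method autoplot activation_curve
#' @export
autoplot.activation_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$voltage, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "voltage (mV)", y = "normalized response") +
    ggplot2::theme_minimal()
}

#' @rdname paddletox-autoplot
#' @method autoplot boltzmann_fit
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$voltage, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "voltage (mV)", y = "normalized response",
                  title = sprintf("Boltzmann fit (%s mode)", object$mode)) +
    ggplot2::theme_minimal()
}

#' @rdname paddletox-autoplot
#' @method autoplot ratio_curve
#' @export
autoplot.ratio_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object)[!object$dropped, ],
                  ggplot2::aes(.data$voltage, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "voltage (mV)", y = expression(I / I[0])) +
    ggplot2::theme_minimal()
}

#' @rdname paddletox-autoplot
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$concentration, .data$fu)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[toxin] (uM)", y = expression(F[u])) +
    ggplot2::theme_minimal()
}

#' @rdname paddletox-autoplot
#' @method autoplot partition_fit
#' @export
autoplot.partition_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$lipid_avail, .data$f_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "available lipid (M)", y = expression(F / F[0])) +
    ggplot2::theme_minimal()
}
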