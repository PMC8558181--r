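#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `ceac_curve` from [ceac()].
#' @param ... Unused.
#' @return A ggplot: probability cost-effective against willingness to
#'   pay.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (euros per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' @param object A `psa_result` from [psa()].
#' @param ... Unused.
#' @return A ggplot of the incremental cost/QALY draws, with the base
#'   case marked.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) {
  base <- object$base
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::annotate("point", x = base$delta_qaly, y = base$delta_cost,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (euros)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' @param object An `owsa_result` from [owsa()].
#' @param ... Unused.
#' @return A ggplot: horizontal bars spanning the ICUR at the low and high
#'   input, ordered by range, with the base-case ICUR marked.
#' @method autoplot owsa_result
#' @export
autoplot.owsa_result <- function(object, ...) {
  base <- attr(object, "base")
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       parameter = factor(.data$parameter,
                                          levels = rev(.data$parameter)))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icur_low,
                                       xend = .data$icur_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base$icur, linetype = 2) +
    ggplot2::labs(x = "ICUR (euros per QALY)", y = NULL,
                  title = "Tornado diagram") +
    ggplot2::theme_minimal()
}
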