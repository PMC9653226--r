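#' Trace plots of a fitted chain
#'
#' @param object A \code{scartree_fit}.
#' @param parameters Trace columns to plot (default: free parameters and
#'   log posterior).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scartree_fit <- function(object, parameters = NULL, ...) {
  if (is.null(parameters))
    parameters <- c("log_posterior", object$free)
  tr <- object$trace |>
    dplyr::select(dplyr::all_of(c("iteration", parameters))) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter",
                        values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Truth-versus-estimate plot of a recovery report
#'
#' Posterior medians with HPD intervals against the true values, one facet
#' per tracked parameter, coloured by phylogenetic-signal stratum; the
#' diagonal marks a perfect estimator.
#'
#' @param object A \code{recovery_report}.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$truth, y = .data$median,
                               colour = .data$signal)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "darkgreen") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           alpha = 0.4, width = 0) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free") +
    ggplot2::labs(x = "true value", y = "posterior median") +
    ggplot2::theme_minimal()
}
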