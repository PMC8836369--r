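#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a VR profile
#'
#' Nodes ordered by increasing VR on a log scale; on hub-rich networks the
#' right tail rises one to two orders of magnitude above the bulk.
#'
#' @param object A [vr_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vr_profile <- function(object, ...) {
  df <- dplyr::arrange(object, .data$vr)
  df$rank <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = pmax(.data$vr, 1e-12)))
  p <- if ("degree" %in% names(df))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$degree))
  else p + ggplot2::geom_point()
  p + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "node (ordered by VR)", y = "payoff variance (VR)",
                  colour = "degree")
}

#' Plot a diversity regression fit
#'
#' Observed versus fitted success rate across strategy compositions.
#'
#' @param object A `diversity_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diversity_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- as.numeric(predict(object$fit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$sr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fitted success rate", y = "observed success rate")
}

#' Plot a reconstruction fit
#'
#' Estimated node degree against VR, coloured by the solver that produced
#' each node's neighbourhood.
#'
#' @param object A `ccs_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccs_fit <- function(object, ...) {
  ggplot2::ggplot(object$provenance,
                  ggplot2::aes(x = pmax(.data$vr, 1e-12),
                               y = .data$est_degree,
                               colour = .data$solver)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "payoff variance (VR)", y = "estimated degree",
                  colour = "solver")
}
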