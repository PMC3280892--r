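#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type: the
#' orbit in state space and over phase (`limit_cycle`), the PRC components
#' (`prc`), the tabulated noise coefficients (`phase_law`), the correlation
#' functions and stationary density with its detected peaks (`phase_dist`),
#' and a histogram-vs-theory overlay (`phase_histogram`, with an optional
#' `dist` argument).
#'
#' @param object A package object.
#' @param ... Unused.
#' @name popsync-plots
NULL

#' @rdname popsync-plots
#' @export
autoplot.limit_cycle <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$theta, y = .data$value,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "phase", y = "activity",
                  title = sprintf("limit cycle (period %.3f)",
                                  attr(object, "period")))
}

#' @rdname popsync-plots
#' @export
autoplot.prc <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$theta, y = .data$Z,
                               colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "phase", y = "phase sensitivity",
                  title = "infinitesimal phase-resetting curve")
}

#' @rdname popsync-plots
#' @export
autoplot.phase_law <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$coefficient %in% c("common", "indep_total", "drift"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coefficient, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "phase", y = NULL, title = "phase-law coefficients")
}

#' @rdname popsync-plots
#' @export
autoplot.phase_dist <- function(object, ...) {
  pk <- attr(object, "peaks")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phi, y = .data$phi0)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk,
                        ggplot2::aes(x = .data$location, y = .data$height),
                        colour = "red") +
    ggplot2::labs(x = "phase difference", y = "stationary density",
                  title = sprintf("pairwise phase differences (eps %.3g, sigma %.3g)",
                                  attr(object, "epsilon"),
                                  attr(object, "sigma")))
}

#' @rdname popsync-plots
#' @param dist Optional analytic [stationary_distribution()] overlay.
#' @export
autoplot.phase_histogram <- function(object, dist = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$phi,
                                            y = .data$density)) +
    ggplot2::geom_col(width = 2 * pi / nrow(object), fill = "grey70") +
    ggplot2::labs(x = "phase difference", y = "density",
                  title = "simulated pairwise phase differences")
  if (!is.null(dist)) {
    p <- p + ggplot2::geom_line(data = dist,
                                ggplot2::aes(x = .data$phi, y = .data$phi0),
                                colour = "red")
  }
  p
}
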