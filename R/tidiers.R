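#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' The tabular objects (`limit_cycle`, `prc`, `phase_law`, `phase_dist`)
#' are already tibbles; their `tidy()` methods return them in long format,
#' and `glance()` summarises the scalar diagnostics in a one-row tibble.
#'
#' @param x A package object.
#' @param ... Unused.
#' @name popsync-tidiers
NULL

#' @rdname popsync-tidiers
#' @export
tidy.limit_cycle <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"theta",
                      names_to = "component", values_to = "value")
}

#' @rdname popsync-tidiers
#' @export
glance.limit_cycle <- function(x, ...) {
  st <- lc_states(x)
  tibble::tibble(period = attr(x, "period"), omega = attr(x, "omega"),
                 n_grid = attr(x, "n_grid"),
                 amplitude = diff(range(st[, 1])))
}

#' @rdname popsync-tidiers
#' @export
tidy.prc <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"theta",
                      names_to = "component", values_to = "Z")
}

#' @rdname popsync-tidiers
#' @export
glance.prc <- function(x, ...) {
  Z <- prc_components(x)
  tibble::tibble(omega = attr(x, "omega"), n_grid = attr(x, "n_grid"),
                 max_abs_Z = max(abs(Z)))
}

#' @rdname popsync-tidiers
#' @export
tidy.phase_law <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"theta",
                      names_to = "coefficient", values_to = "value")
}

#' @rdname popsync-tidiers
#' @export
glance.phase_law <- function(x, ...) {
  tibble::tibble(omega = attr(x, "omega"), epsilon = attr(x, "epsilon"),
                 sigma = attr(x, "sigma"), n_grid = attr(x, "n_grid"))
}

#' @rdname popsync-tidiers
#' @export
tidy.phase_dist <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"phi",
                      names_to = "quantity", values_to = "value")
}

#' @rdname popsync-tidiers
#' @export
glance.phase_dist <- function(x, ...) {
  pk <- attr(x, "peaks")
  i0 <- which.min(abs(x$phi))
  tibble::tibble(epsilon = attr(x, "epsilon"), sigma = attr(x, "sigma"),
                 gamma0 = attr(x, "gamma0"), g0 = attr(x, "g0"),
                 h0 = attr(x, "h0"), phi0_at_zero = x$phi0[i0],
                 n_peaks = nrow(pk))
}
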