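#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PMF profile
#'
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @return Tibble with `rg`, `w`, `stderr`.
#' @export
tidy.pmf_profile <- function(x, ...) {
  tibble::tibble(rg = x$rg, w = x$w, stderr = x$stderr)
}

#' One-row summary of a PMF profile
#'
#' @param x A `pmf_profile`.
#' @param rg_cut Coil/globule boundary for the collapse integral.
#' @param ... Unused.
#' @export
glance.pmf_profile <- function(x, rg_cut = 0.7, ...) {
  dg <- tryCatch(collapse_free_energy(x, rg_cut),
                 error = function(e) list(dg = NA_real_, stderr = NA_real_))
  tibble::tibble(n_bins = sum(is.finite(x$w)),
                 w_max = max(x$w, na.rm = TRUE),
                 dg_collapse = dg$dg, dg_stderr = dg$stderr,
                 temperature = attr(x, "temperature"),
                 wham_iterations = attr(x, "iterations") %||% NA_integer_)
}

#' Tidy a TI result
#'
#' @param x A `ti_result`.
#' @param ... Unused.
#' @export
tidy.ti_result <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, dudl = x$dudl,
                 dudl_stderr = x$dudl_stderr)
}

#' One-row summary of a TI result
#'
#' @param x A `ti_result`.
#' @param ... Unused.
#' @export
glance.ti_result <- function(x, ...) {
  tibble::tibble(dg = attr(x, "dg"), dg_stderr = attr(x, "dg_stderr"),
                 conformation = attr(x, "conformation"),
                 x_alcohol = attr(x, "x_alcohol"), n_lambda = nrow(x))
}

#' Plot a PMF profile
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rg, y = .data$w)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$w - .data$stderr,
                                      ymax = .data$w + .data$stderr),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = expression(R[g] ~ "(nm)"),
                  y = expression(w(R[g]) ~ "(kJ/mol)")) +
    ggplot2::theme_minimal()
}

#' Plot a TI dU/dlambda curve
#'
#' @param object A `ti_result`.
#' @param ... Unused.
#' @export
autoplot.ti_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lambda, y = .data$dudl)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$dudl - .data$dudl_stderr,
      ymax = .data$dudl + .data$dudl_stderr), na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda),
                  y = expression(paste("<", partialdiff * U / partialdiff *
                                         lambda, "> (kJ/mol)"))) +
    ggplot2::theme_minimal()
}

#' Plot an adsorption profile
#'
#' @param object An `adsorption_profile`.
#' @param ... Unused.
#' @export
autoplot.adsorption_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_alcohol, y = .data$gamma,
                                  colour = .data$conformation)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$gamma - .data$gamma_stderr,
      ymax = .data$gamma + .data$gamma_stderr)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(X[Alcohol]),
                  y = expression(Gamma ~ "(molecules)")) +
    ggplot2::theme_minimal()
}

#' Plot cavity-work curves from a TI campaign
#'
#' @param campaign Output of [ti_campaign()].
#' @export
plot_cavity_work <- function(campaign) {
  ggplot2::ggplot(campaign$table,
                  ggplot2::aes(x = .data$x_alcohol, y = .data$dg,
                               colour = .data$conformation)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$dg - .data$stderr,
                                          ymax = .data$dg + .data$stderr)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(X[Alcohol]),
                  y = expression(Delta * G["Excl-Vol"] ~ "(kJ/mol)")) +
    ggplot2::theme_minimal()
}
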