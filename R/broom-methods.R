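#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Stokes flow solution
#'
#' Returns the series coefficients per retained order: the slip mode
#' coefficients \eqn{B_n} and the streamfunction coefficients
#' \eqn{E_n, F_n}.
#'
#' @param x A [stokes_flow()].
#' @param ... Unused.
#' @return A tibble with columns `n`, `B`, `E`, `F`.
#' @export
tidy.stokes_flow <- function(x, ...) {
  nmax <- x$nmax
  n <- seq_len(nmax + 2L)
  tibble::tibble(
    n = n,
    B = c(x$B, rep(NA_real_, length(n) - length(x$B)))[seq_along(n)],
    E = x$E[n + 1L],
    F = c(x$F, rep(NA_real_, 2))[n + 1L]
  )
}

#' Glance at a Stokes flow solution
#'
#' @param x A [stokes_flow()].
#' @param ... Unused.
#' @return A one-row tibble with the truncation order, boundary-residual
#'   norms and geometry constants.
#' @export
glance.stokes_flow <- function(x, ...) {
  tibble::tibble(
    slip = x$slip_name,
    nmax = x$nmax,
    residual_g = x$residual_g,
    residual_dg = x$residual_dg,
    bx = x$geometry$bx,
    bz = x$geometry$bz,
    tau0 = x$geometry$tau0
  )
}

#' Tidy a homogeneity curve
#'
#' @param x A `homogeneity_curve`.
#' @param ... Unused.
#' @return The underlying tibble (`chi`, `phi_mean`, `phi_min`,
#'   `phi_max`).
#' @export
tidy.homogeneity_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("chi", "phi_mean", "phi_min", "phi_max")])
}

#' Glance at a homogeneity curve
#'
#' @param x A `homogeneity_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `chi_star`, the measure and its parameter,
#'   ensemble sizes and seed.
#' @export
glance.homogeneity_curve <- function(x, ...) {
  tibble::tibble(
    chi_star = attr(x, "chi_star"),
    measure = attr(x, "measure"),
    bandwidth = attr(x, "bandwidth"),
    n_strips = attr(x, "n_strips"),
    n = attr(x, "n"),
    n_seeds = attr(x, "n_seeds"),
    base_seed = attr(x, "base_seed"),
    phi_minimum = min(x$phi_mean)
  )
}

#' Tidy an amplitude fit
#'
#' @param x An `amplitude_fit` from [fit_amplitude_gaussians()].
#' @param ... Unused.
#' @return The parameter table with estimates, standard errors and 95\%
#'   intervals.
#' @export
tidy.amplitude_fit <- function(x, ...) x$params

#' Glance at an amplitude fit
#'
#' @param x An `amplitude_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the total \eqn{\chi}, its 95\% range
#'   and the fit RMS residual.
#' @export
glance.amplitude_fit <- function(x, ...) {
  tibble::tibble(
    chi_total = x$chi_total,
    chi_conf_low = x$chi_conf[1],
    chi_conf_high = x$chi_conf[2],
    residual_rms = x$residual_rms,
    n_peaks = length(x$series$a)
  )
}
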