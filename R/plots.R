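#' Plot a meridional flow field
#'
#' Speed map of the flow in the meridional plane, with the zero contour
#' of the streamfunction overlaid to mark vortex boundaries. Works for
#' both the exact and the long-wavelength solutions.
#'
#' @param object A [stokes_flow()] or [lubrication_flow()].
#' @param n_z,n_r Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stokes_flow <- function(object, n_z = 120, n_r = 50, ...) {
  plot_flow_field_(object, n_z, n_r)
}

#' @rdname autoplot.stokes_flow
#' @export
autoplot.lubrication_flow <- function(object, n_z = 120, n_r = 50, ...) {
  plot_flow_field_(object, n_z, n_r)
}

plot_flow_field_ <- function(flow, n_z, n_r) {
  g <- flow$geometry
  zg <- seq(-0.985 * g$bz, 0.985 * g$bz, length.out = n_z)
  grid <- purrr::map_dfr(zg, function(z) {
    rmax <- 0.985 * g$bx * sqrt(1 - (z / g$bz)^2)
    tibble::tibble(r = seq(rmax / n_r, rmax, length.out = n_r), z = z)
  })
  v <- flow_velocity(flow, grid)
  p <- streamfunction(flow, grid)
  dat <- dplyr::mutate(v, speed = sqrt(.data$u_r^2 + .data$u_z^2),
                       psi = p$psi)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$z, y = .data$r)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$speed), size = 0.8) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$psi), breaks = 0,
                          colour = "white", linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "|u| (µm/s)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "z (µm)", y = "r (µm)",
                  title = sprintf("Meridional flow: %s", flow$slip_name)) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble homogeneity curve
#'
#' Normalized ensemble-mean variance against the rescaled time
#' \eqn{\chi}, with the seed-to-seed min–max band and the optimum marked.
#'
#' @param object A `homogeneity_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.homogeneity_curve <- function(object, ...) {
  cs <- attr(object, "chi_star")
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$chi)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$phi_min,
                                      ymax = .data$phi_max),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$phi_mean),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = cs, linetype = "dashed") +
    ggplot2::annotate("point", x = cs,
                      y = min(object$phi_mean), shape = 18, size = 3,
                      colour = "steelblue") +
    ggplot2::labs(
      x = "χ (µm)",
      y = expression(phi(chi) / phi(0)),
      title = sprintf("Axial homogeneity (optimum at χ* = %.0f µm)",
                      cs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the reduced-model variance curve
#'
#' @param object A `reduced_variance_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reduced_variance_curve <- function(object, ...) {
  cs <- attr(object, "chi_star")
  ggplot2::ggplot(tibble::as_tibble(unclass(object)[c("chi", "phi")]),
                  ggplot2::aes(x = .data$chi, y = .data$phi)) +
    ggplot2::geom_line(colour = "purple") +
    ggplot2::geom_vline(xintercept = cs, linetype = "dashed") +
    ggplot2::labs(
      x = "χ (µm)", y = expression(Phi["1D"](chi)),
      title = sprintf("Reduced 1D model (optimum at χ* = %.0f µm)",
                      cs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot reduced-model density snapshots
#'
#' @param chi Values of \eqn{\chi} to draw, \eqn{\mu m}.
#' @param bz Semi-major axis, \eqn{\mu m}.
#' @param Z0 Initial cloud half-width.
#' @return A ggplot object.
#' @export
plot_reduced_snapshots <- function(chi = c(0, 100, 159, 250, 400),
                                   bz = 270, Z0 = 60 / 270) {
  Zg <- seq(-1, 1, length.out = 801)
  dat <- purrr::map_dfr(chi, function(ch) {
    tibble::tibble(chi = ch, Z = Zg,
                   n = reduced_density(Zg, T_from_chi(ch, bz), Z0 = Z0))
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$Z, y = .data$n,
                                    colour = factor(.data$chi))) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_d(name = "χ (µm)") +
    ggplot2::labs(x = "Z = z / bz", y = "n(Z)",
                  title = "Reduced-model axial density") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
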