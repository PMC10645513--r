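#' Axial slip velocity for the long-wavelength model
#'
#' Projects a meridional slip profile onto the axial direction,
#' \eqn{U(z) = (e_\zeta \cdot e_z)\big|_{\tau_0,\, \zeta = z/b_z}\,
#' v_s(z / b_z)}. The projection factor
#' \eqn{\tau_0 \sqrt{(1 - \zeta^2)/(\tau_0^2 - \zeta^2)}} is retained
#' exactly (it equals 1 at the equator and drops to 0 at the poles); the
#' further approximation \eqn{u_{AP} = -v_s} is made only in the reduced
#' one-dimensional model.
#'
#' @param slip A [slip_profile()].
#' @param geometry An [embryo_geometry()].
#' @return A function of `z` (\eqn{\mu m}) returning the axial wall slip
#'   \eqn{U(z)} (\eqn{\mu m\,s^{-1}} at unit amplitude).
#' @export
slip_to_axial <- function(slip, geometry) {
  assert_geometry(geometry)
  stopifnot(inherits(slip, "slip_profile"))
  tau0 <- geometry$tau0
  bz <- geometry$bz
  function(z) {
    zeta <- pmin(1, pmax(-1, z / bz))
    proj <- tau0 * sqrt((1 - zeta^2) / (tau0^2 - zeta^2))
    proj * slip_eval(slip, zeta)
  }
}

#' Long-wavelength (lubrication) flow in an elongated cell
#'
#' The leading-order flow in a closed elongated axisymmetric cell of
#' radius profile \eqn{R(z)}, driven by an axial wall slip \eqn{U(z)}:
#' locally pressure-driven pipe flow with zero net flux through every
#' cross-section,
#' \deqn{u_z(r, z) = U(z)\left[2 (r/R)^2 - 1\right], \qquad
#'   u_r(r, z) = \tfrac{1}{2} U'(z)\, r \left[1 - (r/R)^2\right] +
#'   U(z)\, R'(z)\, (r/R)^3.}
#' The solution satisfies the wall slip, exact no-penetration on the wall
#' and zero cross-sectional mass flux identically. Valid when axial length
#' scales far exceed radial ones (\eqn{|R'(z)| \ll 1}); a warning is
#' issued if the profile is steep over the bulk of the cell.
#'
#' @param slip A [slip_profile()] (projected axially via
#'   [slip_to_axial()]), or a function `U(z)` giving the axial wall slip
#'   directly.
#' @param geometry An [embryo_geometry()]; supplies the spheroidal radius
#'   profile \eqn{R(z) = b_x \sqrt{1 - (z/b_z)^2}} unless `radius` is
#'   given.
#' @param radius Optional radius profile: function `R(z)` (\eqn{\mu m}),
#'   for non-spheroidal elongated shapes. Steepness is checked over the
#'   bulk of the cell (|z| up to 0.75 `bz`); every closed shape is
#'   inevitably steep at its very poles.
#' @param radius_deriv Optional analytic `R'(z)`; by default the
#'   spheroidal derivative is used, or a fourth-order central difference
#'   for a custom `radius`.
#' @param slip_deriv Optional analytic `U'(z)`; by default a fourth-order
#'   central difference on a fine internal step.
#' @return An object of class `lubrication_flow`.
#' @export
lubrication_flow <- function(slip, geometry, radius = NULL,
                             radius_deriv = NULL, slip_deriv = NULL) {
  assert_geometry(geometry)
  bz <- geometry$bz
  U <- if (inherits(slip, "slip_profile")) {
    slip_to_axial(slip, geometry)
  } else {
    stopifnot(is.function(slip))
    slip
  }
  if (is.null(radius)) {
    bx <- geometry$bx
    radius <- function(z) bx * sqrt(pmax(0, 1 - (z / bz)^2))
    if (is.null(radius_deriv)) {
      radius_deriv <- function(z) {
        -bx * (z / bz^2) / sqrt(pmax(1e-12, 1 - (z / bz)^2))
      }
    }
  }
  if (is.null(radius_deriv)) {
    radius_deriv <- central_diff4(radius, h = 1e-4 * bz)
  }
  if (is.null(slip_deriv)) {
    slip_deriv <- central_diff4(U, h = 1e-4 * bz)
  }
  slope <- max(abs(radius_deriv(seq(-0.75 * bz, 0.75 * bz, length.out = 101))))
  if (slope > 0.5) {
    warning(sprintf(
      "max |R'(z)| = %.2f on the bulk of the cell; the long-wavelength ",
      slope), "approximation assumes |R'| << 1.", call. = FALSE)
  }
  structure(
    list(geometry = geometry, U = U, dU = slip_deriv,
         radius = radius, dR = radius_deriv,
         slip_name = if (inherits(slip, "slip_profile")) slip$name else "custom"),
    class = "lubrication_flow"
  )
}

# 4th-order central difference closure
central_diff4 <- function(f, h) {
  function(z) (-f(z + 2 * h) + 8 * f(z + h) - 8 * f(z - h) + f(z - 2 * h)) /
    (12 * h)
}

#' @export
print.lubrication_flow <- function(x, ...) {
  cat(sprintf("<lubrication_flow> slip '%s', bz = %g um\n",
              x$slip_name, x$geometry$bz))
  invisible(x)
}

#' @rdname flow_velocity
#' @param pole_margin Axial evaluation is restricted to
#'   \eqn{|z| \le (1 - \epsilon) b_z} (lubrication method only); points in
#'   the pole caps are clamped to the margin.
#' @export
flow_velocity.lubrication_flow <- function(flow, points,
                                           pole_margin = 1e-6, ...) {
  stopifnot(all(c("r", "z") %in% names(points)))
  bz <- flow$geometry$bz
  z <- pmin((1 - pole_margin) * bz, pmax(-(1 - pole_margin) * bz, points$z))
  r <- points$r
  R <- flow$radius(z)
  if (any(r > R * (1 + 1e-9))) {
    stop("point(s) outside the cell: r > R(z).", call. = FALSE)
  }
  x2 <- (r / R)^2
  U <- flow$U(z)
  tibble::tibble(
    r = points$r, z = points$z,
    u_r = 0.5 * flow$dU(z) * r * (1 - x2) + U * flow$dR(z) * x2 * (r / R),
    u_z = U * (2 * x2 - 1)
  )
}

#' @rdname streamfunction
#' @export
streamfunction.lubrication_flow <- function(flow, points, ...) {
  stopifnot(all(c("r", "z") %in% names(points)))
  bz <- flow$geometry$bz
  z <- pmin(0.999999 * bz, pmax(-0.999999 * bz, points$z))
  r <- points$r
  R <- flow$radius(z)
  # u_z = (1/r) dpsi/dr  =>  psi = U r^2 ((r/R)^2 - 1) / 2
  tibble::tibble(
    r = points$r, z = points$z,
    psi = flow$U(z) * r^2 * ((r / R)^2 - 1) / 2
  )
}

#' Compare the long-wavelength and exact flow solutions
#'
#' Evaluates both solvers for the same geometry and slip, and reports the
#' maximum pointwise error of each velocity component normalized by that
#' component's maximum magnitude in the exact solution,
#' \eqn{\max |u_i^{lub} - u_i^{exact}| / \max |u_i^{exact}|}. The
#' comparison grid spans the interior with a pole cap of 1\% of
#' \eqn{b_z} excluded.
#'
#' @param slip A [slip_profile()].
#' @param geometry An [embryo_geometry()].
#' @param nmax Truncation order of the exact solution.
#' @param n_z,n_r Grid resolution.
#' @return A list with `max_error_uz`, `max_error_ur` (dimensionless
#'   fractions) and `field`, a tibble with columns `r_um`, `z_um`,
#'   `err_uz`, `err_ux` of normalized pointwise errors.
#' @export
compare_to_exact <- function(slip, geometry, nmax = 14, n_z = 60, n_r = 30) {
  assert_geometry(geometry)
  exact <- stokes_flow(slip, geometry, nmax = nmax)
  lub <- lubrication_flow(slip, geometry)
  zg <- seq(-0.99 * geometry$bz, 0.99 * geometry$bz, length.out = n_z)
  grid <- purrr::map_dfr(zg, function(z) {
    rmax <- geometry$bx * sqrt(1 - (z / geometry$bz)^2)
    tibble::tibble(r = seq(0, rmax, length.out = n_r), z = z)
  })
  ve <- flow_velocity(exact, grid)
  vl <- flow_velocity(lub, grid)
  mz <- max(abs(ve$u_z))
  mr <- max(abs(ve$u_r))
  err_z <- abs(vl$u_z - ve$u_z) / mz
  err_r <- abs(vl$u_r - ve$u_r) / mr
  list(
    max_error_uz = max(err_z),
    max_error_ur = max(err_r),
    field = tibble::tibble(r_um = grid$r, z_um = grid$z,
                           err_uz = err_z, err_ux = err_r)
  )
}
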