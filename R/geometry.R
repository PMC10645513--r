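#' Prolate spheroidal cell geometry
#'
#' Defines the model cell: a rigid prolate spheroid with semi-minor axis
#' `bx` (transverse) and semi-major axis `bz` (along the long,
#' anterior–posterior axis). The associated modified prolate spheroidal
#' coordinates \eqn{(\tau, \zeta, \phi)} have semi-focal distance
#' \eqn{c = \sqrt{b_z^2 - b_x^2}} and the cell boundary is the isosurface
#' \eqn{\tau = \tau_0 = b_z / c}; the interior is \eqn{1 \le \tau < \tau_0},
#' with \eqn{\tau = 1} the focal segment on the axis. On the boundary,
#' \eqn{\zeta} is the rescaled axial position \eqn{z / b_z}.
#'
#' @param bx Semi-minor axis, \eqn{\mu m}.
#' @param bz Semi-major axis, \eqn{\mu m}; must exceed `bx`.
#' @return An object of class `embryo_geometry`: a list with fields `bx`,
#'   `bz`, `c` (semi-focal distance, \eqn{\mu m}) and `tau0`
#'   (dimensionless boundary coordinate).
#' @examples
#' embryo_geometry(110, 270) # Drosophila embryo: c = 246.6, tau0 = 1.095
#' embryo_geometry(3, 5)     # c = 4, tau0 = 1.25
#' @export
embryo_geometry <- function(bx = 110, bz = 270) {
  stopifnot(is.numeric(bx), is.numeric(bz), length(bx) == 1L, length(bz) == 1L)
  if (!(bx > 0)) stop("`bx` must be positive.", call. = FALSE)
  if (!(bz > bx)) {
    stop("`bz` must exceed `bx`: a prolate spheroid is elongated along z ",
         "(bx >= bz would be degenerate or oblate).", call. = FALSE)
  }
  cc <- sqrt(bz^2 - bx^2)
  structure(
    list(bx = bx, bz = bz, c = cc, tau0 = bz / cc),
    class = "embryo_geometry"
  )
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat(sprintf(
    "<embryo_geometry> bx = %g um, bz = %g um, c = %.4g um, tau0 = %.6g\n",
    x$bx, x$bz, x$c, x$tau0
  ))
  invisible(x)
}

is_geometry <- function(g) inherits(g, "embryo_geometry")

assert_geometry <- function(g) {
  if (!is_geometry(g)) stop("`geometry` must be an `embryo_geometry` object.",
                            call. = FALSE)
  invisible(g)
}

# Fast internal converters on bare vectors ------------------------------

# (tau, zeta) -> (r, z)
sph_to_cyl_ <- function(tau, zeta, g) {
  list(
    r = g$c * sqrt(pmax(0, tau^2 - 1)) * sqrt(pmax(0, 1 - zeta^2)),
    z = g$c * tau * zeta
  )
}

# (r, z) -> (tau, zeta); numerically stable focal-distance form. Points with
# r = 0 fall out correctly: on the focal segment tau = 1 and zeta = z / c,
# beyond the foci zeta = +-1 and tau = |z| / c.
cyl_to_sph_ <- function(r, z, g) {
  d1 <- sqrt(r^2 + (z + g$c)^2)
  d2 <- sqrt(r^2 + (z - g$c)^2)
  list(
    tau  = pmax(1, (d1 + d2) / (2 * g$c)),
    zeta = pmin(1, pmax(-1, (d1 - d2) / (2 * g$c)))
  )
}

#' Convert spheroidal coordinates to cylindrical coordinates
#'
#' Maps points \eqn{(\tau, \zeta, \phi)} to cylindrical polars
#' \eqn{(r, z, \phi)} via \eqn{r = c\sqrt{(\tau^2-1)(1-\zeta^2)}},
#' \eqn{z = c\,\tau\,\zeta}.
#'
#' @param points A data frame with columns `tau` and `zeta` (and optionally
#'   `phi`, carried through unchanged).
#' @param geometry An [embryo_geometry()].
#' @return A tibble with columns `r`, `z` (\eqn{\mu m}) and `phi` if present,
#'   one row per input point.
#' @export
to_cylindrical <- function(points, geometry) {
  assert_geometry(geometry)
  stopifnot(all(c("tau", "zeta") %in% names(points)))
  if (any(points$tau < 1 - 1e-12) || any(abs(points$zeta) > 1 + 1e-12)) {
    stop("spheroidal points require tau >= 1 and |zeta| <= 1.", call. = FALSE)
  }
  cy <- sph_to_cyl_(points$tau, points$zeta, geometry)
  out <- tibble::tibble(r = cy$r, z = cy$z)
  if ("phi" %in% names(points)) out$phi <- points$phi
  out
}

#' Convert cylindrical coordinates to spheroidal coordinates
#'
#' Inverse of [to_cylindrical()], defined for points inside or on the
#' spheroid. Uses the focal-distance identities, which are exact on the
#' axis and on the focal segment where the direct inversion degenerates.
#'
#' @param points A data frame with columns `r` and `z` (\eqn{\mu m};
#'   optionally `phi`).
#' @param geometry An [embryo_geometry()].
#' @param tol Relative tolerance on \eqn{\tau > \tau_0} before a point is
#'   rejected as outside the cell.
#' @return A tibble with columns `tau`, `zeta` (and `phi` if present).
#' @export
to_spheroidal <- function(points, geometry, tol = 1e-8) {
  assert_geometry(geometry)
  stopifnot(all(c("r", "z") %in% names(points)))
  if (any(points$r < 0)) stop("`r` must be non-negative.", call. = FALSE)
  sp <- cyl_to_sph_(points$r, points$z, geometry)
  if (any(sp$tau > geometry$tau0 * (1 + tol))) {
    stop("point(s) outside the spheroid (tau > tau0).", call. = FALSE)
  }
  out <- tibble::tibble(tau = pmin(sp$tau, geometry$tau0), zeta = sp$zeta)
  if ("phi" %in% names(points)) out$phi <- points$phi
  out
}

#' Lamé metric coefficients of the spheroidal coordinates
#'
#' Returns \eqn{h_\tau = c\sqrt{(\tau^2-\zeta^2)/(\tau^2-1)}},
#' \eqn{h_\zeta = c\sqrt{(\tau^2-\zeta^2)/(1-\zeta^2)}} and
#' \eqn{h_\phi = c\sqrt{(\tau^2-1)(1-\zeta^2)}}. The coefficients
#' degenerate on the symmetry axis (\eqn{|\zeta| = 1}, where
#' \eqn{h_\zeta \to \infty}, \eqn{h_\phi \to 0}) and on the focal segment
#' (\eqn{\tau = 1}); such points are rejected rather than returning
#' non-finite values.
#'
#' @inheritParams to_cylindrical
#' @return A tibble with columns `h_tau`, `h_zeta`, `h_phi` (\eqn{\mu m}).
#' @export
metric_coefficients <- function(points, geometry) {
  assert_geometry(geometry)
  stopifnot(all(c("tau", "zeta") %in% names(points)))
  tau <- points$tau; zeta <- points$zeta
  if (any(tau <= 1) || any(abs(zeta) >= 1)) {
    stop("metric coefficients degenerate on the axis (|zeta| = 1) and the ",
         "focal segment (tau = 1); evaluate strictly inside the open domain.",
         call. = FALSE)
  }
  cc <- geometry$c
  tibble::tibble(
    h_tau  = cc * sqrt((tau^2 - zeta^2) / (tau^2 - 1)),
    h_zeta = cc * sqrt((tau^2 - zeta^2) / (1 - zeta^2)),
    h_phi  = cc * sqrt((tau^2 - 1) * (1 - zeta^2))
  )
}

#' Spheroidal basis vectors in cylindrical components
#'
#' The orthonormal frame \eqn{(e_\tau, e_\zeta)} expressed in cylindrical
#' components \eqn{(e_r, e_z)}:
#' \deqn{e_\tau = \sqrt{\frac{\tau^2-1}{\tau^2-\zeta^2}}
#'   \left(\tau\sqrt{\frac{1-\zeta^2}{\tau^2-1}}\, e_r + \zeta\, e_z\right),
#'   \quad
#'   e_\zeta = \sqrt{\frac{1-\zeta^2}{\tau^2-\zeta^2}}
#'   \left(-\zeta\sqrt{\frac{\tau^2-1}{1-\zeta^2}}\, e_r + \tau\, e_z\right).}
#' \eqn{e_\tau} is the outward normal on isosurfaces of \eqn{\tau}
#' (in particular on the cell boundary), \eqn{e_\zeta} the meridional
#' tangent.
#'
#' @inheritParams metric_coefficients
#' @return A tibble with columns `e_tau_r`, `e_tau_z`, `e_zeta_r`,
#'   `e_zeta_z`.
#' @export
basis_vectors <- function(points, geometry) {
  assert_geometry(geometry)
  stopifnot(all(c("tau", "zeta") %in% names(points)))
  tau <- points$tau; zeta <- points$zeta
  if (any(tau <= 1) || any(abs(zeta) >= 1)) {
    stop("basis vectors degenerate on the axis and focal segment; evaluate ",
         "strictly inside the open domain.", call. = FALSE)
  }
  den <- sqrt(tau^2 - zeta^2)
  tibble::tibble(
    e_tau_r  = tau * sqrt(1 - zeta^2) / den,
    e_tau_z  = zeta * sqrt(tau^2 - 1) / den,
    e_zeta_r = -zeta * sqrt(tau^2 - 1) / den,
    e_zeta_z = tau * sqrt(1 - zeta^2) / den
  )
}
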