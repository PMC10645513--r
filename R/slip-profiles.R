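#' Cortical slip-velocity profiles
#'
#' The flow inside the model cell is driven by a prescribed axisymmetric
#' tangential velocity \eqn{v_s(\zeta)} on the boundary, directed along the
#' meridional tangent \eqn{e_\zeta}. A `slip_profile` wraps the shape
#' function (at unit amplitude, \eqn{\mu m\,s^{-1}} per unit of the
#' cortical amplitude \eqn{V}) together with a name used by the fixture
#' catalogue. Physically sensible profiles vanish at the poles
#' \eqn{\zeta = \pm 1} (no sources or sinks of cortical material there);
#' a profile that does not is accepted with a warning.
#'
#' @param shape A vectorized function of \eqn{\zeta \in [-1, 1]} returning
#'   the tangential speed at unit amplitude.
#' @param name Short identifier for printing and run logs.
#' @return An object of class `slip_profile` (callable list).
#' @seealso [slip_drosophila()], [slip_mode()], [slip_symmetric_sine()]
#' @export
slip_profile <- function(shape, name = "custom") {
  stopifnot(is.function(shape))
  ends <- shape(c(-1, 1))
  if (any(!is.finite(ends))) {
    stop("slip profile must be finite at the poles zeta = +-1.", call. = FALSE)
  }
  if (any(abs(ends) > 1e-8)) {
    warning("slip profile does not vanish at the poles; this implies ",
            "cortical sources/sinks at zeta = +-1.", call. = FALSE)
  }
  structure(list(shape = shape, name = name), class = "slip_profile")
}

#' @export
print.slip_profile <- function(x, ...) {
  cat(sprintf("<slip_profile> %s\n", x$name))
  invisible(x)
}

slip_eval <- function(vs, zeta) {
  stopifnot(inherits(vs, "slip_profile"))
  vs$shape(zeta)
}

#' Drosophila embryo cortical slip shape
#'
#' The shifted-sine fit to the measured cortical flow of cell cycle 6,
#' \deqn{v_s(\zeta) = -\sin(\pi\zeta + \arcsin(1/3)) - 1/3,}
#' at unit amplitude (multiply by the cortical amplitude \eqn{V(t)}, whose
#' peak in cycle 6 is about 0.3 \eqn{\mu m\,s^{-1}}). The shape vanishes
#' at both poles and has a single interior zero at
#' \eqn{\zeta^* = -2\arcsin(1/3)/\pi \approx -0.2163}, the stagnation point
#' toward which the cortex converges and from which the interior flow
#' spreads material along the axis.
#'
#' @return A [slip_profile()].
#' @examples
#' vs <- slip_drosophila()
#' vs$shape(stagnation_zeta()) # 0
#' @export
slip_drosophila <- function() {
  slip_profile(
    function(zeta) -sin(pi * zeta + asin(1 / 3)) - 1 / 3,
    name = "drosophila"
  )
}

#' Stagnation point of the Drosophila slip profile
#'
#' The interior zero of the cortical flow shape,
#' \eqn{\zeta^* = -2\arcsin(1/3)/\pi \approx -0.2163}. On the long axis
#' this is (to the long-wavelength approximation) the point where the
#' axial cytoplasmic flow vanishes, used as the centre of the initial
#' nuclear cloud.
#'
#' @return A single numeric value.
#' @export
stagnation_zeta <- function() -2 * asin(1 / 3) / pi

#' Single-mode slip profiles
#'
#' The slip profile that excites exactly one term of the boundary
#' expansion: \eqn{v_s(\zeta) = \tau_0 (\tau_0^2 - \zeta^2)^{-1/2}
#' P^1_m(\zeta)}, i.e. mode coefficients \eqn{B_n = \delta_{nm}}. Mode `m`
#' drives a flow with exactly `m` meridional vortices.
#'
#' @param m Mode index, \eqn{m \ge 1}.
#' @param geometry An [embryo_geometry()] (the profile depends on
#'   \eqn{\tau_0}).
#' @return A [slip_profile()].
#' @export
slip_mode <- function(m, geometry) {
  assert_geometry(geometry)
  stopifnot(length(m) == 1L, m >= 1, m == as.integer(m))
  m <- as.integer(m)
  tau0 <- geometry$tau0
  slip_profile(
    function(zeta) tau0 / sqrt(tau0^2 - zeta^2) * assoc_legendre_P1(m, zeta),
    name = sprintf("mode-%d", m)
  )
}

#' Symmetric sine slip profile
#'
#' The symmetrized cortical profile used by the one-dimensional reduced
#' model: \eqn{v_s(\zeta) = -\sin(\pi\zeta)}, at unit amplitude. It is the
#' Drosophila shape with its phase shift and offset removed, preserving the
#' sine amplitude.
#'
#' @return A [slip_profile()].
#' @export
slip_symmetric_sine <- function() {
  slip_profile(function(zeta) -sin(pi * zeta), name = "symmetric-sine")
}

#' Slip profile from tabulated samples
#'
#' Builds a [slip_profile()] by monotone-free spline interpolation of
#' sampled \eqn{(\zeta, v_s)} pairs, clamping evaluation to the sampled
#' range.
#'
#' @param data A data frame with columns `zeta` and `vs`.
#' @param name Profile name.
#' @return A [slip_profile()].
#' @export
slip_tabulated <- function(data, name = "tabulated") {
  stopifnot(all(c("zeta", "vs") %in% names(data)))
  f <- stats::splinefun(data$zeta, data$vs, method = "natural")
  rng <- range(data$zeta)
  slip_profile(function(zeta) f(pmin(pmax(zeta, rng[1]), rng[2])), name = name)
}
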