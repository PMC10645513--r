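# Legendre and Gegenbauer machinery used by the semiseparable streamfunction
# series. Everything here is valid for arguments beyond [-1, 1] as well: the
# same polynomials are evaluated on the tau side of the solution, where
# tau >= 1.

# P_0..P_nmax at x; returns length(x) x (nmax + 1) matrix.
legendre_P_all <- function(nmax, x) {
  P <- matrix(0, length(x), nmax + 1L)
  P[, 1L] <- 1
  if (nmax >= 1L) P[, 2L] <- x
  if (nmax >= 2L) {
    for (k in 2:nmax) {
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  P
}

# dP_0..dP_nmax via P'_n = P'_{n-2} + (2n - 1) P_{n-1} (no endpoint
# degeneracy, unlike the (1 - x^2) form).
legendre_dP_all <- function(nmax, x) {
  P <- legendre_P_all(nmax, x)
  D <- matrix(0, length(x), nmax + 1L)
  if (nmax >= 1L) D[, 2L] <- 1
  if (nmax >= 2L) {
    for (k in 2:nmax) D[, k + 1L] <- D[, k - 1L] + (2 * k - 1) * P[, k]
  }
  D
}

# G_0..G_nmax; G_0 = 1, G_1 = -x, G_n = (P_{n-2} - P_n)/(2n - 1) for n >= 2.
gegenbauer_all <- function(nmax, x) {
  P <- legendre_P_all(nmax, x)
  G <- matrix(0, length(x), nmax + 1L)
  G[, 1L] <- 1
  if (nmax >= 1L) G[, 2L] <- -x
  if (nmax >= 2L) {
    for (k in 2:nmax) G[, k + 1L] <- (P[, k - 1L] - P[, k + 1L]) / (2 * k - 1)
  }
  G
}

#' Gegenbauer function of the first kind
#'
#' Evaluates the Gegenbauer function of the first kind \eqn{G_n(x)} of
#' degree \eqn{-1/2}, the basis in which the axisymmetric Stokes
#' streamfunction is expanded. For \eqn{n \ge 2},
#' \eqn{G_n(x) = (P_{n-2}(x) - P_n(x))/(2n - 1)} in terms of Legendre
#' polynomials, so that \eqn{G_n(\pm 1) = 0}; the low orders are
#' \eqn{G_0 = 1} and \eqn{G_1 = -x}. The representation is polynomial and
#' therefore extends analytically to arguments outside \eqn{[-1, 1]},
#' which is how the radial (\eqn{\tau}) side of the series is evaluated.
#'
#' The functions satisfy the weighted orthogonality
#' \deqn{\int_{-1}^{1} \frac{G_n(x) G_m(x)}{1 - x^2}\,dx =
#'   \frac{2}{n(n-1)(2n-1)}\,\delta_{nm}, \qquad n, m \ge 2,}
#' (the normalization constant was verified against direct quadrature) and
#' the derivative identity \eqn{G_n'(x) = -P_{n-1}(x)}.
#'
#' @param n Non-negative integer order.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of \eqn{G_n(x)} values.
#' @seealso [assoc_legendre_P1()] for the associated Legendre functions tied
#'   to \eqn{G_{n+1}} by \eqn{\sqrt{1-x^2}\,P^1_l(x) = -l(l+1) G_{l+1}(x)}.
#' @examples
#' gegenbauer_G(2, 0)        # (1 - 0^2)/2 = 0.5
#' gegenbauer_G(5, c(-1, 1)) # 0 at both poles
#' @export
gegenbauer_G <- function(n, x) {
  stopifnot(length(n) == 1L, n >= 0, n == as.integer(n))
  gegenbauer_all(max(n, 1L), x)[, n + 1L]
}

#' Derivative of the Gegenbauer function of the first kind
#'
#' \eqn{G_n'(x) = -P_{n-1}(x)} for \eqn{n \ge 1} (and \eqn{G_0' = 0}),
#' used for the analytic velocity field; derivatives are never taken by
#' finite differences in the solver.
#'
#' @inheritParams gegenbauer_G
#' @return Numeric vector of \eqn{G_n'(x)} values.
#' @export
gegenbauer_G_deriv <- function(n, x) {
  stopifnot(length(n) == 1L, n >= 0, n == as.integer(n))
  if (n == 0L) return(rep(0, length(x)))
  -legendre_P_all(n - 1L, x)[, n]
}

#' Associated Legendre function of order one
#'
#' Evaluates \eqn{P^1_n(x)} with the Condon–Shortley phase,
#' \eqn{P^1_n(x) = -\sqrt{1 - x^2}\, P_n'(x)}. This sign convention is the
#' one under which the identity
#' \eqn{\sqrt{1 - x^2}\, P^1_l(x) = -l(l+1)\, G_{l+1}(x)} holds exactly,
#' which ties the slip-velocity expansion to the streamfunction basis; the
#' identity (not the convention name) is what the tests pin down.
#'
#' @param n Integer order, \eqn{n \ge 1}.
#' @param x Numeric vector in \eqn{[-1, 1]}.
#' @return Numeric vector of \eqn{P^1_n(x)} values.
#' @export
assoc_legendre_P1 <- function(n, x) {
  stopifnot(length(n) == 1L, n >= 1, n == as.integer(n), all(abs(x) <= 1))
  -sqrt(pmax(0, 1 - x^2)) * legendre_dP_all(n, x)[, n + 1L]
}
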