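#' One-dimensional reduced model of axial nuclear transport
#'
#' Projecting transport onto the anterior–posterior axis and replacing the
#' cortical profile by its symmetrized sine, the axial nuclear density
#' \eqn{n(Z, T)} (with \eqn{Z = z/b_z \in [-1, 1]} and rescaled time
#' \eqn{T = \pi\chi/b_z}) obeys the conservation law
#' \deqn{\partial_T n + \partial_Z\!\left[\frac{\sin(\pi Z)}{\pi}\, n\right] = 0,}
#' solved exactly by the method of characteristics:
#' \deqn{n(Z, T) = e^{-T}\, n_0\!\left(\frac{2}{\pi}\arctan\!\big(e^{-T}
#'   \tan\tfrac{\pi Z}{2}\big)\right)
#'   \frac{\tan^2(\pi Z/2) + 1}{e^{-2T}\tan^2(\pi Z/2) + 1}.}
#' `reduced_density` evaluates this closed form for an arbitrary initial
#' density `n0`; for \eqn{|Z| > 1/2} the expression is reformulated in
#' terms of \eqn{\cot(\pi Z / 2)} so the evaluation stays numerically
#' stable up to the poles, where the characteristic map fixes
#' \eqn{Z = \pm 1}.
#'
#' @param Z Dimensionless axial positions in \eqn{[-1, 1]}.
#' @param T Rescaled time, \eqn{T \ge 0} (scalar).
#' @param n0 Initial density: a function of \eqn{Z}, normalized so
#'   \eqn{\int_{-1}^{1} n_0\, dZ = 1}. Default: the semicircular cloud
#'   [reduced_initial_density()] of half-width `Z0`.
#' @param Z0 Half-width of the default initial cloud (dimensionless;
#'   default \eqn{60/270}, a 60 \eqn{\mu m} cloud in the Drosophila
#'   embryo).
#' @return Density values \eqn{n(Z, T)} (dimensionless).
#' @examples
#' Z <- seq(-1, 1, by = 0.01)
#' n <- reduced_density(Z, T = 1)
#' sum(n) * 0.01  # mass ~ 1
#' @export
reduced_density <- function(Z, T, n0 = NULL, Z0 = 60 / 270) {
  stopifnot(T >= 0, length(T) == 1L, all(abs(Z) <= 1 + 1e-12))
  if (is.null(n0)) n0 <- function(Z) reduced_initial_density(Z, Z0)
  Z <- pmin(1, pmax(-1, Z))
  eT <- exp(-T)
  out <- numeric(length(Z))
  inner <- abs(Z) <= 0.5
  if (any(inner)) {
    tg <- tan(pi * Z[inner] / 2)
    Zm <- 2 / pi * atan(eT * tg)
    out[inner] <- eT * n0(Zm) * (tg^2 + 1) / (eT^2 * tg^2 + 1)
  }
  if (any(!inner)) {
    # cot form: tan = 1/ct, arctan(eT/ct) = sign(Z) pi/2 - arctan(ct/eT)
    zo <- Z[!inner]
    ct <- tan(pi * (sign(zo) - zo) / 2)      # = cot(pi Z / 2), signed
    Zm <- sign(zo) - 2 / pi * atan(ct / eT)
    out[!inner] <- eT * n0(Zm) * (1 + ct^2) / (eT^2 + ct^2)
  }
  out
}

#' Semicircular initial axial density
#'
#' \deqn{n_0(Z) = \frac{\sqrt{\max(0, Z_0^2 - Z^2)}}{\pi Z_0^2 / 2},}
#' the axial projection of a uniform disk-shaped cloud of dimensionless
#' radius \eqn{Z_0}, normalized to unit mass on \eqn{[-1, 1]}. This is
#' the one-dimensional image of the initial tracer cloud used by the full
#' transport simulations (see [sample_nuclei()]).
#'
#' @param Z Dimensionless axial positions.
#' @param Z0 Cloud half-width, \eqn{0 < Z_0 < 1}.
#' @return Density values.
#' @export
reduced_initial_density <- function(Z, Z0 = 60 / 270) {
  stopifnot(Z0 > 0, Z0 < 1)
  sqrt(pmax(0, Z0^2 - Z^2)) / (pi * Z0^2 / 2)
}

#' Rescaled time of the reduced model
#'
#' \eqn{T = \pi \chi / b_z}: converts the rescaled time \eqn{\chi}
#' (\eqn{\mu m}) of the three-dimensional model to the dimensionless time
#' of the one-dimensional model.
#'
#' @param chi Rescaled time, \eqn{\mu m}.
#' @param bz Semi-major axis, \eqn{\mu m}.
#' @return Dimensionless \eqn{T}.
#' @export
T_from_chi <- function(chi, bz) {
  stopifnot(all(chi >= 0), bz > 0)
  pi * chi / bz
}

#' One-dimensional homogeneity variance
#'
#' \deqn{\Phi_{1D} = \int_{-1}^{1} [n(Z) - \bar n]^2\, dZ,
#'   \qquad \bar n \equiv 1/2,}
#' the axial variance of the reduced density (the mean is 1/2 because mass
#' is conserved at 1 on \eqn{[-1, 1]}). Computed by composite Simpson
#' quadrature.
#'
#' @param n Density values on a uniform grid spanning \eqn{[-1, 1]} with
#'   an odd number of points, or a function of \eqn{Z}.
#' @param Z_grid The grid (required when `n` is a vector; default 2001
#'   uniform points when `n` is a function).
#' @return \eqn{\Phi_{1D}} (dimensionless).
#' @export
phi_1d <- function(n, Z_grid = NULL) {
  if (is.function(n)) {
    if (is.null(Z_grid)) Z_grid <- seq(-1, 1, length.out = 2001)
    n <- n(Z_grid)
  }
  stopifnot(!is.null(Z_grid), length(n) == length(Z_grid),
            length(Z_grid) %% 2 == 1)
  if (abs(Z_grid[1] + 1) > 1e-9 || abs(Z_grid[length(Z_grid)] - 1) > 1e-9) {
    stop("`Z_grid` must span [-1, 1].", call. = FALSE)
  }
  h <- Z_grid[2] - Z_grid[1]
  f <- (n - 0.5)^2
  m <- length(f)
  w <- rep(c(4, 2), length.out = m - 2)
  (f[1] + f[m] + sum(w * f[2:(m - 1)])) * h / 3
}

#' Reduced-model variance curve and optimal spreading
#'
#' Evaluates \eqn{\Phi_{1D}(\chi)} of the closed-form solution over a
#' grid of \eqn{\chi}, and locates the optimum (argmin, refined by a
#' local quadratic fit). For the Drosophila embryo
#' (\eqn{b_z = 270\,\mu m}, \eqn{Z_0 = 60/270}) the variance is minimized
#' at \eqn{\chi \approx 159\,\mu m}.
#'
#' @param bz Semi-major axis, \eqn{\mu m}.
#' @param Z0 Initial cloud half-width (dimensionless).
#' @param chi_grid Grid of \eqn{\chi} values, \eqn{\mu m}.
#' @param n_Z Number of Simpson quadrature points (odd).
#' @return An object of class `reduced_variance_curve`: tibble with
#'   columns `chi`, `phi`, plus attributes `chi_star`, `bz`, `Z0`.
#' @export
reduced_variance_curve <- function(bz = 270, Z0 = 60 / 270,
                                   chi_grid = seq(0, 400, by = 1),
                                   n_Z = 2001) {
  Zg <- seq(-1, 1, length.out = n_Z)
  phi <- vapply(chi_grid, function(chi) {
    phi_1d(reduced_density(Zg, T_from_chi(chi, bz), Z0 = Z0), Zg)
  }, numeric(1))
  out <- tibble::tibble(chi = chi_grid, phi = phi)
  class(out) <- c("reduced_variance_curve", class(out))
  attr(out, "chi_star") <- refine_argmin(chi_grid, phi, half_window = 5)
  attr(out, "bz") <- bz
  attr(out, "Z0") <- Z0
  out
}

#' Optimal chi of the reduced model
#'
#' @param bz,Z0,chi_grid As in [reduced_variance_curve()].
#' @return `chi_star` in \eqn{\mu m}.
#' @export
optimal_chi_1d <- function(bz = 270, Z0 = 60 / 270,
                           chi_grid = seq(0, 400, by = 1)) {
  attr(reduced_variance_curve(bz, Z0, chi_grid), "chi_star")
}
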