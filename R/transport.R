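#' Sample an initial cloud of model nuclei
#'
#' Draws `n` passive tracers uniformly from a disk of radius
#' `radius` lying in a meridional plane (i.e. a plane containing the long
#' axis), centred on the axis at `centre_z`. Each tracer is then given an
#' independent uniform azimuth about the long axis, which leaves both the
#' axial density and the axisymmetric dynamics unchanged. The axial
#' projection of this cloud is the semicircular density
#' \eqn{\propto \sqrt{radius^2 - (z - z_c)^2}} that the one-dimensional
#' reduced model adopts as its initial condition. The default centre is
#' the stagnation point of the Drosophila cortical flow,
#' \eqn{z_c = b_z\,\zeta^*} with \eqn{\zeta^* = -2\arcsin(1/3)/\pi}.
#'
#' @param n Number of tracers.
#' @param geometry An [embryo_geometry()].
#' @param seed RNG seed recorded with the cloud.
#' @param centre_z Axial centre of the cloud, \eqn{\mu m}.
#' @param radius Cloud radius, \eqn{\mu m} (default 60, the observed size
#'   of the nuclear cloud at the start of cell cycle 4).
#' @return A tibble with columns `particle`, `x`, `y`, `z` (\eqn{\mu m})
#'   and attributes `seed`, `centre_z`, `radius`.
#' @export
sample_nuclei <- function(n, geometry, seed,
                          centre_z = geometry$bz * stagnation_zeta(),
                          radius = 60) {
  assert_geometry(geometry)
  stopifnot(n >= 1)
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(2 * 2 * n, -1, 1), ncol = 2)
    cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(n), , drop = FALSE] * radius
  phi <- stats::runif(n, 0, 2 * pi)
  a <- pts[, 1]                         # in-plane transverse offset
  out <- tibble::tibble(
    particle = seq_len(n),
    x = a * cos(phi),
    y = a * sin(phi),
    z = centre_z + pts[, 2]
  )
  bad <- (out$x^2 + out$y^2) / geometry$bx^2 + out$z^2 / geometry$bz^2 >= 1
  if (any(bad)) {
    stop("initial cloud extends outside the spheroid; reduce `radius` or ",
         "move `centre_z`.", call. = FALSE)
  }
  attr(out, "seed") <- seed
  attr(out, "centre_z") <- centre_z
  attr(out, "radius") <- radius
  out
}

# velocity in Cartesian components for bare vectors
vel_cartesian_ <- function(flow, x, y, z) {
  r <- sqrt(x^2 + y^2)
  sp <- cyl_to_sph_(r, z, flow$geometry)
  v <- eval_velocity_sph(flow, pmin(sp$tau, flow$geometry$tau0), sp$zeta)
  ct <- ifelse(r > 0, x / r, 0)
  st <- ifelse(r > 0, y / r, 0)
  list(ux = v$u_r * ct, uy = v$u_r * st, uz = v$u_z)
}

# Advance bare coordinate vectors from chi to chi + steps of dchi using
# classic RK4; projects any escapee radially just inside the boundary and
# counts projections.
advect_steps_ <- function(flow, x, y, z, dchi, n_steps) {
  g <- flow$geometry
  n_proj <- 0L
  for (s in seq_len(n_steps)) {
    k1 <- vel_cartesian_(flow, x, y, z)
    k2 <- vel_cartesian_(flow, x + dchi / 2 * k1$ux, y + dchi / 2 * k1$uy,
                         z + dchi / 2 * k1$uz)
    k3 <- vel_cartesian_(flow, x + dchi / 2 * k2$ux, y + dchi / 2 * k2$uy,
                         z + dchi / 2 * k2$uz)
    k4 <- vel_cartesian_(flow, x + dchi * k3$ux, y + dchi * k3$uy,
                         z + dchi * k3$uz)
    x <- x + dchi / 6 * (k1$ux + 2 * k2$ux + 2 * k3$ux + k4$ux)
    y <- y + dchi / 6 * (k1$uy + 2 * k2$uy + 2 * k3$uy + k4$uy)
    z <- z + dchi / 6 * (k1$uz + 2 * k2$uz + 2 * k3$uz + k4$uz)
    f <- (x^2 + y^2) / g$bx^2 + z^2 / g$bz^2
    out <- which(f >= 1)
    if (length(out) > 0) {
      n_proj <- n_proj + length(out)
      scl <- sqrt(f[out]) / (1 - 1e-9)
      x[out] <- x[out] / scl
      y[out] <- y[out] / scl
      z[out] <- z[out] / scl
    }
  }
  list(x = x, y = y, z = z, n_proj = n_proj)
}

#' Advect a tracer cloud in rescaled time
#'
#' Integrates \eqn{d x_i / d\chi = \hat u(x_i)} for every tracer, where
#' \eqn{\hat u} is the unit-amplitude cytoplasmic flow and
#' \eqn{\chi = \int_0^t V(t')\,dt'} is the rescaled time (units of
#' length): because Stokes flow responds instantaneously to its boundary
#' conditions, the trajectory depends on the cortical amplitude history
#' \eqn{V(t)} only through \eqn{\chi}. Uses classic fixed-step RK4
#' (default step 0.5 \eqn{\mu m}); each requested snapshot value of
#' \eqn{\chi} is hit exactly by a final shortened step. Tracers that land
#' outside the spheroid by integration error are projected radially just
#' inside the boundary; the exact flow satisfies no-penetration, so such
#' projections are rare and tiny (the count is recorded in the
#' `n_projected` attribute).
#'
#' @param cloud A tibble from [sample_nuclei()] (columns `particle`, `x`,
#'   `y`, `z`).
#' @param flow A [stokes_flow()] (unit amplitude).
#' @param chi Increasing vector of snapshot values of \eqn{\chi},
#'   \eqn{\mu m}.
#' @param dchi RK4 step, \eqn{\mu m}.
#' @return A long tibble with columns `particle`, `chi`, `x`, `y`, `z`
#'   containing one snapshot per requested \eqn{\chi} (plus \eqn{\chi = 0}
#'   if not requested), with attribute `n_projected`.
#' @export
advect <- function(cloud, flow, chi, dchi = 0.5) {
  stopifnot(inherits(flow, "stokes_flow"),
            all(c("x", "y", "z") %in% names(cloud)),
            all(diff(chi) > 0), all(chi >= 0))
  x <- cloud$x; y <- cloud$y; z <- cloud$z
  id <- if ("particle" %in% names(cloud)) cloud$particle else seq_along(x)
  snaps <- vector("list", length(chi))
  cur <- 0
  n_proj <- 0L
  for (i in seq_along(chi)) {
    span <- chi[i] - cur
    n_full <- floor(span / dchi + 1e-12)
    if (n_full > 0) {
      st <- advect_steps_(flow, x, y, z, dchi, n_full)
      x <- st$x; y <- st$y; z <- st$z; n_proj <- n_proj + st$n_proj
    }
    rem <- span - n_full * dchi
    if (rem > 1e-9) {
      st <- advect_steps_(flow, x, y, z, rem, 1L)
      x <- st$x; y <- st$y; z <- st$z; n_proj <- n_proj + st$n_proj
    }
    cur <- chi[i]
    snaps[[i]] <- tibble::tibble(particle = id, chi = chi[i],
                                 x = x, y = y, z = z)
  }
  out <- dplyr::bind_rows(snaps)
  attr(out, "n_projected") <- n_proj
  out
}

#' Axial kernel density of a tracer cloud
#'
#' The continuous axial density obtained by placing a Gaussian kernel of
#' bandwidth `bandwidth` at each tracer's axial position,
#' \deqn{\rho(z) = \frac{1}{N R \sqrt{2\pi}} \sum_{i=1}^{N}
#'   e^{-(z - z_i)^2 / 2 R^2}.}
#' Integrates to 1 over the whole real line.
#'
#' @param z_positions Numeric vector of axial tracer positions,
#'   \eqn{\mu m}.
#' @param bandwidth Kernel length scale \eqn{R}, \eqn{\mu m} (7
#'   \eqn{\approx} one nuclear diameter; 28 \eqn{\approx} the nuclear
#'   separation set by aster migration).
#' @param grid Evaluation grid (default 1 \eqn{\mu m} spacing over
#'   \eqn{[-b_z, b_z]} requires `geometry`).
#' @param geometry Optional [embryo_geometry()] used to build the default
#'   grid.
#' @return A tibble with columns `z`, `rho` (\eqn{\mu m^{-1}}).
#' @export
axial_density <- function(z_positions, bandwidth, grid = NULL,
                          geometry = NULL) {
  stopifnot(bandwidth > 0)
  if (is.null(grid)) {
    if (is.null(geometry)) stop("supply `grid` or `geometry`.", call. = FALSE)
    grid <- seq(-geometry$bz, geometry$bz, by = 1)
  }
  d2 <- outer(grid, z_positions, "-")^2
  rho <- rowMeans(exp(-d2 / (2 * bandwidth^2))) / (bandwidth * sqrt(2 * pi))
  tibble::tibble(z = grid, rho = rho)
}

# trapezoid rule on a uniform grid
trapz_ <- function(x, y) {
  dx <- x[2] - x[1]
  (sum(y) - (y[1] + y[length(y)]) / 2) * dx
}

#' Variance measure of axial homogeneity
#'
#' \deqn{\Phi = \int_{-b_z}^{b_z} [\rho(z) - \bar\rho]^2\, dz,
#'   \qquad \bar\rho = \frac{1}{2 b_z} \int_{-b_z}^{b_z} \rho\, dz.}
#' Zero exactly when the axial density is uniform across the embryo;
#' smaller values mean more homogeneous spreading.
#'
#' @param density A tibble from [axial_density()] (columns `z`, `rho`)
#'   whose grid spans \eqn{[-b_z, b_z]} uniformly.
#' @param geometry An [embryo_geometry()].
#' @return \eqn{\Phi} (\eqn{\mu m^{-1}} scale).
#' @export
variance_phi <- function(density, geometry) {
  assert_geometry(geometry)
  stopifnot(all(c("z", "rho") %in% names(density)))
  rbar <- trapz_(density$z, density$rho) / (2 * geometry$bz)
  trapz_(density$z, (density$rho - rbar)^2)
}

#' Discrete strip-count variance
#'
#' Divides the embryo into `n_strips` strips of equal axial width and
#' returns the variance over strips of the tracer counts \eqn{n_i}
#' (population variance). An alternative, kernel-free measure of axial
#' homogeneity.
#'
#' @param z_positions Axial tracer positions, \eqn{\mu m}.
#' @param n_strips Number of strips (\eqn{\ge 2}).
#' @param geometry An [embryo_geometry()].
#' @return The count variance (dimensionless).
#' @export
strip_variance <- function(z_positions, n_strips, geometry) {
  assert_geometry(geometry)
  stopifnot(n_strips >= 2)
  breaks <- seq(-geometry$bz, geometry$bz, length.out = n_strips + 1)
  zc <- pmin(pmax(z_positions, -geometry$bz), geometry$bz - 1e-9)
  counts <- tabulate(findInterval(zc, breaks), nbins = n_strips)
  mean((counts - mean(counts))^2)
}

#' Advect an ensemble of seeded tracer clouds
#'
#' Runs `n_seeds` independent simulations (seeds `base_seed + k`,
#' `k = 0 .. n_seeds - 1`), advecting all clouds jointly through the
#' vectorized integrator, and records the axial position of every tracer
#' at each value of the snapshot grid.
#'
#' @param flow A [stokes_flow()] at unit amplitude.
#' @param n Tracers per simulation.
#' @param n_seeds Number of simulations.
#' @param base_seed Base RNG seed.
#' @param chi_grid Snapshot grid, \eqn{\mu m} (default 0–400 in steps
#'   of 2).
#' @param dchi RK4 step.
#' @param centre_z,radius Passed to [sample_nuclei()].
#' @return An object of class `transport_ensemble`: list with `z` (matrix,
#'   tracers x snapshots), `seed_of` (seed index per row), `chi_grid`,
#'   `n`, `n_seeds`, `base_seed`, `n_projected`.
#' @export
advect_ensemble <- function(flow, n = 40, n_seeds = 100, base_seed = 1,
                            chi_grid = seq(0, 400, by = 2), dchi = 0.5,
                            centre_z = NULL, radius = 60) {
  stopifnot(inherits(flow, "stokes_flow"), n_seeds >= 1)
  g <- flow$geometry
  if (is.null(centre_z)) centre_z <- g$bz * stagnation_zeta()
  clouds <- purrr::map(seq_len(n_seeds) - 1L, function(k) {
    sample_nuclei(n, g, seed = base_seed + k, centre_z = centre_z,
                  radius = radius)
  })
  x <- unlist(purrr::map(clouds, "x"))
  y <- unlist(purrr::map(clouds, "y"))
  z <- unlist(purrr::map(clouds, "z"))
  seed_of <- rep(seq_len(n_seeds), each = n)
  stopifnot(chi_grid[1] == 0, all(diff(chi_grid) > 0))
  zs <- matrix(NA_real_, length(z), length(chi_grid))
  zs[, 1] <- z
  n_proj <- 0L
  for (i in seq_along(chi_grid)[-1]) {
    span <- chi_grid[i] - chi_grid[i - 1]
    n_full <- floor(span / dchi + 1e-12)
    st <- advect_steps_(flow, x, y, z, dchi, n_full)
    x <- st$x; y <- st$y; z <- st$z; n_proj <- n_proj + st$n_proj
    rem <- span - n_full * dchi
    if (rem > 1e-9) {
      st <- advect_steps_(flow, x, y, z, rem, 1L)
      x <- st$x; y <- st$y; z <- st$z; n_proj <- n_proj + st$n_proj
    }
    zs[, i] <- z
  }
  structure(
    list(z = zs, seed_of = seed_of, chi_grid = chi_grid, n = n,
         n_seeds = n_seeds, base_seed = base_seed, n_projected = n_proj),
    class = "transport_ensemble"
  )
}

#' @export
print.transport_ensemble <- function(x, ...) {
  cat(sprintf(
    "<transport_ensemble> %d seeds x %d tracers, chi in [%g, %g] um\n",
    x$n_seeds, x$n, min(x$chi_grid), max(x$chi_grid)
  ))
  invisible(x)
}

# quadratic least-squares refinement of a discrete argmin over a window
refine_argmin <- function(x, y, half_window = 10) {
  i <- which.min(y)
  w <- which(abs(x - x[i]) <= half_window + 1e-9)
  if (length(w) < 3) return(x[i])
  co <- stats::coef(stats::lm(y[w] ~ x[w] + I(x[w]^2)))
  if (!is.finite(co[3]) || co[3] <= 0) return(x[i])
  xs <- -co[2] / (2 * co[3])
  if (xs < min(x[w]) || xs > max(x[w])) x[i] else unname(xs)
}

#' Ensemble homogeneity curve and optimal spreading
#'
#' Computes the normalized ensemble-mean homogeneity curve
#' \eqn{\langle\Phi(\chi)\rangle / \langle\Phi(0)\rangle} from a
#' [advect_ensemble()] result, with either the Gaussian-kernel variance
#' (`measure = "kernel"`, defined in [variance_phi()]) or the
#' discrete strip-count variance (`measure = "strips"`). The optimum
#' `chi_star` is the argmin over the snapshot grid, refined by a local
#' quadratic least-squares fit (reported to about 1 \eqn{\mu m}).
#'
#' @param ensemble A `transport_ensemble`.
#' @param geometry The [embryo_geometry()] the ensemble was run in.
#' @param measure `"kernel"` or `"strips"`.
#' @param bandwidth Kernel length scale \eqn{R}, \eqn{\mu m} (kernel
#'   measure).
#' @param n_strips Strip count (strip measure).
#' @param dz Density grid spacing, \eqn{\mu m}.
#' @return An object of class `homogeneity_curve`: tibble columns `chi`,
#'   `phi_mean`, `phi_min`, `phi_max` (all normalized by
#'   \eqn{\langle\Phi(0)\rangle}), with attributes `chi_star`, `measure`,
#'   `bandwidth`/`n_strips`, `n`, `n_seeds`, `base_seed`.
#' @export
homogeneity_curve <- function(ensemble, geometry, measure = c("kernel", "strips"),
                              bandwidth = 7, n_strips = 100, dz = 1) {
  stopifnot(inherits(ensemble, "transport_ensemble"))
  assert_geometry(geometry)
  measure <- match.arg(measure)
  chi <- ensemble$chi_grid
  n_seeds <- ensemble$n_seeds
  PHI <- matrix(0, n_seeds, length(chi))
  if (measure == "kernel") {
    zgrid <- seq(-geometry$bz, geometry$bz, by = dz)
    half <- 1 / (2 * bandwidth^2)
    norm <- 1 / (ensemble$n * bandwidth * sqrt(2 * pi))
    for (j in seq_along(chi)) {
      E <- exp(-outer(zgrid, ensemble$z[, j], "-")^2 * half)
      # per-seed densities: sum kernel columns within each seed
      R <- rowsum(t(E), ensemble$seed_of) * norm   # n_seeds x length(zgrid)
      rbar <- (rowSums(R) - (R[, 1] + R[, ncol(R)]) / 2) * dz / (2 * geometry$bz)
      dev2 <- (R - rbar)^2
      PHI[, j] <- (rowSums(dev2) - (dev2[, 1] + dev2[, ncol(R)]) / 2) * dz
    }
  } else {
    breaks <- seq(-geometry$bz, geometry$bz, length.out = n_strips + 1)
    for (j in seq_along(chi)) {
      zc <- pmin(pmax(ensemble$z[, j], -geometry$bz), geometry$bz - 1e-9)
      idx <- findInterval(zc, breaks)
      for (k in seq_len(n_seeds)) {
        counts <- tabulate(idx[ensemble$seed_of == k], nbins = n_strips)
        PHI[k, j] <- mean((counts - mean(counts))^2)
      }
    }
  }
  phi0 <- mean(PHI[, 1])
  out <- tibble::tibble(
    chi = chi,
    phi_mean = colMeans(PHI) / phi0,
    phi_min = apply(PHI, 2, min) / phi0,
    phi_max = apply(PHI, 2, max) / phi0
  )
  class(out) <- c("homogeneity_curve", class(out))
  # ensemble curves are flat and noisy near the optimum; a +-30 um
  # quadratic least-squares window is a lower-variance argmin estimator
  # than interpolating the raw discrete minimum
  attr(out, "chi_star") <- refine_argmin(chi, out$phi_mean, half_window = 30)
  attr(out, "measure") <- measure
  attr(out, "bandwidth") <- if (measure == "kernel") bandwidth else NA_real_
  attr(out, "n_strips") <- if (measure == "strips") n_strips else NA_integer_
  attr(out, "n") <- ensemble$n
  attr(out, "n_seeds") <- ensemble$n_seeds
  attr(out, "base_seed") <- ensemble$base_seed
  out
}

#' Optimal rescaled time of a homogeneity curve
#'
#' @param curve A `homogeneity_curve`.
#' @return `chi_star` in \eqn{\mu m}.
#' @export
chi_star <- function(curve) {
  stopifnot(inherits(curve, "homogeneity_curve"))
  attr(curve, "chi_star")
}

#' Evaluate a homogeneity curve at given chi
#'
#' Linear interpolation of the normalized ensemble-mean curve; useful for
#' placing experimentally realized values of \eqn{\chi} on the curve.
#'
#' @param curve A `homogeneity_curve`.
#' @param chi Values of \eqn{\chi}, \eqn{\mu m}.
#' @return Numeric vector of normalized variance values.
#' @export
curve_value_at <- function(curve, chi) {
  stats::approx(curve$chi, curve$phi_mean, xout = chi)$y
}
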