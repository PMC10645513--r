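#' Slip-profile mode coefficients
#'
#' Projects a boundary slip profile onto the associated Legendre basis of
#' the boundary expansion
#' \deqn{v_s(\zeta) = \frac{\tau_0}{\sqrt{\tau_0^2 - \zeta^2}}
#'   \sum_{n \ge 1} B_n P^1_n(\zeta),}
#' using the orthogonality of the \eqn{P^1_n},
#' \deqn{B_n = \frac{2n + 1}{2 n (n + 1)\,\tau_0}
#'   \int_{-1}^{1} v_s(\zeta)\,\sqrt{\tau_0^2 - \zeta^2}\,
#'   P^1_n(\zeta)\, d\zeta.}
#' The integral is evaluated by fixed-order Gauss–Legendre quadrature; the
#' \eqn{\sqrt{\tau_0^2 - \zeta^2}} factor is smooth on \eqn{[-1, 1]}
#' because \eqn{\tau_0 > 1}, so no endpoint treatment is needed.
#'
#' @param slip A [slip_profile()].
#' @param geometry An [embryo_geometry()].
#' @param nmax Number of modes to compute (truncation order).
#' @param n_nodes Gauss–Legendre node count (at least 64; automatically
#'   raised to `4 * nmax` for high truncation orders).
#' @return A tibble with columns `n` and `B` (\eqn{\mu m\,s^{-1}}) of class
#'   `mode_coefficients`.
#' @export
slip_coefficients <- function(slip, geometry, nmax = 14, n_nodes = 64) {
  assert_geometry(geometry)
  stopifnot(inherits(slip, "slip_profile"), nmax >= 2)
  n_nodes <- max(n_nodes, 64, 4 * nmax)
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  x <- gl$x; w <- gl$w
  tau0 <- geometry$tau0
  D <- legendre_dP_all(nmax, x)
  f <- slip_eval(slip, x) * sqrt(tau0^2 - x^2)
  B <- vapply(seq_len(nmax), function(n) {
    P1 <- -sqrt(1 - x^2) * D[, n + 1L]
    (2 * n + 1) / (2 * n * (n + 1) * tau0) * sum(w * f * P1)
  }, numeric(1))
  out <- tibble::tibble(n = seq_len(nmax), B = B)
  class(out) <- c("mode_coefficients", class(out))
  out
}

#' Reconstruct a slip profile from mode coefficients
#'
#' Evaluates the truncated boundary expansion (see [slip_coefficients()])
#' at given \eqn{\zeta}; used to monitor the truncation floor of the
#' series solution.
#'
#' @param coefficients A `mode_coefficients` tibble (columns `n`, `B`).
#' @param zeta Evaluation points in \eqn{[-1, 1]}.
#' @param geometry An [embryo_geometry()].
#' @return Numeric vector of slip speeds.
#' @export
reconstruct_slip <- function(coefficients, zeta, geometry) {
  assert_geometry(geometry)
  nmax <- max(coefficients$n)
  D <- legendre_dP_all(nmax, zeta)
  s <- rep(0, length(zeta))
  for (i in seq_len(nrow(coefficients))) {
    n <- coefficients$n[i]
    s <- s - coefficients$B[i] * sqrt(1 - zeta^2) * D[, n + 1L]
  }
  geometry$tau0 / sqrt(geometry$tau0^2 - zeta^2) * s
}

# Order-by-order ladder solve -------------------------------------------
#
# The streamfunction is psi(tau, zeta) = sum_{n>=2} g_n(tau) G_n(zeta) with
#   g_2 = F_2 G_2 + E_4 G_4
#   g_3 = F_3 G_3 + E_5 G_5
#   g_n = F_n G_n + E_{n+2} G_{n+2} + E_n G_{n-2},  n >= 4,
# subject to g_n(tau0) = 0 (impenetrability; psi vanishes on the boundary)
# and g_n'(tau0) = c^2 tau0 n(n-1) B_{n-1} (prescribed slip). Even and odd
# chains are independent; each order is a 2x2 solve reusing the E already
# fixed two orders below.
solve_ladder <- function(B, geometry, nmax) {
  tau0 <- geometry$tau0
  G <- gegenbauer_all(nmax + 2L, tau0)[1, ]          # G[k + 1] = G_k(tau0)
  P <- legendre_P_all(nmax + 1L, tau0)[1, ]          # P[k + 1] = P_k(tau0)
  dG <- c(0, -P[seq_len(nmax + 2L)])                 # dG[k + 1] = G_k'(tau0)
  E <- numeric(nmax + 3L)                            # E[k + 1] = E_k
  FF <- numeric(nmax + 1L)                           # FF[k + 1] = F_k
  rhs <- function(n) {
    if (n - 1L <= length(B)) geometry$c^2 * tau0 * n * (n - 1) * B[n - 1L] else 0
  }
  for (start in c(2L, 3L)) {
    n <- start
    while (n <= nmax) {
      A <- rbind(c(G[n + 1L], G[n + 3L]), c(dG[n + 1L], dG[n + 3L]))
      b <- c(0, rhs(n))
      if (n >= 4L) {
        b <- b - E[n + 1L] * c(G[n - 1L], dG[n - 1L])
      }
      sol <- tryCatch(solve(A, b), error = function(e) {
        stop(sprintf("singular 2x2 step system at order n = %d", n),
             call. = FALSE)
      })
      FF[n + 1L] <- sol[1]
      E[n + 3L] <- sol[2]
      n <- n + 2L
    }
  }
  list(E = E, F = FF)
}

#' Exact interior Stokes flow in a prolate spheroid
#'
#' Solves the boundary-driven Stokes problem inside the spheroid exactly,
#' as a truncated Gegenbauer series for the streamfunction
#' \eqn{\psi(\tau, \zeta) = \sum_{n \ge 2} g_n(\tau) G_n(\zeta)}. The slip
#' profile is decomposed into mode coefficients \eqn{B_n}
#' ([slip_coefficients()]) and the radial functions \eqn{g_n} — specific
#' combinations of first-kind Gegenbauer functions regular at the focal
#' segment — are determined order by order from the impenetrability and
#' slip boundary conditions. Second-kind Gegenbauer terms are excluded by
#' regularity on the axis. The velocity field is linear in the slip
#' amplitude, so the solution is computed once at unit amplitude and
#' rescaled as needed.
#'
#' @param slip A [slip_profile()], or a `mode_coefficients` tibble to
#'   prescribe the \eqn{B_n} directly.
#' @param geometry An [embryo_geometry()].
#' @param nmax Truncation order of the series (default 14; 25 changes the
#'   interior field by about 0.1\% or less for the Drosophila profile).
#' @param n_nodes Quadrature nodes passed to [slip_coefficients()].
#' @return An object of class `stokes_flow` with fields `geometry`,
#'   `nmax`, `B`, `E`, `F`, `slip_name` and boundary-residual diagnostics
#'   (`residual_g`, `residual_dg`, largest absolute residuals of the two
#'   boundary conditions across retained orders).
#' @examples
#' g <- embryo_geometry(110, 270)
#' fl <- stokes_flow(slip_drosophila(), g)
#' flow_velocity(fl, data.frame(r = c(0, 50), z = c(0, 100)))
#' @export
stokes_flow <- function(slip, geometry, nmax = 14, n_nodes = 64) {
  assert_geometry(geometry)
  if (inherits(slip, "mode_coefficients")) {
    Bfull <- numeric(max(nmax - 1L, max(slip$n)))
    Bfull[slip$n] <- slip$B
    B <- Bfull
    slip_name <- "prescribed-modes"
    slip_obj <- NULL
  } else {
    stopifnot(inherits(slip, "slip_profile"))
    co <- slip_coefficients(slip, geometry, nmax = nmax - 1L,
                            n_nodes = n_nodes)
    B <- co$B
    slip_name <- slip$name
    slip_obj <- slip
  }
  lad <- solve_ladder(B, geometry, nmax)
  fl <- structure(
    list(geometry = geometry, nmax = as.integer(nmax), B = B,
         E = lad$E, F = lad$F, slip_name = slip_name, slip = slip_obj),
    class = "stokes_flow"
  )
  res <- boundary_residuals(fl)
  fl$residual_g <- res$g
  fl$residual_dg <- res$dg
  fl
}

#' @export
print.stokes_flow <- function(x, ...) {
  cat(sprintf(
    "<stokes_flow> slip '%s', nmax = %d, boundary residuals %.2e / %.2e\n",
    x$slip_name, x$nmax, x$residual_g, x$residual_dg
  ))
  invisible(x)
}

# max |g_n(tau0)| and |g_n'(tau0) - rhs_n| over retained orders
boundary_residuals <- function(flow) {
  g <- flow$geometry
  ge <- eval_g(flow, g$tau0)
  rg <- max(abs(ge$g[1, ]))
  rhs <- numeric(flow$nmax + 1L)
  for (n in 2:flow$nmax) {
    rhs[n + 1L] <- if (n - 1L <= length(flow$B)) {
      g$c^2 * g$tau0 * n * (n - 1) * flow$B[n - 1L]
    } else 0
  }
  rdg <- max(abs(ge$dg[1, ] - rhs))
  scale <- max(abs(rhs), 1)
  list(g = rg / scale, dg = rdg / scale)
}

# g_n(tau) and g_n'(tau) for n = 2..nmax; returns matrices with column
# n + 1 holding order n.
eval_g <- function(flow, tau) {
  nmax <- flow$nmax
  G <- gegenbauer_all(nmax + 2L, tau)
  P <- legendre_P_all(nmax + 1L, tau)
  g <- matrix(0, length(tau), nmax + 1L)
  dg <- matrix(0, length(tau), nmax + 1L)
  for (n in 2:nmax) {
    g[, n + 1L] <- flow$F[n + 1L] * G[, n + 1L] +
      flow$E[n + 3L] * G[, n + 3L]
    dg[, n + 1L] <- -flow$F[n + 1L] * P[, n] -
      flow$E[n + 3L] * P[, n + 2L]
    if (n >= 4L) {
      g[, n + 1L] <- g[, n + 1L] + flow$E[n + 1L] * G[, n - 1L]
      dg[, n + 1L] <- dg[, n + 1L] - flow$E[n + 1L] * P[, n - 2L]
    }
  }
  list(g = g, dg = dg)
}

# Core field evaluation at spheroidal points. Uses the regular
# representation G_n(zeta) = (1 - zeta^2) P'_{n-1}(zeta) / (n(n-1)), which
# keeps every term finite on the axis; the only guarded degeneracy is the
# focal points tau = 1, |zeta| = 1 where tau^2 - zeta^2 -> 0.
eval_velocity_sph <- function(flow, tau, zeta) {
  g0 <- flow$geometry
  nmax <- flow$nmax
  tau <- pmax(tau, 1 + 1e-12)
  ge <- eval_g(flow, tau)
  Pz <- legendre_P_all(nmax, zeta)
  Dz <- legendre_dP_all(nmax, zeta)
  S0 <- rep(0, length(tau))    # sum g_n(tau) G_n'(zeta)
  S1 <- rep(0, length(tau))    # sum g_n'(tau) P'_{n-1}(zeta) / (n(n-1))
  for (n in 2:nmax) {
    S0 <- S0 - ge$g[, n + 1L] * Pz[, n]
    S1 <- S1 + ge$dg[, n + 1L] * Dz[, n] / (n * (n - 1))
  }
  den <- g0$c^2 * pmax(tau^2 - zeta^2, 1e-12)
  t2 <- tau^2 - 1
  u_z <- (zeta * S0 - tau * (1 - zeta^2) * S1) / den
  u_r <- (tau * sqrt((1 - zeta^2) / t2) * S0 +
            zeta * sqrt(t2) * sqrt(1 - zeta^2) * S1) / den
  # r = 0 exactly on the focal segment and the polar axis: u_r vanishes by
  # axisymmetry (the generic expression there is a 0/0 limit).
  on_axis <- (tau - 1 < 1e-10) | (1 - zeta^2 < 1e-14)
  u_r[on_axis] <- 0
  list(u_r = u_r, u_z = u_z)
}

eval_psi_sph <- function(flow, tau, zeta) {
  nmax <- flow$nmax
  ge <- eval_g(flow, pmax(tau, 1))
  Dz <- legendre_dP_all(nmax, zeta)
  psi <- rep(0, length(tau))
  for (n in 2:nmax) {
    Gn <- (1 - zeta^2) * Dz[, n] / (n * (n - 1))
    psi <- psi + ge$g[, n + 1L] * Gn
  }
  psi
}

#' Evaluate a flow field at points
#'
#' Evaluates the velocity of a flow solution at cylindrical points.
#' Methods exist for the exact series solution ([stokes_flow()]) and the
#' long-wavelength solution ([lubrication_flow()]).
#'
#' @param flow A flow object.
#' @param points Data frame with columns `r`, `z` (\eqn{\mu m}).
#' @param ... Passed to methods.
#' @return A tibble with the input coordinates plus `u_r`, `u_z`
#'   (\eqn{\mu m\,s^{-1}} at unit slip amplitude).
#' @export
flow_velocity <- function(flow, points, ...) UseMethod("flow_velocity")

#' @rdname flow_velocity
#' @export
flow_velocity.stokes_flow <- function(flow, points, ...) {
  stopifnot(all(c("r", "z") %in% names(points)))
  sp <- cyl_to_sph_(points$r, points$z, flow$geometry)
  if (any(sp$tau > flow$geometry$tau0 * (1 + 1e-6))) {
    stop("point(s) outside the spheroid.", call. = FALSE)
  }
  v <- eval_velocity_sph(flow, pmin(sp$tau, flow$geometry$tau0), sp$zeta)
  tibble::tibble(r = points$r, z = points$z, u_r = v$u_r, u_z = v$u_z)
}

#' Stokes streamfunction of a flow solution
#'
#' Evaluates \eqn{\psi(\tau, \zeta)} (exact series) or its long-wavelength
#' counterpart at cylindrical points. \eqn{\psi} vanishes identically on
#' the boundary and on the symmetry axis; its sign partitions the
#' meridional plane into vortices.
#'
#' @inheritParams flow_velocity
#' @return A tibble with the input coordinates plus `psi`
#'   (\eqn{\mu m^3 s^{-1}} scale).
#' @export
streamfunction <- function(flow, points, ...) UseMethod("streamfunction")

#' @rdname streamfunction
#' @export
streamfunction.stokes_flow <- function(flow, points, ...) {
  stopifnot(all(c("r", "z") %in% names(points)))
  sp <- cyl_to_sph_(points$r, points$z, flow$geometry)
  psi <- eval_psi_sph(flow, pmin(sp$tau, flow$geometry$tau0), sp$zeta)
  tibble::tibble(r = points$r, z = points$z, psi = psi)
}

#' Regular interior evaluation grid
#'
#' A meridional grid covering a fraction of the cell cross-section,
#' used for field export, solver comparison and truncation studies.
#'
#' @param geometry An [embryo_geometry()].
#' @param n_z,n_r Number of axial and radial stations.
#' @param fraction Fraction of each semi-axis covered (default 0.95: the
#'   package's standard interior grid, excluding the outermost 5\% shell
#'   where the truncated slip expansion concentrates its error).
#' @return A tibble with columns `r`, `z`.
#' @export
interior_grid <- function(geometry, n_z = 60, n_r = 30, fraction = 0.95) {
  assert_geometry(geometry)
  zg <- seq(-fraction * geometry$bz, fraction * geometry$bz, length.out = n_z)
  purrr::map_dfr(zg, function(z) {
    rmax <- fraction * geometry$bx * sqrt(1 - (z / geometry$bz)^2)
    tibble::tibble(r = seq(0, rmax, length.out = n_r), z = z)
  })
}

#' Truncation study of the series solution
#'
#' Solves the flow at two truncation orders and reports the maximum
#' velocity difference over an interior grid, normalized by the maximum
#' flow speed of the higher-order solution. Points where the flow is
#' nearly zero (below `floor_fraction` of the maximum speed) are excluded,
#' since relative differences there are dominated by noise.
#'
#' @param slip A [slip_profile()].
#' @param geometry An [embryo_geometry()].
#' @param n_low,n_high The two truncation orders to compare.
#' @param grid Evaluation points (default [interior_grid()]).
#' @param floor_fraction Near-zero-flow exclusion threshold.
#' @return Maximum normalized velocity difference (dimensionless; multiply
#'   by 100 for percent).
#' @export
truncation_study <- function(slip, geometry, n_low = 14, n_high = 25,
                             grid = interior_grid(geometry),
                             floor_fraction = 0.01) {
  stopifnot(n_low <= n_high)
  if (n_low == n_high) return(0)
  f1 <- stokes_flow(slip, geometry, nmax = n_low)
  f2 <- stokes_flow(slip, geometry, nmax = n_high)
  v1 <- flow_velocity(f1, grid)
  v2 <- flow_velocity(f2, grid)
  speed <- sqrt(v2$u_r^2 + v2$u_z^2)
  mx <- max(speed)
  keep <- speed > floor_fraction * mx
  d <- sqrt((v1$u_r - v2$u_r)^2 + (v1$u_z - v2$u_z)^2)
  max(d[keep]) / mx
}

#' Export a flow field and its coefficients
#'
#' Writes the velocity and streamfunction on a grid to CSV (columns
#' `r_um`, `z_um`, `u_r`, `u_z`, `psi`) and, for exact solutions, the
#' geometry and series coefficients to JSON.
#'
#' @param flow A flow object.
#' @param csv_path Output CSV path.
#' @param json_path Optional output JSON path for the coefficients.
#' @param grid Evaluation grid (default [interior_grid()]).
#' @return Invisibly, the exported field tibble.
#' @export
export_flow_field <- function(flow, csv_path, json_path = NULL,
                              grid = interior_grid(flow$geometry)) {
  v <- flow_velocity(flow, grid)
  p <- streamfunction(flow, grid)
  out <- tibble::tibble(
    r_um = v$r, z_um = v$z, u_r = v$u_r, u_z = v$u_z, psi = p$psi
  )
  readr::write_csv(out, csv_path)
  if (!is.null(json_path) && inherits(flow, "stokes_flow")) {
    jsonlite::write_json(
      list(
        geometry = list(bx_um = flow$geometry$bx, bz_um = flow$geometry$bz,
                        c_um = flow$geometry$c, tau0 = flow$geometry$tau0),
        nmax = flow$nmax,
        B = flow$B,
        E = flow$E,
        F = flow$F
      ),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out)
}
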