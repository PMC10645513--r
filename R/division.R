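#' Nuclear division with short-range repulsive spreading
#'
#' A toy model of one round of synchronous nuclear division in the
#' absence of flow: every nucleus is duplicated, and the doubled
#' population relaxes under a pairwise short-range repulsion of range
#' `repulsion_range` (default 28 \eqn{\mu m}, the nuclear separation
#' distance set by microtubule aster migration). The force law is a
#' linear spring, \eqn{f(d) = \max(0, 1 - d / range)} along the
#' separation vector — the published description specifies only the range,
#' so the spring form is a documented modelling choice and only the sign
#' and qualitative size of the effect are meaningful. Relaxation uses
#' overdamped explicit steps until the maximum displacement per step
#' falls below `tol` (or `max_iter` is reached, in which case the
#' residual is reported); particles are projected back inside the
#' spheroid after every step.
#'
#' @param cloud A tibble with columns `x`, `y`, `z` (\eqn{\mu m}).
#' @param geometry An [embryo_geometry()].
#' @param repulsion_range Interaction range, \eqn{\mu m}.
#' @param mobility Displacement per unit force per step, \eqn{\mu m}.
#' @param tol Convergence threshold on the per-step max displacement,
#'   \eqn{\mu m}.
#' @param max_iter Iteration cap.
#' @param seed RNG seed for the daughter-separation directions.
#' @return A tibble of `2 * nrow(cloud)` relaxed positions with attribute
#'   `iterations`.
#' @export
divide_nuclei <- function(cloud, geometry, repulsion_range = 28,
                          mobility = 2, tol = 0.01, max_iter = 500,
                          seed = NULL) {
  assert_geometry(geometry)
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  if (!is.null(seed)) set.seed(seed)
  n0 <- nrow(cloud)
  # duplicate with a small random split so daughters are not coincident
  dir <- matrix(stats::rnorm(3 * n0), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  eps <- 0.5
  P <- rbind(
    cbind(cloud$x + eps * dir[, 1], cloud$y + eps * dir[, 2],
          cloud$z + eps * dir[, 3]),
    cbind(cloud$x - eps * dir[, 1], cloud$y - eps * dir[, 2],
          cloud$z - eps * dir[, 3])
  )
  n <- nrow(P)
  project_in <- function(P) {
    f <- (P[, 1]^2 + P[, 2]^2) / geometry$bx^2 + P[, 3]^2 / geometry$bz^2
    out <- f >= 1
    if (any(out)) P[out, ] <- P[out, , drop = FALSE] / (sqrt(f[out]) / (1 - 1e-9))
    P
  }
  it <- 0L
  repeat {
    it <- it + 1L
    dx <- outer(P[, 1], P[, 1], "-")
    dy <- outer(P[, 2], P[, 2], "-")
    dz <- outer(P[, 3], P[, 3], "-")
    d <- sqrt(dx^2 + dy^2 + dz^2)
    diag(d) <- Inf
    w <- pmax(0, 1 - d / repulsion_range) / d
    Fx <- rowSums(w * dx)
    Fy <- rowSums(w * dy)
    Fz <- rowSums(w * dz)
    step <- mobility * cbind(Fx, Fy, Fz)
    P <- project_in(P + step)
    if (max(sqrt(rowSums(step^2))) < tol || it >= max_iter) break
  }
  if (it >= max_iter) {
    warning(sprintf(
      "relaxation stopped at %d iterations; max residual step %.3g um.",
      it, max(sqrt(rowSums(step^2)))), call. = FALSE)
  }
  out <- tibble::tibble(particle = seq_len(n),
                        x = P[, 1], y = P[, 2], z = P[, 3])
  attr(out, "iterations") <- it
  out
}

#' Sample the pre-division nuclear configuration
#'
#' The configuration approximating the start of cell cycle 6: nuclei
#' distributed uniformly in a spheroidal cloud of semi-major axis 140
#' \eqn{\mu m} (along the AP axis) and semi-minor axis 40 \eqn{\mu m},
#' centred at the cell centre.
#'
#' @param n Number of nuclei (default 32).
#' @param seed RNG seed.
#' @param semi_major,semi_minor Cloud semi-axes, \eqn{\mu m}.
#' @return A tibble with columns `particle`, `x`, `y`, `z`.
#' @export
sample_division_cloud <- function(n = 32, seed = 1, semi_major = 140,
                                  semi_minor = 40) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(3 * 2 * n, -1, 1), ncol = 3)
    cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  tibble::tibble(
    particle = seq_len(n),
    x = pts[, 1] * semi_minor,
    y = pts[, 2] * semi_minor,
    z = pts[, 3] * semi_major
  )
}
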