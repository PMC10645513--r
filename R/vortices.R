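#' Count meridional vortices of an axisymmetric flow
#'
#' Counts the recirculation cells of the flow in the meridional half-plane
#' \eqn{(r > 0, z)}. Cells are separated by zero contours of the
#' streamfunction, so the count equals the number of connected components
#' of \eqn{\{\psi > \delta\} \cup \{\psi < -\delta\}} on a regular interior
#' grid, with \eqn{\delta} a small fraction of \eqn{\max|\psi|}. A
#' single-mode slip profile of mode \eqn{m} produces exactly \eqn{m}
#' vortices.
#'
#' @param flow A [stokes_flow()] or [lubrication_flow()] object.
#' @param n_z,n_r Grid resolution.
#' @param floor_fraction Sign threshold \eqn{\delta / \max|\psi|}.
#' @return Integer vortex count.
#' @export
count_vortices <- function(flow, n_z = 160, n_r = 60,
                           floor_fraction = 1e-4) {
  g <- flow$geometry
  zg <- seq(-0.985 * g$bz, 0.985 * g$bz, length.out = n_z)
  rfrac <- seq(0.02, 0.97, length.out = n_r)
  grid <- purrr::map_dfr(zg, function(z) {
    rmax <- g$bx * sqrt(1 - (z / g$bz)^2)
    tibble::tibble(r = rfrac * rmax, z = z)
  })
  psi <- streamfunction(flow, grid)$psi
  mx <- max(abs(psi))
  if (mx < 1e-14) {
    stop("flow magnitude below the numerical floor; no vortices to count.",
         call. = FALSE)
  }
  lab <- matrix(0L, n_r, n_z)   # rows: r index, cols: z index
  sgn <- matrix(sign(psi) * (abs(psi) > floor_fraction * mx), n_r, n_z)
  count <- 0L
  for (j in seq_len(n_z)) {
    for (i in seq_len(n_r)) {
      if (sgn[i, j] != 0 && lab[i, j] == 0L) {
        count <- count + 1L
        # flood fill of the same-sign component
        stack <- list(c(i, j))
        lab[i, j] <- count
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            q <- p + d
            if (q[1] >= 1 && q[1] <= n_r && q[2] >= 1 && q[2] <= n_z &&
                lab[q[1], q[2]] == 0L &&
                sgn[q[1], q[2]] == sgn[p[1], p[2]]) {
              lab[q[1], q[2]] <- count
              stack[[length(stack) + 1L]] <- q
            }
          }
        }
      }
    }
  }
  count
}
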