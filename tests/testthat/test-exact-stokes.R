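test_that("mode coefficients round-trip through the boundary expansion", {
  g <- embryo()
  # a pure mode-3 slip must come back as B3 = 1, all others ~ 0
  co <- slip_coefficients(slip_mode(3, g), g, nmax = 10)
  expect_equal(co$B[3], 1, tolerance = 1e-8)
  expect_lt(max(abs(co$B[-3])), 1e-8)
  # zero slip gives all-zero coefficients
  co0 <- slip_coefficients(slip_profile(function(z) 0 * z, "null"), g, 8)
  expect_true(all(abs(co0$B) < 1e-14))
})

test_that("Drosophila mode coefficients match an independent adaptive quadrature", {
  g <- embryo()
  co <- slip_coefficients(slip_drosophila(), g, nmax = 10)
  vs <- slip_drosophila()
  for (n in c(1, 2, 3, 6, 9)) {
    oracle <- stats::integrate(
      function(x) {
        vs$shape(x) * sqrt(g$tau0^2 - x^2) * assoc_legendre_P1(n, x)
      },
      -1, 1, rel.tol = 1e-12, subdivisions = 500
    )$value * (2 * n + 1) / (2 * n * (n + 1) * g$tau0)
    expect_lt(abs(co$B[n] - oracle), 1e-8)
  }
})

test_that("series solve enforces both boundary conditions at every order", {
  g <- embryo()
  # zero forcing -> identically zero flow
  B0 <- slip_coefficients(slip_profile(function(z) 0 * z, "null"), g, 10)
  f0 <- stokes_flow(B0, g, nmax = 11)
  expect_true(all(abs(f0$E) < 1e-14))
  expect_true(all(abs(f0$F) < 1e-14))
  v0 <- flow_velocity(f0, data.frame(r = c(10, 50), z = c(0, 100)))
  expect_true(all(abs(c(v0$u_r, v0$u_z)) < 1e-14))

  # random coefficients: boundary residuals at solver tolerance
  set.seed(4)
  Br <- tibble::tibble(n = 1:9, B = stats::rnorm(9))
  class(Br) <- c("mode_coefficients", class(Br))
  fr <- stokes_flow(Br, g, nmax = 10)
  expect_lt(fr$residual_g, 1e-10)
  expect_lt(fr$residual_dg, 1e-10)
})

test_that("streamfunction vanishes on the boundary and the axis", {
  g <- embryo()
  fl <- dros_flow()
  zeta <- seq(-1, 1, length.out = 41)
  bdry <- to_cylindrical(data.frame(tau = g$tau0, zeta = zeta), g)
  psi_b <- streamfunction(fl, bdry)$psi
  # scale: typical interior psi magnitude
  psi_int <- streamfunction(fl, interior_grid(g, n_z = 21, n_r = 11))$psi
  expect_lt(max(abs(psi_b)), 1e-10 * max(abs(psi_int)))
  axis <- data.frame(r = 0, z = seq(-260, 260, by = 40))
  expect_lt(max(abs(streamfunction(fl, axis)$psi)), 1e-10 * max(abs(psi_int)))
})

test_that("analytic streamfunction derivative matches central differences", {
  g <- embryo()
  fl <- dros_flow()
  # u_tau = (1/(h_zeta h_phi)) dpsi/dzeta: compare the analytic velocity
  # against finite differences of psi at interior spheroidal points
  pts <- data.frame(tau = c(1.02, 1.05, 1.08), zeta = c(-0.5, 0.2, 0.6))
  h <- 1e-6
  for (i in seq_len(nrow(pts))) {
    tau <- pts$tau[i]; zeta <- pts$zeta[i]
    cyp <- to_cylindrical(data.frame(tau = tau, zeta = zeta + h), g)
    cym <- to_cylindrical(data.frame(tau = tau, zeta = zeta - h), g)
    dpsi <- (streamfunction(fl, cyp)$psi - streamfunction(fl, cym)$psi) / (2 * h)
    hc <- metric_coefficients(data.frame(tau = tau, zeta = zeta), g)
    cy <- to_cylindrical(data.frame(tau = tau, zeta = zeta), g)
    v <- flow_velocity(fl, cy)
    b <- basis_vectors(data.frame(tau = tau, zeta = zeta), g)
    u_tau <- v$u_r * b$e_tau_r + v$u_z * b$e_tau_z
    expect_equal(u_tau, dpsi / (hc$h_zeta * hc$h_phi), tolerance = 1e-6)
  }
})

test_that("boundary velocity reproduces the prescribed slip", {
  g <- embryo()
  fl <- dros_flow()
  vs <- slip_drosophila()
  zeta <- seq(-0.97, 0.97, length.out = 50)
  bdry <- to_cylindrical(data.frame(tau = g$tau0, zeta = zeta), g)
  v <- flow_velocity(fl, bdry)
  b <- basis_vectors(data.frame(tau = g$tau0, zeta = zeta), g)
  u_tau <- v$u_r * b$e_tau_r + v$u_z * b$e_tau_z
  u_zeta <- v$u_r * b$e_zeta_r + v$u_z * b$e_zeta_z
  vmax <- max(abs(vs$shape(zeta)))
  # impenetrability at solver precision
  expect_lt(max(abs(u_tau)), 1e-9 * vmax)
  # tangential slip reproduced to the truncation floor of the expansion
  expect_lt(max(abs(u_zeta - vs$shape(zeta))), 2e-3 * vmax)
})

test_that("slip reconstruction error decreases with truncation order", {
  g <- embryo()
  vs <- slip_drosophila()
  zeta <- seq(-0.99, 0.99, length.out = 201)
  rms <- vapply(c(4, 8, 12, 16, 20), function(nmax) {
    co <- slip_coefficients(vs, g, nmax = nmax)
    sqrt(mean((reconstruct_slip(co, zeta, g) - vs$shape(zeta))^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("velocity is linear in the slip amplitude", {
  g <- embryo()
  set.seed(9)
  B <- tibble::tibble(n = 1:6, B = stats::rnorm(6))
  class(B) <- c("mode_coefficients", class(B))
  B2 <- B; B2$B <- 2 * B2$B
  f1 <- stokes_flow(B, g, nmax = 8)
  f2 <- stokes_flow(B2, g, nmax = 8)
  P <- random_interior_points(20, g, seed = 2, margin = 0.98)
  pts <- data.frame(r = sqrt(P[, 1]^2 + P[, 2]^2), z = P[, 3])
  v1 <- flow_velocity(f1, pts)
  v2 <- flow_velocity(f2, pts)
  expect_equal(v2$u_r, 2 * v1$u_r, tolerance = 1e-12)
  expect_equal(v2$u_z, 2 * v1$u_z, tolerance = 1e-12)
})

test_that("the field is incompressible by finite differences", {
  g <- embryo()
  fl <- dros_flow()
  # cylindrical divergence (1/r) d(r u_r)/dr + d u_z/dz on an interior grid
  zg <- seq(-200, 200, length.out = 50)
  h <- 0.05
  pts <- purrr::map_dfr(zg, function(z) {
    rmax <- 0.9 * g$bx * sqrt(1 - (z / g$bz)^2)
    tibble::tibble(r = seq(5, rmax, length.out = 50), z = z)
  })
  vp <- flow_velocity(fl, transform(pts, r = r + h))
  vm <- flow_velocity(fl, transform(pts, r = r - h))
  wz <- flow_velocity(fl, transform(pts, z = z + h))
  wm <- flow_velocity(fl, transform(pts, z = z - h))
  div <- ((pts$r + h) * vp$u_r - (pts$r - h) * vm$u_r) / (2 * h * pts$r) +
    (wz$u_z - wm$u_z) / (2 * h)
  vmax <- max(sqrt(vp$u_r^2 + vp$u_z^2))
  expect_lt(max(abs(div)), 1e-6 * vmax / g$bx * g$bx) # |div| << u/bx scale
  expect_lt(max(abs(div)) / (vmax / g$bx), 1e-4)
})

test_that("truncation differences behave as the mode ladder predicts", {
  g <- embryo()
  vs <- slip_drosophila()
  # identical orders differ by exactly zero
  expect_identical(truncation_study(vs, g, 14, 14), 0)
  # a single boundary mode still cascades to higher orders through the
  # E-coupling, but the cascade decays geometrically: each +4 orders of
  # truncation shrinks the remaining difference several-fold
  B2 <- tibble::tibble(n = 2, B = 1)
  class(B2) <- c("mode_coefficients", class(B2))
  grid <- interior_grid(g, n_z = 30, n_r = 15)
  diffs <- vapply(c(7, 11, 15, 19), function(nm) {
    f1 <- stokes_flow(B2, g, nmax = nm)
    f2 <- stokes_flow(B2, g, nmax = nm + 8)
    v1 <- flow_velocity(f1, grid)
    v2 <- flow_velocity(f2, grid)
    d <- sqrt((v1$u_r - v2$u_r)^2 + (v1$u_z - v2$u_z)^2)
    max(d) / max(sqrt(v2$u_r^2 + v2$u_z^2))
  }, numeric(1))
  expect_true(all(diff(log(diffs)) < log(0.5)))
  expect_lt(diffs[4], 1e-3)
})

test_that("single-mode slips drive flows with the matching vortex count", {
  g <- embryo()
  for (m in 1:4) {
    fl <- stokes_flow(slip_mode(m, g), g)
    expect_identical(count_vortices(fl), m)
  }
  # zero flow is rejected by the counter
  B0 <- slip_coefficients(slip_profile(function(z) 0 * z, "null"), g, 8)
  f0 <- stokes_flow(B0, g, nmax = 9)
  expect_error(count_vortices(f0), "floor")
})

test_that("field export writes a deterministic CSV and coefficient JSON", {
  g <- embryo()
  fl <- dros_flow()
  d1 <- file.path(tempdir(), "f1.csv"); j1 <- file.path(tempdir(), "f1.json")
  d2 <- file.path(tempdir(), "f2.csv")
  grid <- interior_grid(g, n_z = 10, n_r = 5)
  export_flow_field(fl, d1, j1, grid = grid)
  export_flow_field(fl, d2, grid = grid)
  expect_identical(readLines(d1), readLines(d2))
  js <- jsonlite::read_json(j1)
  expect_equal(js$nmax, 14)
  expect_equal(js$geometry$tau0, g$tau0, tolerance = 1e-12)
  expect_equal(length(js$B), 13)
})
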