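test_that("the Drosophila slip shape has the documented zeros", {
  vs <- slip_drosophila()
  zs <- stagnation_zeta()
  expect_equal(zs, -0.2163, tolerance = 5e-4)
  expect_equal(vs$shape(zs), 0, tolerance = 1e-14)
  expect_equal(vs$shape(c(-1, 1)), c(0, 0), tolerance = 1e-14)
  # single interior zero: sign change only at zeta*
  zeta <- seq(-0.999, 0.999, length.out = 2001)
  sgn <- sign(vs$shape(zeta))
  expect_equal(sum(diff(sgn) != 0), 1)
})

test_that("initial clouds are reproducible and have uniform-disk moments", {
  g <- embryo()
  cl1 <- sample_nuclei(500, g, seed = 5)
  cl2 <- sample_nuclei(500, g, seed = 5)
  expect_identical(cl1, cl2)
  zc <- g$bz * stagnation_zeta()
  d <- sqrt(cl1$x^2 + cl1$y^2 + (cl1$z - zc)^2)
  expect_true(all(d <= 60 + 1e-12))
  # large sample: centre and disk moments E[d^2] = R^2/2, Var(z) = R^2/4
  big <- sample_nuclei(1e5, g, seed = 6)
  expect_lt(abs(mean(big$z) - zc), 1)
  expect_lt(abs(mean(big$x)), 1)
  d2 <- big$x^2 + big$y^2 + (big$z - zc)^2
  expect_equal(mean(d2), 60^2 / 2, tolerance = 0.02)
  expect_equal(mean((big$z - zc)^2), 60^2 / 4, tolerance = 0.02)
  # axial marginal is the semicircle: compare the CDF at quartile points
  semicdf <- function(u) 0.5 + (u * sqrt(1 - u^2) + asin(u)) / pi
  for (u in c(-0.5, 0, 0.5)) {
    expect_equal(mean(big$z - zc <= u * 60), semicdf(u), tolerance = 0.01)
  }
})

test_that("advection preserves fixed points, azimuth and chi = 0 identity", {
  g <- embryo()
  fl <- dros_flow()
  cl <- sample_nuclei(20, g, seed = 8)
  snap0 <- advect(cl, fl, chi = 0)
  expect_equal(snap0$x, cl$x)
  expect_equal(snap0$z, cl$z)
  # the on-axis stagnation point of the flow stays fixed
  zstar <- stats::uniroot(function(z) {
    flow_velocity(fl, data.frame(r = 0, z = z))$u_z
  }, c(-80, -30), tol = 1e-12)$root
  stay <- advect(tibble::tibble(particle = 1, x = 0, y = 0, z = zstar),
                 fl, chi = c(50, 200))
  expect_lt(max(abs(stay$z - zstar)), 1e-6)
  expect_lt(max(abs(stay$x)), 1e-9)
  # axisymmetric flow preserves each particle's azimuth
  snap <- advect(cl, fl, chi = 120)
  phi0 <- atan2(cl$y, cl$x)
  phi1 <- atan2(snap$y, snap$x)
  moved <- sqrt(snap$x^2 + snap$y^2) > 1e-6
  expect_lt(max(abs(sin(phi1 - phi0)[moved])), 1e-9)
})

test_that("transport depends on the amplitude history only through chi", {
  g <- embryo()
  fl <- dros_flow()
  cl <- sample_nuclei(4, g, seed = 13)
  amp <- amplitude_gaussians(0.3, 400, 100)
  t_end <- 800
  chi_end <- chi_from_amplitude(amp, t_end)
  ref <- advect(cl, fl, chi = chi_end, dchi = 0.1)
  # independent time-domain integration of dx/dt = V(t) u(x)
  x <- cl$x; y <- cl$y; z <- cl$z
  vel <- function(x, y, z, t) {
    r <- sqrt(x^2 + y^2)
    v <- flow_velocity(fl, data.frame(r = r, z = z))
    Vt <- amplitude_value(amp, t)
    ct <- ifelse(r > 0, x / r, 0); st <- ifelse(r > 0, y / r, 0)
    list(ux = Vt * v$u_r * ct, uy = Vt * v$u_r * st, uz = Vt * v$u_z)
  }
  tt <- 0; dt <- 0.5
  while (tt < t_end - 1e-9) {
    h <- min(dt, t_end - tt)
    k1 <- vel(x, y, z, tt)
    k2 <- vel(x + h / 2 * k1$ux, y + h / 2 * k1$uy, z + h / 2 * k1$uz, tt + h / 2)
    k3 <- vel(x + h / 2 * k2$ux, y + h / 2 * k2$uy, z + h / 2 * k2$uz, tt + h / 2)
    k4 <- vel(x + h * k3$ux, y + h * k3$uy, z + h * k3$uz, tt + h)
    x <- x + h / 6 * (k1$ux + 2 * k2$ux + 2 * k3$ux + k4$ux)
    y <- y + h / 6 * (k1$uy + 2 * k2$uy + 2 * k3$uy + k4$uy)
    z <- z + h / 6 * (k1$uz + 2 * k2$uz + 2 * k3$uz + k4$uz)
    tt <- tt + h
  }
  expect_lt(max(abs(c(ref$x - x, ref$y - y, ref$z - z))), 1e-6)
})

test_that("the advected flow map is volume preserving", {
  g <- embryo()
  fl <- dros_flow()
  # determinant of the flow-map Jacobian, estimated from an advected
  # tetrahedron of small edge h, stays at 1 (incompressible flow)
  base <- c(30, 10, -60)
  h <- 0.05
  corners <- rbind(base,
                   base + c(h, 0, 0),
                   base + c(0, h, 0),
                   base + c(0, 0, h))
  cl <- tibble::tibble(particle = 1:4, x = corners[, 1], y = corners[, 2],
                       z = corners[, 3])
  snap <- advect(cl, fl, chi = 300, dchi = 0.25)
  M <- cbind(
    c(snap$x[2] - snap$x[1], snap$y[2] - snap$y[1], snap$z[2] - snap$z[1]),
    c(snap$x[3] - snap$x[1], snap$y[3] - snap$y[1], snap$z[3] - snap$z[1]),
    c(snap$x[4] - snap$x[1], snap$y[4] - snap$y[1], snap$z[4] - snap$z[1])
  ) / h
  expect_equal(abs(det(M)), 1, tolerance = 0.01)
})

test_that("axial kernel density matches direct evaluation and normalizes", {
  grid <- seq(-270, 270, by = 1)
  # single particle: Gaussian peak of height 1/(R sqrt(2 pi))
  d1 <- axial_density(15, bandwidth = 7, grid = grid)
  expect_equal(max(d1$rho), 1 / (7 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(d1$z[which.max(d1$rho)], 15)
  expect_equal(sum(d1$rho) * 1, 1, tolerance = 1e-6)
  # N coincident particles equal the single-particle profile
  dN <- axial_density(rep(15, 40), bandwidth = 7, grid = grid)
  expect_equal(dN$rho, d1$rho)
  # two particles at +-50, R = 7: direct two-term sum at 20 grid points
  d2 <- axial_density(c(-50, 50), bandwidth = 7, grid = grid)
  at <- seq(-95, 95, by = 10)
  direct <- (exp(-(at + 50)^2 / (2 * 7^2)) + exp(-(at - 50)^2 / (2 * 7^2))) /
    (2 * 7 * sqrt(2 * pi))
  expect_equal(d2$rho[match(at, d2$z)], direct, tolerance = 1e-12)
})

test_that("variance measure of homogeneity has the expected closed forms", {
  g <- embryo()
  grid <- seq(-g$bz, g$bz, by = 0.5)
  # constant density: zero variance
  expect_equal(variance_phi(tibble::tibble(z = grid, rho = 1 / (2 * g$bz)), g), 0)
  # rho = rbar (1 + cos(pi z / bz)): Phi = rbar^2 * bz
  rbar <- 1 / (2 * g$bz)
  rho <- rbar * (1 + cos(pi * grid / g$bz))
  expect_equal(variance_phi(tibble::tibble(z = grid, rho = rho), g),
               rbar^2 * g$bz, tolerance = 1e-5)
  # adding a constant leaves Phi unchanged (mean is recomputed)
  expect_equal(
    variance_phi(tibble::tibble(z = grid, rho = rho + 0.37), g),
    variance_phi(tibble::tibble(z = grid, rho = rho), g),
    tolerance = 1e-9
  )
})

test_that("strip-count variance follows the population-variance formula", {
  g <- embryo()
  # all N particles in one of 10 strips
  z <- rep(-200, 25)
  counts <- c(25, rep(0, 9))
  expect_equal(strip_variance(z, 10, g),
               mean((counts - mean(counts))^2))
  # equal counts: zero variance (one particle centred in each strip)
  centres <- seq(-g$bz + 27, g$bz - 27, length.out = 10)
  expect_equal(strip_variance(centres, 10, g), 0)
  # permutation invariance: scrambling strip labels leaves Phi unchanged
  set.seed(1)
  z2 <- stats::runif(40, -g$bz, g$bz)
  expect_equal(strip_variance(z2, 10, g), strip_variance(rev(z2), 10, g))
})

test_that("chi accumulates the amplitude history", {
  # constant amplitude
  flat <- tibble::tibble(t = seq(0, 100, by = 1), v = 0.3)
  expect_equal(chi_from_amplitude(flat, 100), 30, tolerance = 1e-12)
  # single Gaussian over all time: a c sqrt(2 pi)
  amp <- amplitude_gaussians(0.25, 2000, 80)
  expect_equal(chi_from_amplitude(amp, Inf), 0.25 * 80 * sqrt(2 * pi),
               tolerance = 1e-9)
  # trapezoid on a fine tabulation matches the analytic Gaussian integral
  ts <- seq(0, 4000, by = 2)
  tab <- tibble::tibble(t = ts, v = amplitude_value(amp, ts))
  expect_equal(chi_from_amplitude(tab, 4000), chi_from_amplitude(amp, 4000),
               tolerance = 1e-3 * chi_from_amplitude(amp, 4000))
  # monotone non-decreasing in t
  chis <- chi_from_amplitude(amp, c(100, 1000, 2500, 8000))
  expect_true(all(diff(chis) >= 0))
})

test_that("Gaussian-sum fitting recovers known amplitude histories", {
  tr <- seq(0, 2400, by = 10)
  true <- amplitude_gaussians(c(0.18, 0.24, 0.30), c(600, 1200, 1800),
                              c(70, 75, 80))
  set.seed(42)
  v <- amplitude_value(true, tr) * (1 + stats::rnorm(length(tr), 0, 0.01))
  fit <- fit_amplitude_gaussians(tibble::tibble(t = tr, v = v), n_peaks = 3)
  est <- fit$series
  expect_equal(sort(est$a), sort(true$a), tolerance = 0.05)
  expect_equal(sort(est$b), sort(true$b), tolerance = 0.05)
  expect_equal(sort(est$c), sort(true$c), tolerance = 0.05)
  expect_equal(fit$chi_total, chi_from_amplitude(true, Inf), tolerance = 0.02)

  # a single clean Gaussian is recovered to optimizer tolerance
  v1 <- amplitude_value(amplitude_gaussians(0.3, 900, 100), tr)
  f1 <- fit_amplitude_gaussians(tibble::tibble(t = tr, v = v1), n_peaks = 1)
  expect_equal(f1$series$a, 0.3, tolerance = 1e-6)
  expect_equal(f1$series$b, 900, tolerance = 1e-4)
  expect_equal(f1$series$c, 100, tolerance = 1e-4)

  # rescaling amplitudes by k rescales a_i, leaves b_i and c_i fixed
  f2 <- fit_amplitude_gaussians(tibble::tibble(t = tr, v = 2 * v1), n_peaks = 1)
  expect_equal(f2$series$a, 2 * f1$series$a, tolerance = 1e-5)
  expect_equal(f2$series$b, f1$series$b, tolerance = 1e-4)
  expect_equal(f2$series$c, f1$series$c, tolerance = 1e-4)
})

test_that("nuclear division spreads the cloud and lowers the axial variance", {
  g <- embryo()
  # two coincident daughters separate under the repulsion
  cl <- tibble::tibble(particle = 1, x = 0, y = 0, z = 10)
  d <- divide_nuclei(cl, g, seed = 3)
  expect_equal(nrow(d), 2)
  sep <- sqrt(diff(d$x)^2 + diff(d$y)^2 + diff(d$z)^2)
  expect_gt(sep, 1)
  # nuclei never exit the spheroid
  inside <- function(p) all((p$x^2 + p$y^2) / g$bx^2 + p$z^2 / g$bz^2 < 1)
  expect_true(inside(d))
  # ensemble sign test on the pre-cycle-6 configuration with R = 28 um:
  # one division round lowers the axial variance
  dphi <- vapply(1:100, function(k) {
    cl <- sample_division_cloud(32, seed = 1000 + k)
    div <- divide_nuclei(cl, g, seed = 2000 + k)
    expect_true(inside(div))
    before <- variance_phi(axial_density(cl$z, 28, geometry = g), g)
    after <- variance_phi(axial_density(div$z, 28, geometry = g), g)
    (after - before) / before
  }, numeric(1))
  expect_lt(mean(dphi), 0)
  expect_gt(mean(dphi < 0), 0.9)
})
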