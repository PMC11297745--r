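test_that("reciprocity holds to solver precision", {
  mesh <- fix_mesh()
  fld <- fix_water_field()
  z1 <- simulate_scheme(mesh, fld, data.frame(A = 1, B = 8, M = 20, N = 25))$Z[1, 1]
  z2 <- simulate_scheme(mesh, fld, data.frame(A = 20, B = 25, M = 1, N = 8))$Z[1, 1]
  expect_lt(abs(z1 - z2) / abs(z1), 1e-10)
})

test_that("potentials scale as 1/c when the field is scaled by a complex constant", {
  mesh <- fix_mesh()
  c0 <- 2.5 * exp(-0.02i)
  f1 <- complex_field(100, rep(0.01 + 0i, nrow(mesh$cells)))
  f2 <- complex_field(100, c0 * f1$sigma)
  u1 <- solve_dipole(mesh, f1, c(3, 30))$u
  u2 <- solve_dipole(mesh, f2, c(3, 30))$u
  expect_lt(max(abs(u2 - u1 / c0)), 1e-9 * max(abs(u1)))
})

test_that("homogeneous solution matches the truncated cosine-series oracle to <0.5%", {
  geom <- fix_geometry()
  mesh <- fix_mesh()
  sigma <- 0.0105
  fld <- complex_field(0, rep(sigma + 0i, nrow(mesh$cells)))
  sol <- solve_dipole(mesh, fld, c(2, 5))
  probes <- 17:21                 # bottom-row electrodes away from the dipole
  u_fem <- Re(sol$u[mesh$electrode_nodes[probes]])
  u_ser <- series_potential(geom$electrodes[probes, ], geom$electrodes[2, ],
                            geom$electrodes[5, ], geom$width, geom$height,
                            sigma, geom$thickness, nterms = 400)
  dif_f <- u_fem - u_fem[1]
  dif_s <- u_ser - u_ser[1]
  expect_lt(max(abs(dif_f[-1] - dif_s[-1]) / abs(dif_s[-1])), 0.005)
  # a finer mesh gets closer to the oracle
  mesh2 <- build_mesh(geom, refinement_level = 0.3, base_h = 0.04)
  sol2 <- solve_dipole(mesh2, complex_field(0, rep(sigma + 0i, nrow(mesh2$cells))),
                       c(2, 5))
  u2 <- Re(sol2$u[mesh2$electrode_nodes[probes]])
  dif_2 <- u2 - u2[1]
  expect_lt(max(abs(dif_2[-1] - dif_s[-1]) / abs(dif_s[-1])),
            max(abs(dif_f[-1] - dif_s[-1]) / abs(dif_s[-1])))
})

test_that("homogeneous fields pass their intrinsic phase through to apparent phase", {
  mesh <- fix_mesh()
  sch <- fix_scheme()
  K <- geometric_factors(mesh, sch)
  # real field: all apparent phases zero
  ds0 <- simulate_scheme(mesh, fix_water_field(), sch)
  expect_lt(max(abs(Arg(K * ds0$Z[, 1]) * 1000)), 1e-9)
  # -10 mrad intrinsic phase appears in every apparent phase
  sig <- rep(complex(modulus = 0.0105, argument = 0.010), nrow(mesh$cells))
  ds1 <- simulate_scheme(mesh, complex_field(1000, sig), sch)
  expect_lt(max(abs(Arg(K * ds1$Z[, 1]) * 1000 + 10)), 1e-6)
})

test_that("geometric factors reproduce the reference resistivity and are scale invariant", {
  mesh <- fix_mesh()
  sch <- fix_scheme()
  K100 <- geometric_factors(mesh, sch, 100)
  fld <- complex_field(0, rep(1 / 100 + 0i, nrow(mesh$cells)))
  Z <- Re(simulate_scheme(mesh, fld, sch)$Z[, 1])
  expect_equal(K100 * Z, rep(100, nrow(sch)), tolerance = 1e-9,
               ignore_attr = TRUE)
  K37 <- geometric_factors(mesh, sch, 37)
  expect_equal(as.numeric(K100), as.numeric(K37), tolerance = 1e-10)
})

test_that("mirror-symmetric quadrupoles share geometric factors", {
  # symmetric 6-electrode layout on a unit-square tank
  el <- rbind(c(0.1, 0), c(0.9, 0), c(0.1, 0.6), c(0.9, 0.6),
              c(0.3, 0.3), c(0.7, 0.3))
  g <- rhizotron_geometry(1, 1, 0.02, electrodes = el,
                          roi = c(0.2, 0.8, 0.2, 0.8))
  mesh <- build_mesh(g, 0.4, 0.1)
  K <- geometric_factors(mesh, data.frame(A = c(1, 2), B = c(3, 4),
                                          M = c(5, 6), N = c(6, 5)))
  expect_equal(K[1], K[2], tolerance = 1e-8)
})

test_that("sensitivity rows sum to one on a homogeneous model", {
  mesh <- fix_mesh()
  J <- sensitivity_matrix(mesh, rep(95.15, nrow(mesh$cells)), fix_scheme(20))
  expect_equal(rowSums(J), rep(1, 20), tolerance = 1e-6)
})

test_that("adjoint sensitivities match central finite differences", {
  mesh <- fix_mesh()
  m <- nrow(mesh$cells)
  set.seed(11)
  rho <- exp(log(95) + 0.3 * rnorm(m))
  sch <- fix_scheme(6)
  K <- geometric_factors(mesh, sch)
  J <- sensitivity_matrix(mesh, rho, sch)
  cells <- sample(m, 20)
  h <- 0.01
  for (cc in cells) {
    lp <- log(rho); lp[cc] <- lp[cc] + h
    lm <- log(rho); lm[cc] <- lm[cc] - h
    fd <- (rootEIT:::forward_lnrhoa(mesh, sch, lp, K) -
           rootEIT:::forward_lnrhoa(mesh, sch, lm, K)) / (2 * h)
    expect_lt(max(abs(fd - J[, cc])) / (max(abs(fd)) + 1e-12), 1e-3)
  }
})

test_that("reciprocal quadrupoles give identical sensitivity rows", {
  mesh <- fix_mesh()
  sch <- data.frame(A = c(1, 20), B = c(8, 25), M = c(20, 1), N = c(25, 8))
  J <- sensitivity_matrix(mesh, rep(95, nrow(mesh$cells)), sch)
  expect_lt(max(abs(J[1, ] - J[2, ])), 1e-10 * max(abs(J)))
})

test_that("invalid schemes and fields are rejected", {
  mesh <- fix_mesh()
  expect_error(as_scheme(data.frame(A = 1, B = 1, M = 2, N = 3)), "repeated")
  expect_error(simulate_scheme(mesh, fix_water_field(),
                               data.frame(A = 1, B = 2, M = 3, N = 99)),
               "unknown electrode")
  expect_error(complex_field(10, c(1 + 0i, -1 + 0i)), "positive")
})
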