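test_that("error-weighted RMS matches hand computations", {
  em <- error_model(0.1, 0.5, 1)
  z <- rep(10 + 0i, 4)
  expect_equal(rms_error(z, z, em), 0)
  # every residual exactly one error estimate (magnitude shifted by a|Z|+b,
  # phase by c) -> RMS 1
  zp <- (10 - (0.1 * 10 + 0.5)) * exp(-1i / 1000)
  expect_equal(rms_error(z, rep(zp, 4), em), 1, tolerance = 1e-3)
  # residuals {2 delta, 0, 0, 0} on 4 data -> sqrt(4/4) = 1 per stream
  zp2 <- c(10 * exp(-2i / 1000), z[2:4])
  expect_equal(rms_error(z, zp2, em, component = "phase"), 1,
               tolerance = 1e-9)
  # pooled over 8 residuals (4 magnitude zeros + phases {2,0,0,0})
  expect_equal(rms_error(z, zp2, em), sqrt(4 / 8), tolerance = 1e-9)
  expect_error(rms_error(z, z[1:2], em), "mismatch")
})

test_that("noiseless homogeneous data invert back to the homogeneous truth", {
  mesh <- fix_mesh()
  ds <- fix_water_dataset()
  em <- error_model(0.01, 0.001, 0.5)
  inv <- invert_frequency(ds, mesh, em)
  rho_true <- 1 / (105.1e-4 / 100)
  expect_lt(max(abs(abs(1 / inv$field$sigma) - rho_true)) / rho_true, 0.01)
  expect_lt(inv$rms_mag, 0.1)
  # zero-phase data: recovered phase is null
  expect_lt(max(abs(field_phase_mrad(inv$field))), 0.1)
})

test_that("matched-noise phantom inversion converges to RMS in [0.9, 1.1]", {
  mesh <- fix_mesh()
  ph <- fix_phantom()
  sch <- fix_scheme()
  ds <- simulate_scheme(mesh, ph$fields[1], sch)
  ds$K <- geometric_factors(mesh, sch)
  noisy <- contaminate(ds, 0.01, 0.001, 0.5, seed = 5)
  inv <- invert_frequency(noisy, mesh, error_model(0.01, 0.001, 0.5))
  expect_gte(inv$rms_mag, 0.5)   # not over-fit
  expect_true(inv$rms >= 0.9 && inv$rms <= 1.1)
  expect_true(inv$converged)
  memo("phantom_inv", inv)
})

test_that("recovered anomalies are smooth (no single-cell checkerboard)", {
  mesh <- fix_mesh()
  inv <- memo("phantom_inv", {
    ph <- fix_phantom()
    ds <- simulate_scheme(mesh, ph$fields[1], fix_scheme())
    ds$K <- geometric_factors(mesh, fix_scheme())
    invert_frequency(contaminate(ds, 0.01, 0.001, 0.5, seed = 5),
                     mesh, error_model(0.01, 0.001, 0.5))
  })
  phi <- field_phase_mrad(inv$field)
  e <- mesh$edges
  neighbour_diff <- abs(phi[e[, 1]] - phi[e[, 2]])
  # neighbour jumps stay well below the anomaly amplitude
  expect_lt(max(neighbour_diff), 0.5 * diff(range(phi)))
})

test_that("band inversion runs in-band frequencies only", {
  mesh <- fix_mesh()
  sch <- fix_scheme(40)
  freqs <- c(0.5, 1, 1000, 45000)
  flds <- lapply(freqs, function(f)
    complex_field(f, rep(0.0105 + 0i, nrow(mesh$cells))))
  ds <- simulate_scheme(mesh, flds, sch)
  ds$K <- geometric_factors(mesh, sch)
  res <- invert_band(ds, mesh, error_model(0.02, 0.01, 0.5))
  expect_equal(names(res), c("1", "1000"))
  expect_equal(attr(res, "skipped"), c(0.5, 45000))
  expect_error(invert_band(ds, mesh, error_model(0.02, 0.01, 0.5),
                           f_min = 2000, f_max = 3000), "band")
  # single-frequency band equals invert_frequency
  one <- invert_band(ds, mesh, error_model(0.02, 0.01, 0.5),
                     f_min = 999, f_max = 1001)
  direct <- invert_frequency(ds, mesh, error_model(0.02, 0.01, 0.5),
                             freq_index = 3)
  expect_equal(one[["1000"]]$field$sigma, direct$field$sigma)
})

test_that("averaging fields is cellwise in log-magnitude and phase and cuts variance", {
  mesh <- fix_mesh()
  n <- nrow(mesh$cells)
  f1 <- complex_field(1000, 1 / (95 * exp(-10i / 1000)) + numeric(n))
  f2 <- complex_field(1000, 1 / (95 * exp(-20i / 1000)) + numeric(n))
  avg <- average_inversions(list(f1, f2))
  expect_equal(field_phase_mrad(avg), rep(-15, n), tolerance = 1e-9)
  expect_equal(average_inversions(list(f1, f1))$sigma, f1$sigma,
               tolerance = 1e-12)
  expect_error(average_inversions(list(f1, complex_field(1000, c(0.01 + 0i)))),
               "different meshes")
  # ensemble averaging reduces background phase variance
  ph <- fix_phantom()
  ds <- simulate_scheme(mesh, ph$fields[1], fix_scheme())
  ds$K <- geometric_factors(mesh, fix_scheme())
  em <- error_model(0.01, 0.001, 0.5)
  flds <- lapply(1:3, function(r)
    invert_frequency(contaminate(ds, 0.01, 0.001, 0.5, seed = 100 + r),
                     mesh, em)$field)
  bg <- ph$m_tot == 0
  v_single <- mean(sapply(flds, function(f) var(field_phase_mrad(f)[bg])))
  v_avg <- var(field_phase_mrad(average_inversions(flds))[bg])
  expect_lt(v_avg, v_single)
})
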