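test_that("volume-weighted chargeability averaging follows the cell volumes", {
  mesh <- fix_mesh()
  n <- nrow(mesh$cells)
  mask <- root_zone_mask(mesh, cells = seq(5, n, by = 11))
  # uniform image: mean equals the value for any mask
  expect_equal(average_chargeability(rep(0.042, n), mask, mesh), 0.042)
  # two cells, volumes 1 and 3, values 0.04 / 0.08 -> 0.07
  m2 <- mesh
  m2$cell_volumes <- c(1, 3)
  mk2 <- structure(list(cells = 1:2, V_rz = 4, n = 2), class = "root_zone_mask")
  expect_equal(average_chargeability(c(0.04, 0.08), mk2, m2), 0.07)
  expect_error(average_chargeability(rep(1, n),
                                     structure(list(cells = integer(0)),
                                               class = "root_zone_mask"),
                                     mesh), "empty")
})

test_that("integrated chargeability converts to cm^3 and is additive", {
  expect_equal(integrated_chargeability(0, 1), 0)
  # m_bar 0.01 over 500 cm^3 -> 5 cm^3
  expect_equal(integrated_chargeability(0.01, 500e-6), 5)
  # additivity over a disjoint union
  mesh <- fix_mesh()
  m_tot <- runif(nrow(mesh$cells))
  a <- root_zone_mask(mesh, cells = 1:100)
  b <- root_zone_mask(mesh, cells = 201:300)
  u <- root_zone_mask(mesh, cells = c(1:100, 201:300))
  mrz <- function(msk) integrated_chargeability(
    average_chargeability(m_tot, msk, mesh), msk$V_rz)
  expect_equal(mrz(u), mrz(a) + mrz(b), tolerance = 1e-12)
})

test_that("averaged relaxation time is the volume-weighted mean over unmasked cells", {
  mesh <- fix_mesh()
  n <- nrow(mesh$cells)
  tau <- rep(3e-3, n)
  mask <- root_zone_mask(mesh, cells = 1:50)
  expect_equal(averaged_relaxation_time(tau, mask, mesh), 3e-3)
  m2 <- mesh; m2$cell_volumes <- c(1, 1)
  mk2 <- structure(list(cells = 1:2), class = "root_zone_mask")
  expect_equal(averaged_relaxation_time(c(2e-3, 4e-3), mk2, m2), 3e-3)
  # NA cells are excluded; all-NA errors
  expect_equal(averaged_relaxation_time(c(2e-3, NA), mk2, m2), 2e-3)
  expect_error(averaged_relaxation_time(c(NA, NA), mk2, m2), "masked")
})

test_that("trait prediction evaluates the power-law calibrations", {
  p <- predict_traits(1)
  expect_equal(p$A_surf, 221)
  expect_equal(p$M_bio, 0.169)
  p0 <- predict_traits(0)
  expect_equal(p0$A_surf, 0)
  expect_equal(p0$M_bio, 0)
  # m_rz = 13.9 -> biomass ~ 2.0 g
  expect_equal(predict_traits(13.9)$M_bio, 0.169 * 13.9^0.94,
               tolerance = 1e-12)
  expect_equal(round(predict_traits(13.9)$M_bio, 1), 2.0)
  expect_error(predict_traits(-1), "non-negative")
})

test_that("power-law fitting is exact on exact data and matches a grid-search oracle", {
  x <- c(0.5, 1, 2, 4, 8, 16)
  y <- 2 * x^0.9
  fit <- fit_powerlaw(x, y)
  expect_equal(fit$coef, 2, tolerance = 1e-10)
  expect_equal(fit$exponent, 0.9, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  set.seed(17)
  for (trial in 1:10) {
    xs <- exp(runif(12, -1, 3))
    ys <- exp(runif(1, -1, 1)) * xs^runif(1, 0.3, 1.5) *
      exp(rnorm(12, 0, 0.2))
    f1 <- fit_powerlaw(xs, ys)
    f2 <- grid_search_powerlaw(xs, ys)
    expect_equal(f1$exponent, f2$exponent, tolerance = 5e-3)
    expect_equal(log10(f1$coef), log10(f2$coef), tolerance = 5e-3)
  }
  expect_error(fit_powerlaw(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_powerlaw(c(1, 2, -3), c(1, 2, 3)), "positive")
})

test_that("unit rescaling of x changes the coefficient analytically, not the exponent", {
  x <- c(1, 3, 9, 27); y <- 5 * x^0.8
  f1 <- fit_powerlaw(x, y)
  f2 <- fit_powerlaw(10 * x, y)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-10)
  expect_equal(f2$coef, f1$coef / 10^f1$exponent, tolerance = 1e-9)
})

test_that("image metrics behave on identity, negation and a hand-built PCC case", {
  mesh <- fix_mesh()
  n <- nrow(mesh$cells)
  set.seed(2)
  img <- rnorm(n)
  m <- image_metrics(img, img, mesh)
  expect_equal(m$pcc, 1)
  expect_gt(m$ssim, 0.999)
  expect_equal(image_metrics(img, -img, mesh)$pcc, -1)
  expect_error(image_metrics(rep(1, n), img, mesh), "constant")
  # PCC equals the covariance formula on a small hand-built case
  a <- c(1, 2, 3, 4, 2, 0, 1, 5, 3, 2, 4, 1, 0, 2, 3, 1)
  b <- c(2, 1, 4, 4, 1, 1, 0, 6, 2, 2, 5, 2, 1, 1, 4, 0)
  pcc_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cor(a, b), pcc_direct, tolerance = 1e-12)
})

test_that("background masking partitions cells at the 1e-3 threshold", {
  m <- c(1e-4, 9.99e-4, 1e-3, 2e-3, 0.05)
  expect_equal(mask_background(m), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(mask_background(rep(1e-4, 10))))
  # phantom root cells survive masking; water cells do not
  ph <- fix_phantom()
  bgmask <- mask_background(ph$m_tot)
  expect_true(all(bgmask[setdiff(seq_along(ph$m_tot), ph$root_cells)]))
  expect_false(any(bgmask[ph$root_cells]))
})

test_that("polygon masks match centroid-in-polygon point tests", {
  mesh <- fix_mesh()
  poly <- rbind(c(0.1, 0.1), c(0.4, 0.1), c(0.4, 0.35), c(0.1, 0.35))
  mask <- root_zone_mask(mesh, polygon = poly)
  cen <- mesh$cell_centroids
  expected <- which(cen[, 1] > 0.1 & cen[, 1] < 0.4 &
                    cen[, 2] > 0.1 & cen[, 2] < 0.35)
  expect_equal(mask$cells, expected)
  expect_equal(mask$V_rz, sum(mesh$cell_volumes[expected]))
})
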