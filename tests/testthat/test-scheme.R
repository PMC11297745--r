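test_that("candidate enumeration matches brute force for 4 electrodes", {
  el <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  cand <- enumerate_candidates(el)
  bf <- brute_force_candidates(4)
  expect_equal(cand, bf)
  # 3 reciprocal-unique dipole pairings x 2 orientations... minus reciprocal
  # duplicates kept once each
  expect_equal(nrow(cand), 3)
})

test_that("pool rules restrict dipoles and the pool is duplicate-free", {
  el <- fix_geometry()$electrodes
  ab <- rbind(c(1, 8), c(2, 9))
  cand <- enumerate_candidates(el, list(ab_dipoles = ab))
  expect_true(all(paste(cand$A, cand$B) %in% c("1 8", "2 9")))
  cand2 <- enumerate_candidates(el, list(min_ab_sep = 0.2, max_mn_sep = 0.15))
  expect_equal(anyDuplicated(cand2), 0)
  expect_error(enumerate_candidates(el[1:3, ]), "at least 4")
})

test_that("resolution diagonal reaches its limits in lambda", {
  set.seed(5)
  n <- 12
  J <- matrix(rnorm(n * n), n, n)          # full rank
  Wm <- Matrix::sparseMatrix(i = rep(1:(n - 1), 2),
                             j = c(1:(n - 1), 2:n),
                             x = rep(c(1, -1), each = n - 1),
                             dims = c(n - 1, n))
  r_lo <- resolution_diagonal(J, 1, Wm, 1e-12)
  expect_equal(r_lo, rep(1, n), tolerance = 1e-4)
  r_hi <- resolution_diagonal(J, 1, Wm, 1e12)
  expect_equal(r_hi, rep(0, n), tolerance = 1e-4)
  expect_error(resolution_diagonal(J, 1, Wm, 0), "positive")
  # matches a dense direct computation
  wd <- runif(n, 0.5, 2)
  expect_equal(resolution_diagonal(J, wd, Wm, 0.7),
               dense_resolution_diag(J, wd, Wm, 0.7), tolerance = 1e-10)
})

test_that("appending a configuration never decreases the resolution trace", {
  set.seed(6)
  m <- 15
  Wm <- Matrix::sparseMatrix(i = rep(1:(m - 1), 2),
                             j = c(1:(m - 1), 2:m),
                             x = rep(c(1, -1), each = m - 1),
                             dims = c(m - 1, m))
  for (trial in 1:50) {
    J <- matrix(rnorm(8 * m), 8, m)
    extra <- rnorm(m)
    t0 <- sum(resolution_diagonal(J, 1, Wm, 0.5))
    t1 <- sum(resolution_diagonal(rbind(J, extra), 1, Wm, 0.5))
    expect_gte(t1, t0 - 1e-8)
  }
})

test_that("greedy optimization meets the size and dipole budget with a monotone objective", {
  geom <- fix_geometry()
  dmesh <- memo("dmesh", build_mesh(geom, base_h = 0.05,
                                    refine_electrodes = FALSE))
  cand <- enumerate_candidates(geom$electrodes,
                               list(min_ab_sep = 0.2, n_ab_dipoles = 30,
                                    max_mn_sep = 0.15))
  sch <- optimize_scheme(dmesh, cand, target_size = 60, dipole_budget = 10,
                         batch = 10, n_start = 5)
  expect_equal(nrow(sch), 60)
  expect_lte(attr(sch, "injection_dipoles"), 10)
  obj <- attr(sch, "objective")
  expect_true(all(diff(obj) >= -1e-8))
  res <- attr(sch, "resolution")
  expect_true(all(res >= -1e-5 & res <= 1 + 1e-5))
  # determinism
  sch2 <- optimize_scheme(dmesh, cand, target_size = 60, dipole_budget = 10,
                          batch = 10, n_start = 5)
  expect_identical(sch, sch2)
  memo("small_opt_scheme", sch)
})

test_that("the optimized scheme beats random schemes on the ROI objective", {
  geom <- fix_geometry()
  dmesh <- memo("dmesh", build_mesh(geom, base_h = 0.05,
                                    refine_electrodes = FALSE))
  cand <- enumerate_candidates(geom$electrodes,
                               list(min_ab_sep = 0.2, n_ab_dipoles = 30,
                                    max_mn_sep = 0.15))
  sch <- memo("small_opt_scheme",
              optimize_scheme(dmesh, cand, target_size = 60,
                              dipole_budget = 10, batch = 10, n_start = 5))
  lambda <- attr(sch, "lambda")
  roi <- geom$roi
  cen <- dmesh$cell_centroids
  w <- ifelse(cen[, 1] >= roi[1] & cen[, 1] <= roi[2] &
              cen[, 2] >= roi[3] & cen[, 2] <= roi[4], 1, 0.05)
  Wm <- smoothness_matrix(dmesh)
  rho <- rep(95.15, nrow(dmesh$cells))
  obj_of <- function(s) {
    J <- sensitivity_matrix(dmesh, rho, s)
    sum(w * resolution_diagonal(J, 1, Wm, lambda))
  }
  # baseline draws come from the measurable part of the pool (near-null and
  # strongly cancelling configurations make the comparison degenerate)
  Jc <- sensitivity_matrix(dmesh, rho, cand)
  ok <- which(is.finite(rowSums(Jc)) & rowSums(abs(Jc)) <= 6)
  obj_opt <- obj_of(sch)
  set.seed(99)
  for (r in 1:20) {
    rnd <- cand[sample(ok, nrow(sch)), ]
    expect_gt(obj_opt, obj_of(rnd))
  }
})

test_that("electrode exclusion filters configurations and lowers ROI resolution", {
  geom <- fix_geometry()
  dmesh <- memo("dmesh", build_mesh(geom, base_h = 0.05,
                                    refine_electrodes = FALSE))
  cand <- enumerate_candidates(geom$electrodes,
                               list(min_ab_sep = 0.2, n_ab_dipoles = 30,
                                    max_mn_sep = 0.15))
  sch <- memo("small_opt_scheme",
              optimize_scheme(dmesh, cand, target_size = 60,
                              dipole_budget = 10, batch = 10, n_start = 5))
  expect_identical(exclude_electrodes(sch, integer(0)), sch)
  red <- exclude_electrodes(sch, geom$central_batch)
  expect_lt(nrow(red), nrow(sch))
  touched <- unlist(red[, 1:4])
  expect_false(any(touched %in% geom$central_batch))
  # ROI-weighted resolution drops at matched lambda
  lambda <- attr(sch, "lambda")
  roi <- geom$roi
  cen <- dmesh$cell_centroids
  w <- ifelse(cen[, 1] >= roi[1] & cen[, 1] <= roi[2] &
              cen[, 2] >= roi[3] & cen[, 2] <= roi[4], 1, 0.05)
  Wm <- smoothness_matrix(dmesh)
  rho <- rep(95.15, nrow(dmesh$cells))
  J_full <- sensitivity_matrix(dmesh, rho, sch)
  J_red <- sensitivity_matrix(dmesh, rho, red)
  expect_gt(sum(w * resolution_diagonal(J_full, 1, Wm, lambda)),
            sum(w * resolution_diagonal(J_red, 1, Wm, lambda)))
  # excluding everything flags an empty scheme
  expect_warning(out <- exclude_electrodes(sch, 1:36), "every configuration")
  expect_true(isTRUE(attr(out, "empty")))
})

test_that("scheme files round-trip", {
  sch <- fix_scheme(20)
  path <- tempfile(fileext = ".txt")
  write_scheme(sch, path, header = c(seed = "1"))
  back <- read_scheme(path)
  expect_equal(back, as_scheme(sch), ignore_attr = TRUE)
})
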