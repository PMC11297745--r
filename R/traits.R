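#' Root-zone mask from a polygon or cell list
#'
#' A root zone is the set of mesh cells whose centroids fall inside the
#' root-area polygon traced from rhizotron photographs (or an explicit cell
#' list). Cell volumes give the zone volume V_rz.
#'
#' @param mesh A `tri_mesh`.
#' @param polygon n x 2 matrix of polygon vertices (m), or `NULL`.
#' @param cells Explicit integer cell indices (alternative to `polygon`).
#' @return A `root_zone_mask`: list with `cells`, `V_rz` (m^3) and `n`.
#' @export
root_zone_mask <- function(mesh, polygon = NULL, cells = NULL) {
  if (is.null(cells)) {
    if (is.null(polygon)) stop("give a polygon or a cell list")
    inside <- point_in_polygon(mesh$cell_centroids, polygon)
    cells <- which(inside)
  }
  cells <- sort(unique(as.integer(cells)))
  if (any(cells < 1 | cells > nrow(mesh$cells))) stop("cells outside mesh")
  structure(list(cells = cells, V_rz = sum(mesh$cell_volumes[cells]),
                 n = length(cells)),
            class = "root_zone_mask")
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param pts n x 2 matrix of points.
#' @param poly m x 2 matrix of polygon vertices (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- matrix(pts, ncol = 2)
  px <- poly[, 1]; py <- poly[, 2]
  nv <- length(px)
  jx <- c(nv, seq_len(nv - 1))
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(nv)) {
    j <- jx[k]
    crosses <- ((py[k] > pts[, 2]) != (py[j] > pts[, 2])) &
      (pts[, 1] < (px[j] - px[k]) * (pts[, 2] - py[k]) / (py[j] - py[k]) + px[k])
    inside <- xor(inside, crosses)
  }
  inside
}

#' Volume-weighted mean chargeability of a root zone
#'
#' `m_bar = sum(V_k m_k) / sum(V_k)` over the member cells, accounting for
#' the varying cell volumes of the irregular grid.
#'
#' @param m_tot Per-cell total chargeability image.
#' @param mask A [root_zone_mask()].
#' @param mesh The mesh the image lives on.
#' @return Scalar mean chargeability.
#' @export
average_chargeability <- function(m_tot, mask, mesh) {
  cells <- mask$cells
  if (length(cells) == 0) stop("empty root-zone mask")
  V <- mesh$cell_volumes[cells]
  sum(V * m_tot[cells]) / sum(V)
}

#' Integrated root-zone chargeability
#'
#' `m_rz = V_rz * m_bar`, reported in cm^3 (the unit of the power-law
#' calibrations).
#'
#' @param m_bar Mean chargeability (dimensionless).
#' @param V_rz Root-zone volume in m^3.
#' @return m_rz in cm^3.
#' @export
integrated_chargeability <- function(m_bar, V_rz) {
  stopifnot(V_rz > 0)
  V_rz * 1e6 * m_bar
}

#' Volume-weighted mean relaxation time of a root zone
#'
#' `tau_bar = sum(V_k tau_mean_k) / V_rz` over member cells; cells with `NA`
#' relaxation time (masked background) are excluded.
#'
#' @param tau_mean Per-cell mean relaxation time image (s).
#' @param mask A [root_zone_mask()].
#' @param mesh The mesh.
#' @return Scalar tau_bar in s.
#' @export
averaged_relaxation_time <- function(tau_mean, mask, mesh) {
  cells <- mask$cells[!is.na(tau_mean[mask$cells])]
  if (length(cells) == 0) stop("all member cells are masked")
  V <- mesh$cell_volumes[cells]
  sum(V * tau_mean[cells]) / sum(V)
}

#' Power-law trait calibration constants
#'
#' Defaults are the calibrations linking integrated root-zone chargeability
#' (cm^3) to total root surface area (`A_surf ~ 221 m_rz^0.93`, cm^2) and dry
#' root biomass (`M_bio ~ 0.169 m_rz^0.94`, g).
#'
#' @param surface_coef,surface_exp Surface-area power law.
#' @param biomass_coef,biomass_exp Biomass power law.
#' @return A `powerlaw_calibration` object.
#' @export
trait_calibration <- function(surface_coef = 221, surface_exp = 0.93,
                              biomass_coef = 0.169, biomass_exp = 0.94) {
  stopifnot(surface_coef > 0, biomass_coef > 0)
  structure(list(surface_coef = surface_coef, surface_exp = surface_exp,
                 biomass_coef = biomass_coef, biomass_exp = biomass_exp),
            class = "powerlaw_calibration")
}

#' Predict root traits from integrated chargeability
#'
#' Evaluates the power-law calibrations at `m_rz` (cm^3).
#'
#' @param m_rz Integrated root-zone chargeability in cm^3 (>= 0).
#' @param calibration A [trait_calibration()].
#' @return List with `A_surf` (cm^2) and `M_bio` (g).
#' @export
predict_traits <- function(m_rz, calibration = trait_calibration()) {
  if (any(m_rz < 0)) stop("m_rz must be non-negative")
  list(A_surf = calibration$surface_coef * m_rz^calibration$surface_exp,
       M_bio = calibration$biomass_coef * m_rz^calibration$biomass_exp)
}

#' Fit a power law in log-log space
#'
#' Least-squares line in log10-log10 space, back-transformed to
#' `y = coef * x^exp`. R^2 and the Pearson correlation are reported in log
#' space (trait relations are fitted and plotted log-log).
#'
#' @param x,y Positive paired observations (>= 3 pairs).
#' @return List with `coef`, `exponent`, `r_squared`, `pcc`.
#' @export
fit_powerlaw <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) stop("need >= 3 pairs")
  if (any(x <= 0) || any(y <= 0)) stop("values must be positive")
  lx <- log10(x); ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  list(coef = 10^stats::coef(fit)[[1]], exponent = stats::coef(fit)[[2]],
       r_squared = r2, pcc = stats::cor(lx, ly))
}

#' Rasterize a per-cell image onto a regular pixel grid
#'
#' Nearest-cell sampling at pixel centres, used by the SSIM computation
#' (which requires a regular grid).
#'
#' @param mesh A `tri_mesh`.
#' @param values Per-cell values.
#' @param res Pixel size in m (default 2 mm).
#' @return Numeric matrix (rows = y, columns = x).
#' @export
rasterize_cells <- function(mesh, values, res = 0.002) {
  gx <- seq(res / 2, max(mesh$breaks_x) - res / 2, by = res)
  gy <- seq(res / 2, max(mesh$breaks_y) - res / 2, by = res)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  cells <- locate_cells(mesh, pts)
  matrix(values[cells], length(gy), length(gx), byrow = TRUE)
}

# mean structural similarity of two equal-size images (standard constants,
# 11 x 11 Gaussian window, sigma = 1.5); L = dynamic range of the reference
ssim_images <- function(img1, img2, L = diff(range(img1))) {
  if (L <= 0) stop("constant reference image: SSIM undefined")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  k <- stats::dnorm(seq(-5, 5), sd = 1.5); k <- k / sum(k)
  blur <- function(img) {
    # separable convolution, valid region only
    a <- apply(img, 2, function(col) stats::convolve(col, rev(k), type = "filter"))
    t(apply(t(a), 2, function(row) stats::convolve(row, rev(k), type = "filter")))
  }
  mu1 <- blur(img1); mu2 <- blur(img2)
  s11 <- blur(img1 * img1) - mu1^2
  s22 <- blur(img2 * img2) - mu2^2
  s12 <- blur(img1 * img2) - mu1 * mu2
  ssim <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim)
}

#' Image-reconstruction quality metrics
#'
#' Pearson correlation between the per-cell images, and structural similarity
#' (SSIM) between their rasterized versions (2 mm pixels, nearest-cell
#' sampling, standard SSIM constants with the true image's dynamic range).
#'
#' @param true_values,recon_values Per-cell images on the same mesh.
#' @param mesh The mesh.
#' @param res Raster resolution in m for SSIM.
#' @return List with `pcc` and `ssim`.
#' @export
image_metrics <- function(true_values, recon_values, mesh, res = 0.002) {
  if (length(true_values) != length(recon_values)) stop("images differ in size")
  if (stats::sd(true_values) == 0 || stats::sd(recon_values) == 0)
    stop("constant image: PCC undefined")
  pcc <- stats::cor(true_values, recon_values)
  r1 <- rasterize_cells(mesh, true_values, res)
  r2 <- rasterize_cells(mesh, recon_values, res)
  ok <- is.finite(r1) & is.finite(r2)
  r1[!ok] <- 0; r2[!ok] <- 0
  list(pcc = pcc, ssim = ssim_images(r1, r2))
}

#' Mask background cells by chargeability threshold
#'
#' Cells with total chargeability below the threshold (default 1e-3) are
#' considered non-polarizable background.
#'
#' @param m_tot Per-cell total chargeability.
#' @param threshold Background threshold.
#' @return Logical vector, `TRUE` for background cells.
#' @export
mask_background <- function(m_tot, threshold = 1e-3) {
  m_tot < threshold
}
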