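#' Rhizotron geometry description
#'
#' Describes the water-filled rhizotron tank as a 2D modelling domain: a
#' rectangle of `width` x `modelled_height` metres with a uniform out-of-plane
#' `thickness`. The modelled height is the water level, 3 cm below the tank's
#' upper opening, so the default 52 cm tank is modelled as 0.52 x 0.49 m.
#' Coordinates are metres, x rightward and y upward from the bottom-left
#' corner.
#'
#' @param width Inner tank width in m.
#' @param modelled_height Height of the modelled (water-filled) domain in m.
#' @param thickness Inner tank thickness in m.
#' @param electrodes Numeric matrix (n x 2) of electrode positions in m, or
#'   `NULL` for the default 36-electrode layout of [default_electrode_layout()].
#' @param roi Axis-aligned rectangle `c(xmin, xmax, ymin, ymax)` marking the
#'   expected rooting zone used for spatially weighted scheme optimization.
#' @return An object of class `rhizotron_geometry`: a list with fields
#'   `width`, `height`, `thickness`, `electrodes` (n x 2 matrix),
#'   `central_batch` (indices of the central electrode column, see
#'   [default_electrode_layout()]) and `roi`.
#' @export
rhizotron_geometry <- function(width = 0.52, modelled_height = 0.49,
                               thickness = 0.025, electrodes = NULL,
                               roi = c(0.085, 0.435, 0.125, 0.425)) {
  stopifnot(width > 0, modelled_height > 0, thickness > 0)
  if (is.null(electrodes)) {
    layout <- default_electrode_layout(width, modelled_height)
    electrodes <- layout$positions
    central_batch <- layout$central_batch
  } else {
    electrodes <- as.matrix(electrodes)
    central_batch <- attr(electrodes, "central_batch") %||% integer(0)
  }
  if (anyDuplicated(round(electrodes, 9)))
    stop("duplicate electrode positions")
  inside <- electrodes[, 1] >= 0 & electrodes[, 1] <= width &
    electrodes[, 2] >= 0 & electrodes[, 2] <= modelled_height
  if (!all(inside)) stop("electrode positions outside the domain")
  if (!(roi[1] >= 0 && roi[2] <= width && roi[3] >= 0 &&
        roi[4] <= modelled_height && roi[1] < roi[2] && roi[3] < roi[4]))
    stop("roi not contained in the domain")
  structure(list(width = width, height = modelled_height,
                 thickness = thickness, electrodes = electrodes,
                 central_batch = central_batch, roi = roi),
            class = "rhizotron_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default 36-electrode rhizotron layout
#'
#' Reconstructs a 36-electrode arrangement for the rhizotron: rings of
#' electrodes along the left, right and bottom boundaries plus three interior
#' columns spanning the rooting zone. The middle interior column is tagged as
#' the "central batch"; the reduced-scheme experiment removes every
#' measurement configuration that touches it, creating the low-sensitivity
#' central zone the scheme comparison probes.
#'
#' Electrode coordinates are parameterized by the domain size, so non-default
#' tanks get a proportionally scaled layout.
#'
#' @param width,height Domain size in m.
#' @return A list with `positions` (36 x 2 matrix) and `central_batch`
#'   (integer indices into the rows of `positions`).
#' @export
default_electrode_layout <- function(width = 0.52, height = 0.49) {
  sx <- width / 0.52
  sy <- height / 0.49
  side_y <- seq(0.05, 0.47, length.out = 7) * sy
  bot_x <- seq(0.09, 0.43, length.out = 7) * sx
  col_x <- c(0.155, 0.26, 0.365) * sx
  col_y <- seq(0.11, 0.45, length.out = 5) * sy
  pos <- rbind(
    cbind(0.02 * sx, side_y),            # left column
    cbind(0.50 * sx, side_y),            # right column
    cbind(bot_x, 0.02 * sy),             # bottom row
    cbind(rep(col_x, each = 5), rep(col_y, times = 3))  # interior columns
  )
  dimnames(pos) <- NULL
  if (anyDuplicated(round(pos, 9))) stop("duplicate electrode positions")
  # central batch: the lower three electrodes of each interior column (a
  # compact batch in the tank centre). Excluding every configuration that
  # touches it creates a central low-sensitivity zone, so the reduced scheme
  # under-resolves the lower part of a root anomaly.
  central <- 21L + c(1:3, 6:8, 11:13)
  list(positions = pos, central_batch = central)
}

# Merge a set of axis breaks: electrode coordinates are kept verbatim (groups
# of fixed breaks within 1e-9 collapse to their first member, so coordinates
# that agree only up to floating-point noise give one grid line), other breaks
# closer than `tol` to a kept break are dropped.
merge_breaks <- function(base, fixed, tol) {
  fixed <- sort(fixed)
  grp <- cumsum(c(TRUE, diff(fixed) > 1e-9))
  fixed <- vapply(split(fixed, grp), `[`, numeric(1), 1L)
  keep <- base[vapply(base, function(b) all(abs(b - fixed) > tol), logical(1))]
  sort(unique(c(fixed, keep)))
}

#' Build a graded triangular mesh for the rhizotron
#'
#' Generates a conforming triangulation of the rectangular domain from a
#' graded tensor-product grid: a coarse background grid is merged with grid
#' lines through every electrode coordinate plus extra lines at a fraction of
#' the nearest-electrode spacing on either side, so cells are refined near the
#' electrodes. Each grid quad is split into two triangles. Every electrode
#' coincides exactly with a mesh node.
#'
#' @param geometry A [rhizotron_geometry()].
#' @param refinement_level Fraction of the nearest-electrode spacing used as
#'   the local edge length near electrodes (smaller = finer).
#' @param base_h Background grid spacing in m.
#' @param refine_electrodes If `FALSE`, only the grid lines through the
#'   electrodes are added, without the extra refinement lines around them
#'   (used for coarse design meshes in scheme optimization).
#' @return An object of class `tri_mesh`: list with `nodes` (n x 2), `cells`
#'   (m x 3 node indices, counter-clockwise), `cell_volumes` (m^3, triangle
#'   area times thickness), `cell_centroids`, `electrode_nodes` (one node
#'   index per electrode), `thickness`, the grid breaks, and `edges` (interior
#'   cell-adjacency pairs used by the smoothness operator).
#' @export
build_mesh <- function(geometry, refinement_level = 0.3, base_h = 0.04,
                       refine_electrodes = TRUE) {
  stopifnot(inherits(geometry, "rhizotron_geometry"),
            refinement_level > 0, base_h > 0)
  el <- geometry$electrodes
  n_el <- nrow(el)
  # nearest-electrode spacing per electrode
  dmat <- as.matrix(stats::dist(el))
  diag(dmat) <- Inf
  near <- apply(dmat, 1, min)
  hfine <- pmax(refinement_level * near, 1e-4)

  if (refine_electrodes) {
    fine_x <- c(el[, 1], el[, 1] + hfine, el[, 1] - hfine)
    fine_y <- c(el[, 2], el[, 2] + hfine, el[, 2] - hfine)
  } else {
    fine_x <- el[, 1]
    fine_y <- el[, 2]
  }
  clamp <- function(v, lo, hi) v[v >= lo - 1e-12 & v <= hi + 1e-12]
  fine_x <- clamp(fine_x, 0, geometry$width)
  fine_y <- clamp(fine_y, 0, geometry$height)
  tolx <- min(hfine) * 0.5
  bx <- merge_breaks(seq(0, geometry$width, length.out = ceiling(geometry$width / base_h) + 1),
                     c(0, geometry$width, fine_x), tolx)
  by <- merge_breaks(seq(0, geometry$height, length.out = ceiling(geometry$height / base_h) + 1),
                     c(0, geometry$height, fine_y), tolx)
  # ensure exact domain corners survive
  bx[1] <- 0; bx[length(bx)] <- geometry$width
  by[1] <- 0; by[length(by)] <- geometry$height

  nx <- length(bx); ny <- length(by)
  if (nx < 2 || ny < 2) stop("degenerate geometry")
  nodes <- cbind(rep(bx, times = ny), rep(by, each = nx))
  node_id <- function(i, j) (j - 1L) * nx + i  # i along x, j along y

  ii <- rep(seq_len(nx - 1), times = ny - 1)
  jj <- rep(seq_len(ny - 1), each = nx - 1)
  n00 <- node_id(ii, jj); n10 <- node_id(ii + 1L, jj)
  n01 <- node_id(ii, jj + 1L); n11 <- node_id(ii + 1L, jj + 1L)
  # split each quad along the (n00, n11) diagonal; CCW orientation
  cells <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))

  x <- nodes[, 1]; y <- nodes[, 2]
  area <- 0.5 * abs((x[cells[, 2]] - x[cells[, 1]]) * (y[cells[, 3]] - y[cells[, 1]]) -
                    (x[cells[, 3]] - x[cells[, 1]]) * (y[cells[, 2]] - y[cells[, 1]]))
  if (any(area <= 0)) stop("degenerate cell in mesh")
  centroids <- cbind((x[cells[, 1]] + x[cells[, 2]] + x[cells[, 3]]) / 3,
                     (y[cells[, 1]] + y[cells[, 2]] + y[cells[, 3]]) / 3)

  # electrode -> node map (must be exact grid intersections)
  enodes <- integer(n_el)
  for (e in seq_len(n_el)) {
    i <- which.min(abs(bx - el[e, 1])); j <- which.min(abs(by - el[e, 2]))
    if (abs(bx[i] - el[e, 1]) > 1e-9 || abs(by[j] - el[e, 2]) > 1e-9)
      stop("electrode does not coincide with a mesh node")
    enodes[e] <- node_id(i, j)
  }
  if (anyDuplicated(enodes)) stop("two electrodes map to one node")

  # cell adjacency across shared edges (for first-order smoothness)
  ek <- rbind(cbind(cells[, 1], cells[, 2]), cbind(cells[, 2], cells[, 3]),
              cbind(cells[, 3], cells[, 1]))
  ek <- t(apply(ek, 1, sort))
  key <- paste(ek[, 1], ek[, 2])
  owner <- rep(seq_len(nrow(cells)), times = 3)
  sp <- split(owner, key)
  shared <- sp[lengths(sp) == 2L]
  edges <- do.call(rbind, shared)
  dimnames(edges) <- NULL
  # geometric weight per shared edge: edge length over centroid distance, so
  # smoothing strength per physical distance is uniform across the graded mesh
  nd <- do.call(rbind, strsplit(names(shared), " "))
  n1 <- as.integer(nd[, 1]); n2 <- as.integer(nd[, 2])
  elen <- sqrt((x[n1] - x[n2])^2 + (y[n1] - y[n2])^2)
  cdist <- sqrt(rowSums((centroids[edges[, 1], ] - centroids[edges[, 2], ])^2))
  edge_weights <- elen / cdist

  structure(list(nodes = nodes, cells = cells,
                 cell_volumes = area * geometry$thickness,
                 cell_areas = area, cell_centroids = centroids,
                 electrode_nodes = enodes, thickness = geometry$thickness,
                 breaks_x = bx, breaks_y = by, nx = nx, ny = ny,
                 edges = edges, edge_weights = edge_weights,
                 geometry = geometry),
            class = "tri_mesh")
}

#' Total modelled volume of a mesh
#'
#' Sum of all cell volumes (triangle area times tank thickness), in m^3.
#'
#' @param mesh A [build_mesh()] result.
#' @return Total volume in m^3.
#' @export
total_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (length(mesh$cell_volumes) == 0) stop("mesh has no cells")
  sum(mesh$cell_volumes)
}

#' First-order smoothness operator on mesh cells
#'
#' Sparse matrix with one row per interior cell-adjacency: the difference of
#' the two neighbouring cell values, weighted by the shared edge length over
#' the centroid distance so the roughness penalty per physical distance is
#' uniform on the graded mesh. Constant fields lie in its null space.
#'
#' @param mesh A `tri_mesh`.
#' @param weighted Apply the geometric edge weights (default) or plain +1/-1
#'   differences.
#' @return A `dgCMatrix` of size n_edges x n_cells.
#' @export
smoothness_matrix <- function(mesh, weighted = TRUE) {
  e <- mesh$edges
  w <- if (weighted && !is.null(mesh$edge_weights)) mesh$edge_weights else
    rep(1, nrow(e))
  Matrix::sparseMatrix(i = rep(seq_len(nrow(e)), 2),
                       j = c(e[, 1], e[, 2]),
                       x = c(w, -w),
                       dims = c(nrow(e), length(mesh$cell_volumes)))
}

#' Locate mesh cells containing query points
#'
#' Uses the tensor-grid structure: each point is binned into its grid quad and
#' assigned to one of the quad's two triangles by the diagonal test. Points
#' outside the domain get `NA`.
#'
#' @param mesh A `tri_mesh`.
#' @param pts n x 2 matrix of coordinates in m.
#' @return Integer vector of cell indices (NA outside the domain).
#' @export
locate_cells <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 2)
  bx <- mesh$breaks_x; by <- mesh$breaks_y
  nqx <- mesh$nx - 1L
  i <- findInterval(pts[, 1], bx, rightmost.closed = TRUE)
  j <- findInterval(pts[, 2], by, rightmost.closed = TRUE)
  ok <- i >= 1 & i <= nqx & j >= 1 & j <= (mesh$ny - 1L)
  quad <- ifelse(ok, (j - 1L) * nqx + i, NA_integer_)
  # local coordinates within the quad; lower triangle if ly <= lx
  lx <- (pts[, 1] - bx[pmax(i, 1)]) / (bx[pmin(i + 1L, length(bx))] - bx[pmax(i, 1)])
  ly <- (pts[, 2] - by[pmax(j, 1)]) / (by[pmin(j + 1L, length(by))] - by[pmax(j, 1)])
  lower <- ly <= lx
  # cells were built as rbind(lower-triangles, upper-triangles)
  nquad <- nqx * (mesh$ny - 1L)
  ifelse(lower, quad, quad + nquad)
}

#' Write a mesh to a plain-text unstructured-mesh file
#'
#' Simple node/cell table format: a header line, node coordinates, then cell
#' connectivity (1-based).
#'
#' @param mesh A `tri_mesh`.
#' @param path Output file path.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tri_mesh nodes=%d cells=%d thickness=%.12g",
                     nrow(mesh$nodes), nrow(mesh$cells), mesh$thickness), con)
  utils::write.table(format(mesh$nodes, digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(mesh$cells, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
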