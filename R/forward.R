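#' Per-cell complex conductivity field at one frequency
#'
#' The inversion unknown and the phantom ground truth: one complex
#' conductivity sigma* = sigma' + i sigma'' (S/m) per mesh cell. The complex
#' resistivity is its reciprocal, rho* = 1/sigma*, with magnitude |rho*| in
#' Ohm m and phase phi_rho in rad (negative for capacitive polarization).
#'
#' @param frequency Frequency in Hz.
#' @param sigma Complex vector, one value per cell; `Re(sigma) > 0`.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(frequency, sigma) {
  sigma <- as.complex(sigma)
  if (any(Re(sigma) <= 0)) stop("sigma' must be positive everywhere")
  if (any(abs(Arg(1 / sigma)) >= pi / 2)) stop("|phase| must be < pi/2")
  structure(list(frequency = frequency, sigma = sigma),
            class = "complex_field")
}

#' @rdname complex_field
#' @param field A `complex_field`.
#' @return `field_rho(field)`: complex resistivity per cell (Ohm m).
#' @export
field_rho <- function(field) 1 / field$sigma

#' @rdname complex_field
#' @return `field_phase_mrad(field)`: resistivity phase per cell in mrad.
#' @export
field_phase_mrad <- function(field) Arg(1 / field$sigma) * 1000

# --- FEM assembly ----------------------------------------------------------

# Per-cell P1 shape-function coefficients: gradients of the three hat
# functions are (b_i, c_i) / (2 A).
cell_coeffs <- function(mesh) {
  cl <- mesh$cells
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  x1 <- x[cl[, 1]]; x2 <- x[cl[, 2]]; x3 <- x[cl[, 3]]
  y1 <- y[cl[, 1]]; y2 <- y[cl[, 2]]; y3 <- y[cl[, 3]]
  list(b = cbind(y2 - y3, y3 - y1, y1 - y2),
       c = cbind(x3 - x2, x1 - x3, x2 - x1),
       A = mesh$cell_areas)
}

# Assemble the thickness-scaled conductance stiffness matrix for a per-cell
# scalar `cond` (= sigma * thickness): K_ij = sum_cells cond * (b_i b_j +
# c_i c_j) / (4 A). Returns a real dgCMatrix; complex fields assemble the real
# and imaginary parts separately.
assemble_stiffness <- function(mesh, cond) {
  cc <- cell_coeffs(mesh)
  cl <- mesh$cells
  n <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- cl[, a]
    jj[[k]] <- cl[, b]
    xx[[k]] <- cond * (cc$b[, a] * cc$b[, b] + cc$c[, a] * cc$c[, b]) / (4 * cc$A)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# Solve the (possibly complex) FEM system for a dense RHS matrix B. The pure
# Neumann system is singular up to a constant; one node (`pin`) is removed and
# solutions are returned with zero mean. Complex systems are solved as a 2x2
# real block system since no complex sparse factorization is available.
fem_solve <- function(mesh, sigma, B, pin = NULL) {
  if (any(Re(sigma) <= 0)) stop("singular system: sigma' <= 0")
  n <- nrow(mesh$nodes)
  if (is.null(pin)) pin <- mesh$electrode_nodes[1]
  keep <- setdiff(seq_len(n), pin)
  B <- as.matrix(B)
  iscomplex <- is.complex(sigma) && any(Im(sigma) != 0)
  t <- mesh$thickness
  if (!iscomplex) {
    K <- assemble_stiffness(mesh, Re(sigma) * t)[keep, keep]
    u <- as.matrix(Matrix::solve(K, B[keep, , drop = FALSE]))
    U <- matrix(0, n, ncol(B))
    U[keep, ] <- u
  } else {
    KR <- assemble_stiffness(mesh, Re(sigma) * t)[keep, keep]
    KI <- assemble_stiffness(mesh, Im(sigma) * t)[keep, keep]
    Kb <- rbind(cbind(KR, -KI), cbind(KI, KR))
    Bb <- rbind(B[keep, , drop = FALSE],
                matrix(0, length(keep), ncol(B)))
    ub <- as.matrix(Matrix::solve(Kb, Bb))
    m <- length(keep)
    U <- matrix(0i, n, ncol(B))
    U[keep, ] <- ub[seq_len(m), , drop = FALSE] +
      1i * ub[m + seq_len(m), , drop = FALSE]
  }
  # zero-mean gauge
  sweep(U, 2, colMeans(U))
}

# Pole solutions: potential for unit current injected at each electrode and
# extracted at the reference electrode (electrode 1). Any dipole solution is a
# difference of two poles. Returns nodes x n_electrodes matrix.
solve_poles <- function(mesh, sigma) {
  en <- mesh$electrode_nodes
  n <- nrow(mesh$nodes)
  B <- matrix(0, n, length(en))
  for (e in seq_along(en)) {
    B[en[e], e] <- B[en[e], e] + 1
    B[en[1], e] <- B[en[1], e] - 1
  }
  fem_solve(mesh, sigma, B)
}

#' Forward solution for one current dipole
#'
#' Solves the 2D thin-tank complex conduction equation
#' `-div(sigma* t grad u) = I (delta_A - delta_B)` with insulating boundaries
#' and unit current, returning nodal complex potentials in the zero-mean
#' gauge.
#'
#' @param mesh A `tri_mesh`.
#' @param field A [complex_field()] on the mesh cells.
#' @param dipole Length-2 integer vector `c(A, B)` of electrode indices.
#' @return List with `u` (nodal complex potentials, V per A) and a helper-use
#'   `potential_difference(M, N)` closure giving `u[M] - u[N]` at electrodes.
#' @export
solve_dipole <- function(mesh, field, dipole) {
  stopifnot(length(dipole) == 2, dipole[1] != dipole[2])
  en <- mesh$electrode_nodes
  if (any(dipole < 1 | dipole > length(en))) stop("unknown electrode index")
  n <- nrow(mesh$nodes)
  B <- matrix(0, n, 1)
  B[en[dipole[1]], 1] <- 1
  B[en[dipole[2]], 1] <- -1
  u <- drop(fem_solve(mesh, field$sigma, B))
  list(u = u,
       potential_difference = function(M, N) u[en[M]] - u[en[N]])
}

#' Validate and normalize a measurement scheme
#'
#' A scheme is a data frame with integer columns A, B (current electrodes) and
#' M, N (potential electrodes), 1-based. Within each quadrupole all four
#' electrodes are distinct.
#'
#' @param scheme Data frame or 4-column matrix of quadrupoles.
#' @param n_electrodes Number of electrodes available (for bounds checking).
#' @return The scheme as a validated data frame.
#' @export
as_scheme <- function(scheme, n_electrodes = NULL) {
  scheme <- as.data.frame(scheme)
  names(scheme)[1:4] <- c("A", "B", "M", "N")
  bad <- scheme$A == scheme$B | scheme$M == scheme$N |
    scheme$A == scheme$M | scheme$A == scheme$N |
    scheme$B == scheme$M | scheme$B == scheme$N
  if (any(bad)) stop("quadrupole with repeated electrode")
  if (!is.null(n_electrodes) &&
      any(unlist(scheme[, 1:4]) > n_electrodes | unlist(scheme[, 1:4]) < 1))
    stop("quadrupole references unknown electrode")
  if (anyDuplicated(scheme[, 1:4])) stop("duplicate quadrupoles in scheme")
  scheme[, 1:4]
}

#' Simulate complex impedances for a measurement scheme
#'
#' Runs the forward solver for every injection dipole and frequency and
#' assembles the quadrupole impedances Z* = U*/I* (unit current).
#'
#' @param mesh A `tri_mesh`.
#' @param fields A single [complex_field()] or list of them, one per
#'   frequency.
#' @param scheme Quadrupole data frame (see [as_scheme()]).
#' @return A `complex_dataset`: list with `scheme`, `frequencies`, `Z`
#'   (complex matrix, quadrupoles x frequencies) and `K` (geometric factors,
#'   filled in by [geometric_factors()], initially `NULL`).
#' @export
simulate_scheme <- function(mesh, fields, scheme) {
  if (inherits(fields, "complex_field")) fields <- list(fields)
  scheme <- as_scheme(scheme, length(mesh$electrode_nodes))
  freqs <- vapply(fields, `[[`, numeric(1), "frequency")
  if (is.unsorted(freqs, strictly = TRUE)) stop("frequencies must be strictly increasing")
  en <- mesh$electrode_nodes
  Z <- matrix(0i, nrow(scheme), length(fields))
  for (f in seq_along(fields)) {
    U <- solve_poles(mesh, fields[[f]]$sigma)
    # Z_q = (uA - uB)(M) - (uA - uB)(N), poles indexed by electrode
    Z[, f] <- (U[cbind(en[scheme$M], scheme$A)] - U[cbind(en[scheme$M], scheme$B)] -
               U[cbind(en[scheme$N], scheme$A)] + U[cbind(en[scheme$N], scheme$B)])
  }
  structure(list(scheme = scheme, frequencies = freqs, Z = Z, K = NULL),
            class = "complex_dataset")
}

#' @rdname simulate_scheme
#' @param dataset A `complex_dataset`.
#' @return `dataset_phase_mrad(dataset)`: impedance phases in mrad
#'   (quadrupoles x frequencies).
#' @export
dataset_phase_mrad <- function(dataset) Arg(dataset$Z) * 1000

#' Numerical geometric factors
#'
#' K per quadrupole such that K * Z* is the apparent complex resistivity
#' (Eq. rho_a* = K Z*), computed from a homogeneous reference solve so that
#' the apparent resistivity of the homogeneous model equals
#' `reference_resistivity` exactly. K is independent of the chosen reference
#' resistivity (scale invariance of the Laplace problem).
#'
#' @param mesh A `tri_mesh`.
#' @param scheme Quadrupole data frame.
#' @param reference_resistivity Homogeneous resistivity in Ohm m.
#' @return Numeric vector of geometric factors (m). Near-null configurations
#'   (|Z_hom| below 1e-12 of the median) are flagged via the `near_null`
#'   attribute.
#' @export
geometric_factors <- function(mesh, scheme, reference_resistivity = 100) {
  scheme <- as_scheme(scheme, length(mesh$electrode_nodes))
  fld <- complex_field(0, rep(1 / reference_resistivity + 0i, nrow(mesh$cells)))
  ds <- simulate_scheme(mesh, list(fld), scheme)
  zh <- Re(ds$Z[, 1])
  floor_z <- 1e-12 * stats::median(abs(zh))
  K <- reference_resistivity / zh
  attr(K, "near_null") <- which(abs(zh) < floor_z)
  K
}

#' Adjoint sensitivity (Jacobian) matrix
#'
#' Log-log sensitivities d ln(rho_a) / d ln(rho_cell) of every quadrupole's
#' apparent resistivity with respect to every cell resistivity, computed with
#' the adjoint method: one forward solve per electrode, then per-cell gradient
#' dot products. For a real homogeneous field each row sums to one
#' (apparent resistivity is degree-1 homogeneous in the resistivity field).
#'
#' @param mesh A `tri_mesh`.
#' @param rho Real per-cell resistivity vector (Ohm m).
#' @param scheme Quadrupole data frame.
#' @param poles Optional precomputed pole-solution matrix from an earlier call
#'   (nodes x electrodes), to reuse factorizations.
#' @return Dense matrix, rows = quadrupoles, columns = cells.
#' @export
sensitivity_matrix <- function(mesh, rho, scheme, poles = NULL) {
  stopifnot(is.numeric(rho), all(rho > 0))
  scheme <- as_scheme(scheme, length(mesh$electrode_nodes))
  sigma <- 1 / rho
  if (is.null(poles)) poles <- solve_poles(mesh, sigma)
  cc <- cell_coeffs(mesh)
  cl <- mesh$cells
  # per-pole constant cell gradients: (n_cells x n_electrodes)
  GX <- (cc$b[, 1] * poles[cl[, 1], ] + cc$b[, 2] * poles[cl[, 2], ] +
         cc$b[, 3] * poles[cl[, 3], ]) / (2 * cc$A)
  GY <- (cc$c[, 1] * poles[cl[, 1], ] + cc$c[, 2] * poles[cl[, 2], ] +
         cc$c[, 3] * poles[cl[, 3], ]) / (2 * cc$A)
  en <- mesh$electrode_nodes
  Zq <- (poles[cbind(en[scheme$M], scheme$A)] - poles[cbind(en[scheme$M], scheme$B)] -
         poles[cbind(en[scheme$N], scheme$A)] + poles[cbind(en[scheme$N], scheme$B)])
  # J[q, c] = sigma_c * t * A_c * (grad u_AB . grad u_MN)_c / Z_q
  dABx <- t(GX[, scheme$A, drop = FALSE] - GX[, scheme$B, drop = FALSE])
  dABy <- t(GY[, scheme$A, drop = FALSE] - GY[, scheme$B, drop = FALSE])
  dMNx <- t(GX[, scheme$M, drop = FALSE] - GX[, scheme$N, drop = FALSE])
  dMNy <- t(GY[, scheme$M, drop = FALSE] - GY[, scheme$N, drop = FALSE])
  dots <- dABx * dMNx + dABy * dMNy
  w <- sigma * mesh$thickness * cc$A
  J <- dots * matrix(w, nrow(scheme), length(w), byrow = TRUE) / Zq
  dimnames(J) <- NULL
  J
}
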