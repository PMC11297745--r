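#' Enumerate candidate quadrupoles
#'
#' Builds the deterministic, lexicographically ordered (A, B, M, N) candidate
#' pool for scheme optimization. Dipoles are stored with A < B and M < N;
#' exact reciprocals (current and potential dipole swapped) are kept only in
#' their lexicographically smaller orientation. Optional pool rules restrict
#' the injection and potential dipoles by electrode separation, which keeps
#' the pool tractable for greedy optimization on the 36-electrode layout.
#'
#' @param electrodes n x 2 matrix of electrode positions (m), n >= 4.
#' @param rules List of pool rules: `min_ab_sep` (minimum current-dipole
#'   length, m), `max_mn_sep` (maximum potential-dipole length, m),
#'   `ab_dipoles` (explicit 2-column matrix of allowed injection pairs;
#'   overrides `min_ab_sep`), `max_pool` (cap on the pool size, enforced by a
#'   deterministic lexicographic stride so the greedy search stays tractable).
#' @return Data frame with columns A, B, M, N.
#' @export
enumerate_candidates <- function(electrodes, rules = list()) {
  electrodes <- as.matrix(electrodes)
  n <- nrow(electrodes)
  if (n < 4) stop("need at least 4 electrodes")
  pairs <- t(utils::combn(n, 2))
  seps <- sqrt((electrodes[pairs[, 1], 1] - electrodes[pairs[, 2], 1])^2 +
               (electrodes[pairs[, 1], 2] - electrodes[pairs[, 2], 2])^2)
  if (!is.null(rules$ab_dipoles)) {
    ab <- as.matrix(rules$ab_dipoles)
    ab <- cbind(pmin(ab[, 1], ab[, 2]), pmax(ab[, 1], ab[, 2]))
  } else if (!is.null(rules$min_ab_sep)) {
    ab <- pairs[seps >= rules$min_ab_sep, , drop = FALSE]
  } else ab <- pairs
  if (!is.null(rules$n_ab_dipoles) && nrow(ab) > rules$n_ab_dipoles)
    ab <- ab[round(seq(1, nrow(ab), length.out = rules$n_ab_dipoles)), ,
             drop = FALSE]
  if (!is.null(rules$max_mn_sep)) {
    mn <- pairs[seps <= rules$max_mn_sep, , drop = FALSE]
  } else mn <- pairs
  # cross product, disjointness, lexicographic order
  ia <- rep(seq_len(nrow(ab)), each = nrow(mn))
  im <- rep(seq_len(nrow(mn)), times = nrow(ab))
  cand <- data.frame(A = ab[ia, 1], B = ab[ia, 2],
                     M = mn[im, 1], N = mn[im, 2])
  keep <- cand$A != cand$M & cand$A != cand$N &
    cand$B != cand$M & cand$B != cand$N
  cand <- cand[keep, ]
  # drop reciprocal duplicates: keep the orientation whose (AB, MN) key is
  # lexicographically smaller
  key <- function(a, b, m, n2) ((a * (n + 1) + b) * (n + 1) + m) * (n + 1) + n2
  k1 <- key(cand$A, cand$B, cand$M, cand$N)
  k2 <- key(cand$M, cand$N, cand$A, cand$B)
  recip_present <- k2 %in% k1
  cand <- cand[!(recip_present & k2 < k1), ]
  cand <- cand[order(cand$A, cand$B, cand$M, cand$N), ]
  if (!is.null(rules$max_pool) && nrow(cand) > rules$max_pool)
    cand <- cand[round(seq(1, nrow(cand), length.out = rules$max_pool)), ]
  rownames(cand) <- NULL
  if (anyDuplicated(cand)) stop("internal: duplicate candidates")
  cand
}

#' Diagonal of the model resolution matrix
#'
#' For a linearized inverse problem with Jacobian `J`, diagonal data weights
#' `wd` and smoothness operator `Wm`, computes the diagonal of
#' `R = (J' Wd' Wd J + lambda Wm' Wm)^-1 J' Wd' Wd J`. Entries near 1 mean a
#' cell is well constrained by the data; near 0, determined only by the
#' regularization. A tiny ridge (1e-8 relative) removes the constant null
#' space of the smoothness operator.
#'
#' @param J Jacobian matrix (data x cells).
#' @param wd Data weight vector (1/error), length nrow(J), or a single value.
#' @param Wm Smoothness matrix (rows = model-space differences).
#' @param lambda Regularization strength (> 0).
#' @return Numeric vector of resolution-diagonal entries.
#' @export
resolution_diagonal <- function(J, wd, Wm, lambda) {
  if (lambda <= 0) stop("lambda must be positive")
  J <- as.matrix(J)
  wd <- rep_len(wd, nrow(J))
  Jw <- J * wd
  M <- crossprod(Jw)
  R <- as.matrix(Matrix::crossprod(Wm))
  ridge <- 1e-8 * mean(diag(R))
  G <- M + lambda * (R + ridge * diag(ncol(J)))
  diag(solve(G, M))
}

#' Greedy optimization of a measurement scheme
#'
#' Builds a measurement scheme that maximizes the ROI-weighted sum of the
#' model-resolution-matrix diagonal, evaluated for a homogeneous model on the
#' supplied (design) mesh. Starting from a sparse skeleton, candidates are
#' ranked each iteration by their exact marginal increase of the weighted
#' objective (rank-one Sherman-Morrison update) and the best `batch` are
#' added, until `target_size` configurations are selected. At most
#' `dipole_budget` distinct injection dipoles are used: once the budget is
#' exhausted, candidates introducing new dipoles become ineligible. Ties
#' break lexicographically via the candidate ordering. Only the real
#' (conduction) sensitivities enter the optimization.
#'
#' @param mesh Design mesh (`tri_mesh`); a coarse mesh keeps this fast.
#' @param candidates Candidate pool from [enumerate_candidates()].
#' @param target_size Number of configurations in the final scheme.
#' @param dipole_budget Maximum number of distinct injection dipoles.
#' @param roi_weights Per-cell spatial weights (>= 0), e.g. 1 inside the
#'   rooting zone and 0 outside; `NULL` = weight the geometry ROI 1 / 0.05.
#' @param lambda Regularization strength for the resolution computation;
#'   `NULL` = trace heuristic from the starting scheme.
#' @param batch Candidates added per greedy iteration.
#' @param n_start Size of the sparse starting skeleton.
#' @param rho_ref Homogeneous linearization resistivity (Ohm m).
#' @param l1_cap Maximum L1 norm of a candidate's log-log sensitivity row.
#'   Rows sum to 1, so the L1 norm measures sensitivity cancellation: it is
#'   the factor by which relative errors and intrinsic phases are amplified
#'   in the apparent resistivity. Configurations above the cap are
#'   measurable but uninterpretable (noise-amplifying) and are excluded.
#' @return The selected scheme (data frame A, B, M, N) with attributes
#'   `objective` (trajectory of the weighted resolution sum), `lambda`,
#'   `resolution` (final per-cell diagonal) and `injection_dipoles`.
#' @export
optimize_scheme <- function(mesh, candidates, target_size = 800,
                            dipole_budget = 40, roi_weights = NULL,
                            lambda = NULL, batch = 10, n_start = 20,
                            rho_ref = 95.15, l1_cap = 6) {
  nc <- nrow(candidates)
  if (target_size < 1 || nc < target_size)
    stop("candidate pool smaller than target size")
  m <- nrow(mesh$cells)
  if (is.null(roi_weights)) {
    roi <- mesh$geometry$roi
    cen <- mesh$cell_centroids
    inside <- cen[, 1] >= roi[1] & cen[, 1] <= roi[2] &
      cen[, 2] >= roi[3] & cen[, 2] <= roi[4]
    roi_weights <- ifelse(inside, 1, 0.05)
  }
  stopifnot(length(roi_weights) == m, all(roi_weights >= 0))

  rho <- rep(rho_ref, m)
  poles <- solve_poles(mesh, 1 / rho)
  # drop near-null configurations (|Z| too small to measure; their log-scale
  # sensitivity rows blow up and they carry no usable signal)
  en <- mesh$electrode_nodes
  Zq <- (poles[cbind(en[candidates$M], candidates$A)] -
         poles[cbind(en[candidates$M], candidates$B)] -
         poles[cbind(en[candidates$N], candidates$A)] +
         poles[cbind(en[candidates$N], candidates$B)])
  ok <- abs(Zq) >= 1e-4 * stats::median(abs(Zq))
  candidates <- candidates[ok, ]
  rownames(candidates) <- NULL
  Jc <- sensitivity_matrix(mesh, rho, candidates, poles = poles)
  # cap sensitivity cancellation (error/phase amplification in rho_a)
  ok <- rowSums(abs(Jc)) <= l1_cap
  candidates <- candidates[ok, ]
  rownames(candidates) <- NULL
  Jc <- Jc[ok, , drop = FALSE]
  nc <- nrow(candidates)
  if (nc < target_size) stop("candidate pool smaller than target size")

  Wm <- smoothness_matrix(mesh)
  Rm <- as.matrix(Matrix::crossprod(Wm))
  Rm <- Rm + 1e-8 * mean(diag(Rm)) * diag(m)

  # sparse starting skeleton: one configuration per injection dipole, dipoles
  # chosen by a deterministic stride through the pool's distinct dipoles
  dip_id <- candidates$A * 1000L + candidates$B
  dips <- unique(dip_id)
  n_start <- min(n_start, dipole_budget, length(dips))
  take <- dips[round(seq(1, length(dips), length.out = n_start))]
  sel <- match(take, dip_id)   # first candidate of each chosen dipole
  sel <- unique(sel)

  dipole_of <- dip_id
  used_dipoles <- unique(dipole_of[sel])

  if (is.null(lambda)) {
    # same trace heuristic the inversion uses for its starting lambda,
    # extrapolated from the skeleton to the final scheme size
    Js <- Jc[sel, , drop = FALSE]
    lambda <- (target_size / length(sel)) * sum(Js * Js) / sum(diag(Rm))
  }
  lamR <- lambda * Rm

  selected <- logical(nc)
  selected[sel] <- TRUE
  M <- crossprod(Jc[sel, , drop = FALSE])
  objective <- numeric(0)

  repeat {
    G <- M + lamR
    Gi <- solve(G)
    obj <- sum(roi_weights * rowSums(Gi * t(M)))   # tr(Wroi Gi M)
    objective <- c(objective, obj)
    n_sel <- sum(selected)
    if (n_sel >= target_size) break

    eligible <- !selected
    if (length(used_dipoles) >= dipole_budget)
      eligible <- eligible & (dipole_of %in% used_dipoles)
    if (!any(eligible)) stop("injection-dipole budget infeasible for target size")
    idx <- which(eligible)

    Gall <- Jc[idx, , drop = FALSE] %*% Gi        # rows g' = j' Gi
    GW <- sweep(Gall, 2, roi_weights, `*`)
    t1 <- rowSums(Jc[idx, , drop = FALSE] * GW)   # j' Wroi g
    jg <- rowSums(Jc[idx, , drop = FALSE] * Gall) # j' g
    gMWg <- rowSums((Gall %*% M) * GW)            # g' M Wroi g
    beta <- 1 / (1 + jg)
    gain <- t1 - beta * gMWg - beta * t1 * jg

    k <- min(batch, target_size - n_sel)
    add <- idx[order(gain, decreasing = TRUE)[seq_len(k)]]
    # respect the dipole budget within the batch
    for (a in add) {
      d <- dipole_of[a]
      if (!(d %in% used_dipoles)) {
        if (length(used_dipoles) >= dipole_budget) next
        used_dipoles <- c(used_dipoles, d)
      }
      selected[a] <- TRUE
      M <- M + tcrossprod(Jc[a, ])
    }
  }

  out <- candidates[selected, ]
  rownames(out) <- NULL
  G <- M + lamR
  attr(out, "objective") <- objective
  attr(out, "lambda") <- lambda
  attr(out, "resolution") <- diag(solve(G, M))
  attr(out, "injection_dipoles") <- length(used_dipoles)
  out
}

#' Remove configurations touching excluded electrodes
#'
#' Filters a scheme so that no surviving quadrupole uses any electrode in
#' `excluded`; ordering is preserved. Used to build the reduced scheme of the
#' synthetic comparison experiment by excluding the central electrode batch.
#'
#' @param scheme Quadrupole data frame.
#' @param excluded Integer vector of electrode indices to remove.
#' @return The reduced scheme; if empty, it carries attribute `empty = TRUE`
#'   and a warning is raised.
#' @export
exclude_electrodes <- function(scheme, excluded) {
  if (length(excluded) == 0) return(scheme)
  scheme <- as_scheme(scheme)
  keep <- !(scheme$A %in% excluded | scheme$B %in% excluded |
            scheme$M %in% excluded | scheme$N %in% excluded)
  out <- scheme[keep, ]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("exclusion removed every configuration")
    attr(out, "empty") <- TRUE
  }
  out
}
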