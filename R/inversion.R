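#' Error-weighted RMS misfit
#'
#' Root of the mean squared error-normalized residuals: magnitude residuals
#' are normalized by `a |Z_obs| + b`, phase residuals by `c`, and both pooled
#' into one mean. Convergence of the inversion is declared when this is close
#' to 1 (the data are explained to within their assumed errors).
#'
#' @param observed,predicted `complex_dataset`s (or complex vectors) with
#'   matching entries.
#' @param error_model An [error_model()].
#' @param component `"both"` pools magnitude and phase residuals;
#'   `"magnitude"` / `"phase"` return the per-stream RMS used as the stage
#'   convergence criterion.
#' @return Scalar RMS.
#' @export
rms_error <- function(observed, predicted, error_model,
                      component = c("both", "magnitude", "phase")) {
  component <- match.arg(component)
  zo <- if (inherits(observed, "complex_dataset")) observed$Z else observed
  zp <- if (inherits(predicted, "complex_dataset")) predicted$Z else predicted
  if (length(zo) != length(zp)) stop("mismatched lengths")
  sd_mag <- error_model$a * abs(zo) + error_model$b
  if (any(sd_mag <= 0) || error_model$c <= 0) stop("zero error estimates")
  rmag <- (abs(zo) - abs(zp)) / sd_mag
  rph <- Arg(zo / zp) * 1000 / error_model$c   # phase difference mod 2 pi
  r <- switch(component, both = c(rmag, rph), magnitude = rmag, phase = rph)
  sqrt(mean(r^2))
}

# Solve (J' Wd^2 J + lambda (Wm'Wm + ridge I)) x = rhs for tall model vectors
# via the Woodbury identity: the smoothness part is sparse (Cholesky once per
# lambda), the data part has rank <= n_data.
gn_solve <- function(J, wd, RmChol_env, Rm, lambda, rhs) {
  key <- as.character(lambda)
  if (is.null(RmChol_env$cache[[key]])) {
    RmChol_env$cache[[key]] <- Matrix::Cholesky(lambda * Rm, LDL = FALSE)
    if (length(RmChol_env$cache) > 4) # keep memory bounded
      RmChol_env$cache <- RmChol_env$cache[key]
  }
  ch <- RmChol_env$cache[[key]]
  U <- t(J * wd)                                   # m x nd
  rhs <- as.matrix(rhs)
  RiU <- as.matrix(Matrix::solve(ch, U))
  Rir <- as.matrix(Matrix::solve(ch, rhs))
  S <- diag(ncol(U)) + crossprod(U, RiU)
  Rir - RiU %*% solve(S, crossprod(U, Rir))
}

# Forward response of a real log-resistivity model: log apparent resistivity
# |K Z| (geometric factors carry the sign of negative transfer impedances).
forward_lnrhoa <- function(mesh, scheme, lnrho, K) {
  fld <- complex_field(0, 1 / exp(lnrho) + 0i)
  ds <- simulate_scheme(mesh, list(fld), scheme)
  log(abs(K * Re(ds$Z[, 1])))
}

#' Single-frequency complex-resistivity inversion
#'
#' Two-stage regularized Gauss-Newton inversion of one frequency's data.
#' Stage 1 inverts log impedance magnitudes for log resistivity with
#' first-order smoothness; the regularization strength is cooled (halved)
#' until the error-weighted magnitude RMS reaches 1, following the
#' discrepancy principle. Stage 2 solves the linearized phase problem about
#' the converged magnitude model under the same smoothness operator, cooling
#' its own lambda until the phase RMS reaches 1. Magnitude positivity is
#' guaranteed by the log parameterization; no positivity constraint applies
#' to phase.
#'
#' @param dataset `complex_dataset` restricted to one frequency (or with
#'   `freq_index` choosing the column).
#' @param mesh Inversion mesh.
#' @param error_model [error_model()] whose parameters weight the misfit.
#' @param freq_index Column of `dataset$Z` to invert.
#' @param max_iter Maximum Gauss-Newton iterations (magnitude stage).
#' @param lambda0 Starting regularization strength; `NULL` = trace heuristic.
#' @param rms_target Stop cooling once the stage RMS is at or below this.
#' @param verbose Print per-iteration diagnostics.
#' @return An `inversion_result`: list with `field` (the recovered
#'   [complex_field()]), `rms` (pooled), `rms_mag`, `rms_phase`,
#'   `iterations`, `lambda_mag`, `lambda_phase`, `converged`, and `log`
#'   (per-iteration data frame).
#' @export
invert_frequency <- function(dataset, mesh, error_model, freq_index = 1,
                             max_iter = 30, lambda0 = NULL, rms_target = 1,
                             verbose = FALSE) {
  scheme <- dataset$scheme
  Z <- dataset$Z[, freq_index]
  frequency <- dataset$frequencies[freq_index]
  K <- dataset$K %||% geometric_factors(mesh, scheme)
  m <- nrow(mesh$cells)

  # --- magnitude stage ------------------------------------------------------
  d <- log(abs(K) * abs(Z))
  sd_ln <- error_model$a + error_model$b / abs(Z)   # sd of ln|Z| = ln(rho_a)
  wd <- 1 / sd_ln
  Wm <- smoothness_matrix(mesh)
  Rm <- Matrix::crossprod(Wm)
  Rm <- Rm + 1e-8 * mean(Matrix::diag(Rm)) * Matrix::Diagonal(m)
  chol_env <- new.env(); chol_env$cache <- list()

  rho_a <- abs(K) * abs(Z)
  lnrho <- rep(log(stats::median(rho_a)), m)
  f <- forward_lnrhoa(mesh, scheme, lnrho, K)
  rms_mag <- sqrt(mean((wd * (d - f))^2))
  lambda <- NULL
  it <- 0
  log_df <- data.frame(iter = 0, lambda = NA, rms_mag = rms_mag, step = NA)
  poles <- NULL

  fails <- 0
  while (rms_mag > rms_target && it < max_iter) {
    it <- it + 1
    rho <- exp(lnrho)
    poles <- solve_poles(mesh, 1 / rho)
    J <- sensitivity_matrix(mesh, rho, scheme, poles = poles)
    if (is.null(lambda)) {
      lambda <- if (!is.null(lambda0)) lambda0 else
        sum((J * wd)^2) / sum(Matrix::diag(Rm))
    }
    rhs <- crossprod(J * wd, wd * (d - f)) - lambda * as.matrix(Rm %*% lnrho)
    dm <- drop(gn_solve(J, wd, chol_env, Rm, lambda, rhs))
    # halving line search on the error-weighted magnitude misfit; forward
    # failures (extreme trial models) count as rejections
    step <- 1; improved <- FALSE
    while (step > 1 / 64) {
      lnrho_try <- lnrho + step * dm
      f_try <- tryCatch(forward_lnrhoa(mesh, scheme, lnrho_try, K),
                        error = function(e) NULL)
      if (!is.null(f_try)) {
        rms_try <- sqrt(mean((wd * (d - f_try))^2))
        if (rms_try < rms_mag) { improved <- TRUE; break }
      }
      step <- step / 2
    }
    if (improved) {
      # if the accepted step dives below the discrepancy window, shorten it
      # by bisection so the final misfit lands near the target (data should
      # be fit to, not beyond, their errors)
      if (rms_try < 0.9 * rms_target) {
        lo <- 0; hi <- step
        for (bi in 1:8) {
          mid <- (lo + hi) / 2
          f_mid <- tryCatch(forward_lnrhoa(mesh, scheme, lnrho + mid * dm, K),
                            error = function(e) NULL)
          r_mid <- if (is.null(f_mid)) Inf else sqrt(mean((wd * (d - f_mid))^2))
          if (r_mid > rms_target) lo <- mid else { hi <- mid
            lnrho_try <- lnrho + mid * dm; f_try <- f_mid; rms_try <- r_mid }
          if (rms_try >= 0.9 * rms_target && rms_try <= rms_target) break
        }
      }
      lnrho <- lnrho_try; f <- f_try; rms_mag <- rms_try
      fails <- 0
      # discrepancy principle: keep cooling while data are over-fit-able
      if (rms_mag > rms_target) lambda <- lambda / 2
    } else {
      # step rejected: back off the cooling instead of destabilizing further
      fails <- fails + 1
      lambda <- lambda * 4
      if (fails >= 4) break
    }
    log_df <- rbind(log_df, data.frame(iter = it, lambda = lambda,
                                       rms_mag = rms_mag, step = step))
    if (verbose) message(sprintf("it %d lambda %.3g rms %.3f", it, lambda, rms_mag))
  }
  diverged <- rms_mag > 1.2
  if (diverged)
    warning(sprintf("magnitude RMS %.2f did not reach 1.2", rms_mag))

  # --- phase stage (linearized about the magnitude model) -------------------
  rho <- exp(lnrho)
  if (is.null(poles)) poles <- solve_poles(mesh, 1 / rho)
  J <- sensitivity_matrix(mesh, rho, scheme, poles = poles)
  phi_d <- Arg(K * Z) * 1000                   # apparent phase, mrad
  wphi <- rep(1 / error_model$c, length(phi_d))
  # cool lambda from well above the trace heuristic and take the first
  # crossing of the discrepancy target; if the misfit plateaus above the
  # target (model error floor), keep the smoothest model on the plateau
  # rather than chasing the last fraction of a percent into noise fitting
  lam_phi <- 100 * sum((J * wphi)^2) / sum(Matrix::diag(Rm))
  lam_floor <- lam_phi * 1e-10
  chol_env$cache <- list()
  rhs <- crossprod(J * wphi, wphi * phi_d)
  phase_solve <- function(lam) {
    phi <- drop(gn_solve(J, wphi, chol_env, Rm, lam, rhs))
    list(phi = phi, lam = lam,
         rms = sqrt(mean((wphi * (phi_d - drop(J %*% phi)))^2)))
  }
  best <- NULL; prev <- NULL
  repeat {
    cur <- phase_solve(lam_phi)
    if (!is.null(best) && cur$rms > 0.97 * best$rms) break   # plateau
    prev <- best; best <- cur
    if (cur$rms <= rms_target || lam_phi <= lam_floor) break
    lam_phi <- lam_phi / 3
  }
  # if the crossing overshot below the window, bisect lambda back up to it
  if (best$rms < 0.9 * rms_target && !is.null(prev)) {
    lo <- best$lam; hi <- prev$lam
    for (bi in 1:8) {
      cur <- phase_solve(sqrt(lo * hi))
      if (cur$rms > rms_target) hi <- cur$lam else { lo <- cur$lam; best <- cur }
      if (best$rms >= 0.9 * rms_target && best$rms <= rms_target) break
    }
  }
  phi_m <- best$phi; rms_phi <- best$rms; lam_phi <- best$lam
  # keep the recovered field physical (|phase| < pi/2)
  phi_m <- pmin(pmax(phi_m, -1500), 1500)

  sigma <- 1 / (rho * exp(1i * phi_m / 1000))
  field <- complex_field(frequency, sigma)
  pred <- K_to_Z(K, rho_a_pred = exp(f), phi_pred = drop(J %*% phi_m))
  res <- list(field = field,
              rms = rms_error(Z, pred, error_model),
              rms_mag = rms_mag, rms_phase = rms_phi,
              iterations = it, lambda_mag = lambda %||% NA,
              lambda_phase = lam_phi,
              converged = !diverged, log = log_df)
  class(res) <- "inversion_result"
  res
}

# predicted complex impedances from predicted apparent resistivity and phase
K_to_Z <- function(K, rho_a_pred, phi_pred) {
  (rho_a_pred / K) * exp(1i * phi_pred / 1000)
}

#' Invert all frequencies within the analysis band
#'
#' Runs [invert_frequency()] independently for every dataset frequency inside
#' `[f_min, f_max]`; out-of-band frequencies are skipped with a log entry.
#'
#' @param dataset Multi-frequency `complex_dataset`.
#' @param mesh Inversion mesh.
#' @param error_model [error_model()] (phase error may also be a vector, one
#'   entry per frequency).
#' @param f_min,f_max Analysis band in Hz.
#' @param ... Passed to [invert_frequency()].
#' @return List of `inversion_result`s, named by frequency; attribute
#'   `skipped` lists out-of-band frequencies.
#' @export
invert_band <- function(dataset, mesh, error_model, f_min = 0.79,
                        f_max = 1000, ...) {
  fr <- dataset$frequencies
  in_band <- fr >= f_min & fr <= f_max
  if (!any(in_band)) stop("no dataset frequencies inside the band")
  cs <- rep_len(error_model$c, length(fr))
  res <- list()
  for (i in which(in_band)) {
    em <- error_model(error_model$a, error_model$b, cs[i])
    res[[as.character(fr[i])]] <-
      invert_frequency(dataset, mesh, em, freq_index = i, ...)
  }
  attr(res, "skipped") <- fr[!in_band]
  res
}

#' Average complex fields over noise realizations
#'
#' Cell-wise mean of log resistivity magnitude and of resistivity phase over
#' an ensemble of recovered fields (same mesh and frequency), mitigating
#' outliers from individual noise realizations.
#'
#' @param fields List of [complex_field()]s.
#' @return The averaged `complex_field`.
#' @export
average_inversions <- function(fields) {
  if (inherits(fields, "complex_field")) fields <- list(fields)
  n <- length(fields)
  sizes <- vapply(fields, function(f) length(f$sigma), integer(1))
  if (length(unique(sizes)) != 1) stop("fields live on different meshes")
  lnmag <- Reduce(`+`, lapply(fields, function(f) log(abs(1 / f$sigma)))) / n
  ph <- Reduce(`+`, lapply(fields, function(f) Arg(1 / f$sigma))) / n
  complex_field(fields[[1]]$frequency, 1 / (exp(lnmag) * exp(1i * ph)))
}
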