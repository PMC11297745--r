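#' Relaxation-time grid for Debye decomposition
#'
#' Log-spaced relaxation times covering the analysis band: from one decade
#' below `1/(2 pi f_max)` to one decade above `1/(2 pi f_min)`, with a fixed
#' number of points per decade.
#'
#' @param f_min,f_max Analysis band in Hz (defaults 0.79 Hz - 1 kHz).
#' @param per_decade Grid density (points per decade of tau).
#' @return Strictly increasing vector of relaxation times in seconds.
#' @export
relaxation_grid <- function(f_min = 0.79, f_max = 1000, per_decade = 20) {
  stopifnot(f_min > 0, f_max > f_min, per_decade > 0)
  lo <- log10(frequency_to_tau(f_max) / 10)
  hi <- log10(frequency_to_tau(f_min) * 10)
  n <- max(2L, ceiling((hi - lo) * per_decade) + 1L)
  10^seq(lo, hi, length.out = n)
}

#' Debye-model complex resistivity spectrum
#'
#' Superposition of Debye relaxation terms:
#' `rho*(w) = rho0 (1 - sum_k m_k (1 - 1/(1 + i w tau_k)))`.
#'
#' @param rho0 DC resistivity (Ohm m, real).
#' @param m Chargeabilities (>= 0) on the relaxation-time grid; `sum(m)` must
#'   be < 1.
#' @param tau Relaxation times (s), same length as `m`.
#' @param frequencies Frequencies (Hz) at which to evaluate.
#' @return Complex resistivity vector.
#' @export
debye_forward <- function(rho0, m, tau, frequencies) {
  stopifnot(length(m) == length(tau), all(m >= 0))
  if (sum(m) >= 1) stop("total chargeability must be < 1")
  if (length(m) == 0) return(rep(rho0 + 0i, length(frequencies)))
  w <- 2 * pi * frequencies
  iwt <- outer(w, tau)                       # n_freq x n_terms
  disp <- (1i * iwt) / (1 + 1i * iwt)        # 1 - 1/(1 + i w tau)
  rho0 * (1 - drop(disp %*% m))
}

#' Fit a Debye decomposition to a complex resistivity spectrum
#'
#' Non-negative (log-parameterized) smoothness-regularized least squares:
#' unknowns are `log(rho0)` and `log(m_k)` on the fixed tau grid; the misfit
#' is the real and imaginary residual relative to the spectrum scale, plus
#' first-order smoothing of the chargeability spectrum over log tau. Solved
#' by damped Gauss-Newton with analytic derivatives.
#'
#' @param spectrum Complex resistivity values (Ohm m).
#' @param frequencies Frequencies (Hz) of the samples.
#' @param tau Relaxation-time grid (see [relaxation_grid()]).
#' @param lambda Smoothness strength on the m(log tau) spectrum.
#' @param max_iter Gauss-Newton iteration cap.
#' @return A `debye_fit`: list with `rho0`, `m`, `tau`, `m_tot`, `tau_mean`
#'   (chargeability-weighted geometric mean relaxation time, NA when
#'   `m_tot = 0`), and `rms` (relative data residual).
#' @export
fit_debye <- function(spectrum, frequencies, tau = relaxation_grid(),
                      lambda = 0.01, max_iter = 60) {
  if (any(!is.finite(spectrum))) stop("non-finite spectrum values")
  nf <- length(frequencies); nk <- length(tau)
  w <- 2 * pi * frequencies
  disp <- (1i * outer(w, tau)) / (1 + 1i * outer(w, tau))
  scale <- mean(abs(spectrum))
  dobs <- c(Re(spectrum), Im(spectrum)) / scale

  D <- diff(diag(nk))                        # first-order smoothing of m
  x <- c(log(abs(spectrum[which.min(frequencies)])), rep(log(1e-6), nk))

  resid_jac <- function(x) {
    rho0 <- exp(x[1]); m <- exp(x[-1])
    pred <- rho0 * (1 - drop(disp %*% m))
    r <- c(Re(pred), Im(pred)) / scale - dobs
    # d pred / d ln rho0 = pred ; d pred / d ln m_k = -rho0 * disp_k * m_k
    Jc <- cbind(pred, -rho0 * sweep(disp, 2, m, `*`))
    J <- rbind(Re(Jc), Im(Jc)) / scale
    rp <- sqrt(lambda) * drop(D %*% m)
    Jp <- sqrt(lambda) * cbind(0, sweep(D, 2, m, `*`))
    list(r = c(r, rp), J = rbind(J, Jp), data_rms = sqrt(mean(r^2)))
  }

  rj <- resid_jac(x)
  cost <- sum(rj$r^2)
  nu <- 1e-6
  for (it in seq_len(max_iter)) {
    A <- crossprod(rj$J)
    g <- crossprod(rj$J, rj$r)
    step_ok <- FALSE
    for (damp in nu * 10^(0:8)) {
      dx <- tryCatch(-solve(A + damp * diag(nk + 1), g), error = function(e) NULL)
      if (is.null(dx)) next
      x_try <- x + drop(dx)
      x_try[-1] <- pmax(x_try[-1], log(1e-12))   # keep m finite
      rj_try <- resid_jac(x_try)
      if (sum(rj_try$r^2) < cost) {
        x <- x_try; rj <- rj_try
        delta <- cost - sum(rj$r^2)
        cost <- sum(rj$r^2)
        nu <- max(damp / 10, 1e-9)
        step_ok <- TRUE
        break
      }
    }
    if (!step_ok) break
    if (delta < 1e-12 * cost) break
  }

  rho0 <- exp(x[1]); m <- exp(x[-1])
  m_tot <- sum(m)
  tau_mean <- if (m_tot > 0) exp(sum(m * log(tau)) / m_tot) else NA_real_
  structure(list(rho0 = rho0, m = m, tau = tau, m_tot = m_tot,
                 tau_mean = tau_mean, rms = rj$data_rms),
            class = "debye_fit")
}

#' Per-cell Debye decomposition of inverted fields
#'
#' Extracts each cell's complex resistivity spectrum from a list of
#' per-frequency fields and fits a Debye decomposition independently per
#' cell, returning total-chargeability and mean-relaxation-time images.
#'
#' @param fields List of [complex_field()]s (same mesh, increasing
#'   frequencies).
#' @param tau Relaxation-time grid.
#' @param lambda Smoothness strength passed to [fit_debye()].
#' @return List with vectors `m_tot`, `tau_mean`, `rho0` (per cell; NA where
#'   a fit failed) and `failed` (indices of failed cells).
#' @export
decompose_field <- function(fields, tau = NULL, lambda = 0.01) {
  freqs <- vapply(fields, `[[`, numeric(1), "frequency")
  if (is.null(tau)) tau <- relaxation_grid(min(freqs), max(freqs))
  ncell <- length(fields[[1]]$sigma)
  rho <- vapply(fields, function(f) 1 / f$sigma, complex(ncell))
  rho <- matrix(rho, ncell, length(fields))
  m_tot <- tau_mean <- rho0 <- rep(NA_real_, ncell)
  failed <- integer(0)
  for (cc in seq_len(ncell)) {
    fit <- tryCatch(fit_debye(rho[cc, ], freqs, tau, lambda),
                    error = function(e) NULL)
    if (is.null(fit)) { failed <- c(failed, cc); next }
    m_tot[cc] <- fit$m_tot; tau_mean[cc] <- fit$tau_mean; rho0[cc] <- fit$rho0
  }
  list(m_tot = m_tot, tau_mean = tau_mean, rho0 = rho0, failed = failed)
}

#' Polarization length scale of a relaxation time
#'
#' Stern-layer diffusion relation `tau = r^2 / (2 D)`: a relaxation time
#' `tau` corresponds to a characteristic length `r = sqrt(2 D tau)`.
#'
#' @param tau Relaxation time in s (> 0).
#' @param D Ion diffusion coefficient in m^2/s (default 1e-9).
#' @return Length scale r in m.
#' @export
relaxation_length <- function(tau, D = 1e-9) {
  if (any(tau <= 0) || D <= 0) stop("tau and D must be positive")
  sqrt(2 * D * tau)
}

#' @rdname relaxation_length
#' @param r Length scale in m.
#' @return `length_to_tau(r, D)`: relaxation time in s.
#' @export
length_to_tau <- function(r, D = 1e-9) {
  if (any(r <= 0) || D <= 0) stop("r and D must be positive")
  r^2 / (2 * D)
}

#' @rdname relaxation_length
#' @param f Frequency in Hz.
#' @return `frequency_to_tau(f)`: the relaxation time `1/(2 pi f)`.
#' @export
frequency_to_tau <- function(f) {
  if (any(f <= 0)) stop("frequency must be positive")
  1 / (2 * pi * f)
}

#' @rdname relaxation_length
#' @return `tau_to_frequency(tau)`: the frequency `1/(2 pi tau)`.
#' @export
tau_to_frequency <- function(tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  1 / (2 * pi * tau)
}
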