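#' Measurement error model
#'
#' Linear impedance-magnitude error `d|Z| = a |Z| + b` and constant phase
#' error `d(phi) = c`. These errors drive both the synthetic noise generator
#' and the data weighting in the inversion, so simulated noise and assumed
#' errors share one model.
#'
#' @param a Relative magnitude error (dimensionless; real-data default 0.02).
#' @param b Absolute magnitude error in Ohm (default 0.01).
#' @param c Absolute phase error in mrad.
#' @return An `error_model` object.
#' @export
error_model <- function(a = 0.02, b = 0.01, c = 0.5) {
  stopifnot(a >= 0, b > 0, c > 0)
  structure(list(a = a, b = b, c = c), class = "error_model")
}

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Contaminate a dataset with Gaussian noise
#'
#' Perturbs every impedance magnitude with zero-mean Gaussian noise of
#' standard deviation `a |Z| + b` and every phase with zero-mean Gaussian
#' noise of standard deviation `c` mrad; all draws independent and
#' reproducible per seed. Magnitudes that would become non-positive are
#' redrawn (up to 100 times, then the call fails).
#'
#' @param dataset A `complex_dataset`.
#' @param a,b,c Error-model parameters (see [error_model()]).
#' @param seed Integer seed for the noise draws.
#' @return The noisy `complex_dataset`.
#' @export
contaminate <- function(dataset, a, b, c, seed) {
  Z <- dataset$Z
  mag <- abs(Z); ph <- Arg(Z) * 1000  # mrad
  with_seed(seed, {
    sd_mag <- a * mag + b
    mag2 <- mag + stats::rnorm(length(mag), 0, 1) * sd_mag
    tries <- 0
    while (any(mag2 <= 0)) {
      tries <- tries + 1
      if (tries > 100) stop("magnitude noise produced non-positive |Z|")
      bad <- mag2 <= 0
      mag2[bad] <- mag[bad] + stats::rnorm(sum(bad), 0, 1) * sd_mag[bad]
    }
    ph2 <- ph + stats::rnorm(length(ph), 0, 1) * c
    dataset$Z <- matrix(mag2 * exp(1i * ph2 / 1000), nrow(Z), ncol(Z))
  })
  dataset
}

#' Data-driven phase-error estimate
#'
#' The constant phase error at a frequency is set to half the (population)
#' standard deviation of the measured phases at that frequency, with a small
#' floor so that no datum gets infinite weight. When geometric factors are
#' available, phases are polarity-corrected (Arg(K Z)) so that
#' negative-transfer-impedance configurations do not inflate the spread.
#'
#' @param dataset A `complex_dataset`.
#' @param frequency Frequency (Hz) whose phases are used.
#' @param floor_mrad Lower bound on the returned error (mrad).
#' @return Phase error c in mrad.
#' @export
estimate_phase_error <- function(dataset, frequency, floor_mrad = 0.1) {
  fi <- which(abs(dataset$frequencies - frequency) <= 1e-9 * frequency)
  if (length(fi) != 1) stop("frequency not in dataset")
  z <- dataset$Z[, fi]
  if (!is.null(dataset$K)) z <- dataset$K * z
  ph <- Arg(z) * 1000
  if (length(ph) < 2) stop("need at least 2 measurements")
  pop_sd <- sqrt(mean((ph - mean(ph))^2))
  max(pop_sd / 2, floor_mrad)
}

#' Correct measured data with a water reference
#'
#' Interface for the measured-data corrections: accounts for the 2D inversion
#' of data collected in a 3D domain and for polarization of the measurement
#' setup, using an sEIT measurement on water only. Per quadrupole and
#' frequency the magnitude is multiplied by the ratio of the modelled
#' homogeneous magnitude to the measured water magnitude, and the measured
#' water phase is subtracted. If the dataset equals the water reference the
#' result is exactly the modelled homogeneous dataset.
#'
#' @param dataset Measured `complex_dataset`.
#' @param water_measured Measured water-only `complex_dataset` (same scheme
#'   and frequencies).
#' @param water_modelled Modelled homogeneous `complex_dataset`.
#' @return Corrected `complex_dataset`; data without a finite reference entry
#'   are dropped (with the surviving row index in attribute `kept`).
#' @export
correct_with_water_reference <- function(dataset, water_measured, water_modelled) {
  if (!identical(dim(dataset$Z), dim(water_measured$Z)) ||
      !identical(dim(dataset$Z), dim(water_modelled$Z)))
    stop("datasets must share scheme and frequencies")
  ratio <- abs(water_modelled$Z) / abs(water_measured$Z)
  ok <- apply(is.finite(ratio), 1, all)
  mag <- abs(dataset$Z) * ratio
  ph <- Arg(dataset$Z) - Arg(water_measured$Z) + Arg(water_modelled$Z)
  dataset$Z <- mag * exp(1i * ph)
  if (!all(ok)) {
    dataset$Z <- dataset$Z[ok, , drop = FALSE]
    dataset$scheme <- dataset$scheme[ok, ]
    if (!is.null(dataset$K)) dataset$K <- dataset$K[ok]
  }
  attr(dataset, "kept") <- which(ok)
  dataset
}
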