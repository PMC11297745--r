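#' Write / read a measurement scheme file
#'
#' Plain-text table of 1-based electrode indices, columns A B M N, with a
#' comment header carrying provenance (seed, config hash if given).
#'
#' @param scheme Quadrupole data frame.
#' @param path File path.
#' @param header Optional named character vector written as `# key: value`.
#' @export
write_scheme <- function(scheme, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  writeLines("A B M N", con)
  utils::write.table(as_scheme(scheme), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @return `read_scheme(path)`: the scheme data frame.
#' @export
read_scheme <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  as_scheme(df)
}

#' Write / read a complex dataset table
#'
#' Columns: A B M N frequency_Hz mag_Ohm phase_mrad K (12 significant
#' digits, lossless round trip at printed precision).
#'
#' @param dataset A `complex_dataset`.
#' @param path File path.
#' @param header Optional named character vector of `# key: value` lines.
#' @export
write_dataset <- function(dataset, path, header = NULL) {
  sch <- dataset$scheme
  rows <- expand.grid(q = seq_len(nrow(sch)), f = seq_along(dataset$frequencies))
  df <- data.frame(A = sch$A[rows$q], B = sch$B[rows$q],
                   M = sch$M[rows$q], N = sch$N[rows$q],
                   frequency_Hz = dataset$frequencies[rows$f],
                   mag_Ohm = abs(dataset$Z[cbind(rows$q, rows$f)]),
                   phase_mrad = Arg(dataset$Z[cbind(rows$q, rows$f)]) * 1000,
                   K = if (is.null(dataset$K)) NA else dataset$K[rows$q])
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  writeLines(paste(names(df), collapse = " "), con)
  utils::write.table(format(df, digits = 12, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @return `read_dataset(path)`: the `complex_dataset`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  freqs <- sort(unique(df$frequency_Hz))
  first <- df[df$frequency_Hz == freqs[1], ]
  scheme <- as_scheme(first[, c("A", "B", "M", "N")])
  Z <- matrix(0i, nrow(scheme), length(freqs))
  for (f in seq_along(freqs)) {
    sub <- df[df$frequency_Hz == freqs[f], ]
    Z[, f] <- sub$mag_Ohm * exp(1i * sub$phase_mrad / 1000)
  }
  K <- if (all(is.na(first$K))) NULL else first$K
  structure(list(scheme = scheme, frequencies = freqs, Z = Z, K = K),
            class = "complex_dataset")
}

#' Write / read a per-cell field table
#'
#' Columns: cell, rho_mag_Ohmm, phase_mrad.
#'
#' @param field A [complex_field()].
#' @param path File path.
#' @param header Optional named character vector of `# key: value` lines.
#' @export
write_field <- function(field, path, header = NULL) {
  rho <- 1 / field$sigma
  df <- data.frame(cell = seq_along(rho), rho_mag_Ohmm = abs(rho),
                   phase_mrad = Arg(rho) * 1000)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frequency_Hz: %.12g", field$frequency), con)
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  writeLines(paste(names(df), collapse = " "), con)
  utils::write.table(format(df, digits = 12, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @return `read_field(path)`: the `complex_field`.
#' @export
read_field <- function(path) {
  hdr <- readLines(path, n = 1)
  freq <- as.numeric(sub("# frequency_Hz: ", "", hdr))
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  complex_field(freq, 1 / (df$rho_mag_Ohmm * exp(1i * df$phase_mrad / 1000)))
}

#' Read a plain key-value run configuration
#'
#' Lines of `key: value`; `#` starts a comment. Values are parsed as numeric
#' vectors when possible (comma separated), otherwise kept as strings.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
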