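# Independent oracles used by the tests. These never call the package's
# forward/inversion code paths they are checking.

# Analytic potential in a homogeneous rectangle [0,a]x[0,b] with insulating
# boundaries, thickness t, conductivity sigma, unit current injected at `src`
# and extracted at `snk`: truncated cosine series with the y-dependence
# summed analytically (stable exponential form). Zero-mean gauge is
# irrelevant because only potential differences are compared.
series_potential <- function(pts, src, snk, a, b, sigma, thickness,
                             nterms = 400) {
  pts <- matrix(pts, ncol = 2)
  gk <- function(k, y, y0) {
    ylo <- pmin(y, y0); yhi <- pmax(y, y0)
    d <- yhi - ylo; s <- ylo + yhi
    (exp(-k * d) + exp(-k * s) + exp(-k * (2 * b - s)) + exp(-k * (2 * b - d))) /
      (2 * k * (1 - exp(-2 * k * b)))
  }
  g0 <- function(y, y0) (y^2 + y0^2) / (2 * b) - pmax(y, y0)
  u <- (g0(pts[, 2], src[2]) - g0(pts[, 2], snk[2])) / a
  for (m in seq_len(nterms)) {
    k <- m * pi / a
    u <- u + (2 / a) * cos(k * pts[, 1]) *
      (cos(k * src[1]) * gk(k, pts[, 2], src[2]) -
       cos(k * snk[1]) * gk(k, pts[, 2], snk[2]))
  }
  u / (sigma * thickness)
}

# Exhaustive quadrupole enumeration for small n: unordered dipoles A<B, M<N,
# disjoint, reciprocal-unique (smaller lexicographic orientation kept).
brute_force_candidates <- function(n) {
  out <- list()
  for (A in 1:(n - 1)) for (B in (A + 1):n)
    for (M in 1:(n - 1)) for (N in (M + 1):n) {
      if (length(intersect(c(A, B), c(M, N))) > 0) next
      out[[length(out) + 1]] <- c(A, B, M, N)
    }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("A", "B", "M", "N")
  key <- function(a, b, m, n2) ((a * (n + 1) + b) * (n + 1) + m) * (n + 1) + n2
  k1 <- key(df$A, df$B, df$M, df$N)
  k2 <- key(df$M, df$N, df$A, df$B)
  df <- df[!(k2 %in% k1 & k2 < k1), ]
  df <- df[order(df$A, df$B, df$M, df$N), ]
  rownames(df) <- NULL
  df
}

# Brute-force power-law fit: grid search over (log10 coef, exponent)
# minimizing the log10-space SSE, refined to ~1e-3 resolution.
grid_search_powerlaw <- function(x, y) {
  lx <- log10(x); ly <- log10(y)
  sse <- function(lc, e) sum((ly - (lc + e * lx))^2)
  lc_rng <- c(-3, 3); e_rng <- c(-2, 3)
  for (pass in 1:4) {
    lcs <- seq(lc_rng[1], lc_rng[2], length.out = 61)
    es <- seq(e_rng[1], e_rng[2], length.out = 61)
    grid <- outer(lcs, es, Vectorize(sse))
    ij <- which(grid == min(grid), arr.ind = TRUE)[1, ]
    step_lc <- diff(lc_rng) / 60; step_e <- diff(e_rng) / 60
    lc_rng <- lcs[ij[1]] + c(-2, 2) * step_lc
    e_rng <- es[ij[2]] + c(-2, 2) * step_e
  }
  list(coef = 10^lcs[ij[1]], exponent = es[ij[2]])
}

# Dense direct computation of the resolution diagonal (independent of the
# package's implementation shortcuts).
dense_resolution_diag <- function(J, wd, Wm, lambda) {
  Jw <- J * wd
  M <- t(Jw) %*% Jw
  R <- as.matrix(Matrix::crossprod(Wm))
  G <- M + lambda * (R + 1e-8 * mean(diag(R)) * diag(ncol(J)))
  diag(solve(G) %*% M)
}
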