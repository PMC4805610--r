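# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Kendall's W: explicit rank matrix, direct formula with tie
# correction. Independent of the package's implementation path.
brute_w <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X); n <- nrow(X)
  R <- apply(X, 2, rank)
  Ri <- rowSums(R)
  S <- sum((Ri - mean(Ri))^2)
  Tj <- 0
  for (j in seq_len(k)) {
    tt <- table(X[, j])
    Tj <- Tj + sum(tt^3 - tt)
  }
  denom <- k^2 * (n^3 - n) - k * Tj
  if (denom <= 0) 0 else 12 * S / denom
}

# A small bold_series with the given per-voxel generator function.
tiny_series <- function(nx = 4, ny = 4, nz = 3, nt = 30, tr = 2, seed = 1,
                        mask = NULL) {
  set.seed(seed)
  bold_series(array(rnorm(nx * ny * nz * nt), c(nx, ny, nz, nt)),
              tr_s = tr, mask = mask)
}

# Single-voxel series wrapper for filter tests.
one_voxel <- function(x, tr = 2) {
  bold_series(array(x, c(1, 1, 1, length(x))), tr_s = tr)
}

# Fraction of a signal's spectral mass (periodogram, detrended) inside
# [f_low, f_high]; oracle for band-purity checks.
spectral_fraction <- function(x, tr, f_low, f_high) {
  n <- length(x)
  x <- stats::residuals(stats::lm(x ~ seq_len(n)))
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1)
  f <- pmin(f, n - f) / (n * tr)
  sum(p[f > f_low & f <= f_high]) / sum(p[f > 0])
}
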