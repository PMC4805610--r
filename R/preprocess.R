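#' Discard leading volumes
#'
#' Drops the first `n_discard` time points of a BOLD series, the standard
#' equilibration / volume-matching step (e.g. 46 leading resting volumes or
#' 9 leading task volumes, leaving 154 in both states at TR = 2 s).
#'
#' @param series A `bold_series`.
#' @param n_discard Number of leading volumes to drop (may be 0).
#' @return The trimmed `bold_series`; metadata preserved.
#' @export
trim_volumes <- function(series, n_discard) {
  stopifnot(inherits(series, "bold_series"))
  n_discard <- as.integer(n_discard)
  t_len <- n_volumes(series)
  if (n_discard < 0) stop("'n_discard' must be non-negative")
  if (n_discard >= t_len)
    stop("cannot discard ", n_discard, " of ", t_len, " volumes")
  if (n_discard == 0) return(series)
  bold_series(series$data[, , , (n_discard + 1):t_len, drop = FALSE],
              tr_s = series$tr_s, voxel_size_mm = series$voxel_size_mm,
              mask = series$mask)
}

#' Head-motion quality control
#'
#' Applies the inclusion rule "head motion less than `threshold_mm` in any
#' one direction": a scan fails iff any translation parameter's absolute
#' excursion reaches or exceeds the threshold (strict pass below it). Also
#' returns mean framewise displacement (FD) as a scalar motion summary for
#' use as a covariate: the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations (radians) converted to mm of arc on
#' a 50 mm sphere.
#'
#' @param motion_params A t-by-6 numeric matrix or data frame: three
#'   translations in mm then three rotations in radians.
#' @param threshold_mm Exclusion threshold in mm (default 3).
#' @return List with `pass` (logical), `max_excursion_mm`, `mean_fd_mm`.
#' @export
motion_qc <- function(motion_params, threshold_mm = 3) {
  mp <- as.matrix(motion_params)
  if (ncol(mp) != 6L || !is.numeric(mp) || anyNA(mp))
    stop("'motion_params' must be a numeric t x 6 table (3 translations mm, 3 rotations rad)")
  max_exc <- max(abs(mp[, 1:3]))
  d <- abs(diff(mp))
  d[, 4:6] <- d[, 4:6] * 50   # arc length on a 50 mm radius sphere
  fd <- c(0, rowSums(d))
  list(pass = max_exc < threshold_mm,
       max_excursion_mm = max_exc,
       mean_fd_mm = mean(fd))
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per voxel, replaces the time series with its least-squares residual on
#' an intercept plus the nuisance regressors (head motion parameters,
#' global mean, white-matter and CSF signals). Residuals are exactly
#' orthogonal to every retained regressor. Collinear columns are dropped
#' with a warning.
#'
#' @param series A `bold_series`.
#' @param nuisance A t-by-q numeric matrix or data frame of regressors.
#' @return The residual `bold_series`.
#' @export
regress_nuisance <- function(series, nuisance) {
  stopifnot(inherits(series, "bold_series"))
  X <- as.matrix(nuisance)
  if (nrow(X) != n_volumes(series))
    stop("nuisance rows (", nrow(X), ") must match time points (",
         n_volumes(series), ")")
  if (any(!is.finite(X))) stop("nuisance regressors must be finite")
  X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning("dropping ", length(drop), " collinear nuisance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Y <- mask_matrix(series)                       # t x v
  res <- qr.resid(qrX, Y)
  d <- dim(series$data)
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  flat[as.vector(series$mask), ] <- t(res)
  dim(flat) <- d
  new_bold_series(flat, tr_s = series$tr_s,
                  voxel_size_mm = series$voxel_size_mm, mask = series$mask)
}

# Remove per-column best-fit line (least squares on [1, t]).
detrend_linear <- function(Y) {
  n <- nrow(Y)
  tt <- seq_len(n) - (n + 1) / 2
  Y <- sweep(Y, 2, colMeans(Y))
  slope <- crossprod(tt, Y) / sum(tt^2)
  Y - outer(tt, drop(slope))
}

# Ideal rectangular band-pass of a t x v matrix: DFT bins with
# f_low < f <= f_high are kept (f = 0 never kept). Input is assumed
# detrended by the caller.
ideal_bandpass_matrix <- function(Y, tr_s, f_low, f_high) {
  n <- nrow(Y)
  f <- seq_len(n) - 1L
  f <- pmin(f, n - f) / (n * tr_s)              # two-sided bin frequencies
  keep <- f > f_low & f <= f_high
  Z <- stats::mvfft(Y)
  Z[!keep, ] <- 0
  Re(stats::mvfft(Z, inverse = TRUE)) / n
}

#' Ideal band-pass filter
#'
#' Per in-mask voxel: remove the best-fit line (linear detrend), take the
#' discrete Fourier transform, zero every bin outside the band, and invert.
#' The rectangular ("ideal") filter matches the convention of the
#' REST/DPABI toolbox family. Bin membership follows the [band_spec()]
#' convention `f_low < f <= f_high`, so the named slow bands are disjoint
#' and tile `(0, Nyquist]`: per-voxel variances of the band outputs sum to
#' the variance of the detrended series.
#'
#' The rectangular filter itself is an orthogonal projection, hence exactly
#' idempotent; the preceding detrend is a separate projection, so
#' re-filtering an already-filtered series with `detrend = FALSE` returns
#' it unchanged to machine precision. (Re-detrending a band-limited series
#' perturbs it slightly, because spectral leakage gives such a series a
#' small nonzero best-fit line.)
#'
#' @param series A `bold_series`.
#' @param band A `band_spec`, canonical band name, or list with
#'   `f_low`/`f_high`.
#' @param detrend Remove the best-fit line before filtering (default TRUE).
#' @return The filtered `bold_series` (band recorded in attribute `band`).
#' @export
bandpass <- function(series, band, detrend = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  band <- as_band(band)
  nyq <- 1 / (2 * series$tr_s)
  if (band$f_high > nyq + 1e-12)
    stop(sprintf("band '%s' exceeds the Nyquist frequency %.4g Hz",
                 band$name, nyq))
  Y <- mask_matrix(series)
  if (detrend) Y <- detrend_linear(Y)
  Yf <- ideal_bandpass_matrix(Y, series$tr_s, band$f_low, band$f_high)
  d <- dim(series$data)
  flat <- matrix(0, prod(d[1:3]), d[4])
  flat[as.vector(series$mask), ] <- t(Yf)
  dim(flat) <- d
  out <- new_bold_series(flat, tr_s = series$tr_s,
                         voxel_size_mm = series$voxel_size_mm,
                         mask = series$mask)
  attr(out, "band") <- band
  out
}

#' Standard temporal preprocessing chain
#'
#' trim -> nuisance regression -> detrend + ideal band-pass, in that order.
#'
#' @param series A `bold_series`.
#' @param n_discard Leading volumes to drop.
#' @param nuisance Optional t-by-q regressor table (rows matching the
#'   trimmed length).
#' @param band Optional band to filter into; `NULL` skips filtering.
#' @return The preprocessed `bold_series`.
#' @export
preprocess_series <- function(series, n_discard = 0, nuisance = NULL,
                              band = NULL) {
  out <- trim_volumes(series, n_discard)
  if (!is.null(nuisance)) out <- regress_nuisance(out, nuisance)
  if (!is.null(band)) out <- bandpass(out, band)
  out
}
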