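#' In-mask neighbors of a voxel
#'
#' Returns the grid coordinates of the in-mask neighbors of a voxel under a
#' 6- (faces), 18- (faces + edges) or 26- (full cube) connectivity scheme,
#' excluding the voxel itself. At mask borders the available subset is
#' returned, so the neighborhood size varies across the mask.
#'
#' @param voxel Integer length-3 grid coordinate (1-based).
#' @param mask Logical 3D array.
#' @param connectivity One of 6, 18, 26 (default 26, the classical ReHo
#'   neighborhood).
#' @return Integer matrix with one row per neighbor (columns x, y, z).
#' @export
neighborhood <- function(voxel, mask, connectivity = 26) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  voxel <- as.integer(voxel)
  if (length(voxel) != 3) stop("'voxel' must be a length-3 grid coordinate")
  if (any(voxel < 1) || any(voxel > dim(mask)))
    stop("voxel outside the grid")
  if (!mask[voxel[1], voxel[2], voxel[3]]) stop("voxel outside the mask")
  flat <- cpp_neighbors(voxel[1] - 1L, voxel[2] - 1L, voxel[3] - 1L,
                        as.logical(mask), as.integer(dim(mask)),
                        as.integer(connectivity))
  arrayInd(flat + 1L, dim(mask))
}

#' Kendall's coefficient of concordance
#'
#' Concordance of k time series of common length n: each series is ranked
#' over time (average ranks for ties), rank sums \eqn{R_t} are formed per
#' time point, and
#' \deqn{W = \frac{12 \sum_t (R_t - k(n+1)/2)^2}{k^2(n^3 - n) - k \sum_j T_j}}
#' where \eqn{T_j = \sum (t^3 - t)} over tie groups of size t within series
#' j. W is 1 for identical rank orderings, about 1/k under independence,
#' and 0 when the denominator vanishes (all series constant), with a
#' warning.
#'
#' @param series_set Numeric matrix, one column per series (n rows of time
#'   points), or a list of equal-length numeric vectors.
#' @return W in [0, 1].
#' @export
kendalls_w <- function(series_set) {
  if (is.list(series_set)) series_set <- do.call(cbind, series_set)
  X <- as.matrix(series_set)
  k <- ncol(X); n <- nrow(X)
  if (k < 2 || n < 2) stop("need at least 2 series of at least 2 time points")
  R <- apply(X, 2, rank)
  Tj <- apply(X, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })
  rs <- rowSums(R)
  S <- sum((rs - k * (n + 1) / 2)^2)
  denom <- k^2 * (n^3 - n) - k * sum(Tj)
  if (denom <= 0) {
    warning("degenerate input (all series constant); returning W = 0")
    return(0)
  }
  12 * S / denom
}

#' Voxel-wise regional homogeneity map
#'
#' For each in-mask voxel, computes Kendall's W between the voxel's time
#' series and those of its in-mask neighbors (k = 1 + number of neighbors;
#' 26 neighbors in the interior under the default scheme). ReHo is computed
#' on unsmoothed, band-filtered data; smoothing comes after
#' standardization.
#'
#' @param series A preprocessed `bold_series`.
#' @param connectivity Neighborhood scheme: 6, 18 or 26 (default).
#' @return A `reho_map` object: list with `values` (3D raw W grid, zeros
#'   outside mask), `k` (neighborhood-size grid), `mask`, `voxel_size_mm`,
#'   `standardized = FALSE`, and the filtering band if recorded.
#' @export
reho_map <- function(series, connectivity = 26) {
  stopifnot(inherits(series, "bold_series"))
  if (!any(series$mask)) stop("empty mask")
  connectivity <- as.integer(match.arg(as.character(connectivity),
                                       c("6", "18", "26")))
  res <- cpp_reho_map(as.numeric(series$data), as.logical(series$mask),
                      as.integer(dim(series$data)), connectivity)
  structure(
    list(values = res$W, k = res$k, mask = series$mask,
         voxel_size_mm = series$voxel_size_mm, standardized = FALSE,
         band = attr(series, "band")),
    class = "reho_map"
  )
}

#' @export
print.reho_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<reho_map %s, %d voxels, mean %.4f, range [%.4f, %.4f]%s>\n",
              if (x$standardized) "z" else "raw W", sum(x$mask),
              mean(v), min(v), max(v),
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Subject-wise z-standardization of a ReHo map
#'
#' Subtracts the within-mask ("whole brain") mean and divides by the
#' within-mask sample standard deviation, improving normality and
#' cross-subject comparability. Out-of-mask voxels stay zero.
#'
#' @param map A raw `reho_map`.
#' @return The standardized `reho_map` (`standardized = TRUE`).
#' @export
standardize_map <- function(map) {
  stopifnot(inherits(map, "reho_map"))
  v <- map$values[map$mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("constant map: cannot standardize")
  map$values <- unmask((v - mean(v)) / s, map$mask)
  map$standardized <- TRUE
  map
}

# Discrete Gaussian kernel, unit sum, truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 3D Gaussian convolution with zero padding, via banded matrices.
smooth_array_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    ker <- gaussian_kernel_1d(sigma_vox[ax])
    if (length(ker) == 1) next
    n <- d[ax]
    r <- (length(ker) - 1) / 2
    B <- matrix(0, n, n)
    for (j in seq_along(ker)) {
      off <- j - r - 1
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      B[cbind(idx[ok], src[ok])] <- B[cbind(idx[ok], src[ok])] + ker[j]
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- B %*% matrix(a, da[1])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Gaussian smoothing of a ReHo map
#'
#' 3D Gaussian convolution with per-axis sigma (in voxels) of
#' `fwhm / (voxel_size * 2 sqrt(2 ln 2))`; e.g. a 4 mm FWHM kernel at 3 mm
#' voxels gives sigma of about 0.566 voxels. Out-of-mask voxels are treated
#' as zero and the mask is re-applied afterwards. `fwhm_mm = 0` is the
#' identity.
#'
#' @param map A (standardized) `reho_map`.
#' @param fwhm_mm Full width at half maximum in mm (default 4).
#' @return The smoothed `reho_map`.
#' @export
smooth_map <- function(map, fwhm_mm = 4) {
  stopifnot(inherits(map, "reho_map"))
  if (fwhm_mm < 0) stop("'fwhm_mm' must be non-negative")
  if (fwhm_mm == 0) return(map)
  sigma <- fwhm_mm / (map$voxel_size_mm * 2 * sqrt(2 * log(2)))
  sm <- smooth_array_3d(map$values, sigma)
  map$values <- sm * map$mask
  map
}

#' One-line summary of a ReHo map
#'
#' @param map A `reho_map`.
#' @return Data frame with within-mask mean, SD, min, max and voxel count.
#' @export
summarize_map <- function(map) {
  v <- map$values[map$mask]
  data.frame(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
             n_voxels = length(v))
}
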