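#' Construct a masked 4D BOLD time series
#'
#' The unit every temporal operation transforms: a 4D array (x, y, z, t)
#' with repetition time, voxel size and a 3D logical brain mask.
#'
#' @param data Numeric 4D array (x, y, z, t).
#' @param tr_s Repetition time in seconds.
#' @param voxel_size_mm Numeric length-3 voxel edge lengths in mm (a scalar
#'   is recycled).
#' @param mask Logical 3D array matching the spatial dimensions of `data`.
#'   Defaults to all-true.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, tr_s, voxel_size_mm = 3, mask = NULL) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("a BOLD series needs at least 2 time points")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("'tr_s' must be positive")
  spatial <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, spatial)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(as.integer(dim(mask)), as.integer(spatial)))
    stop("mask shape must equal the spatial shape of 'data'")
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  vals <- matrix(data, prod(spatial))[as.vector(mask), ]
  if (any(!is.finite(vals))) stop("non-finite values inside the mask")
  structure(
    list(data = data, tr_s = as.numeric(tr_s),
         voxel_size_mm = as.numeric(voxel_size_mm), mask = mask),
    class = "bold_series"
  )
}

# Internal constructor without finiteness/shape validation, for hot paths
# whose inputs are already validated (filters, residuals, simulators).
new_bold_series <- function(data, tr_s, voxel_size_mm, mask) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  structure(list(data = data, tr_s = tr_s,
                 voxel_size_mm = voxel_size_mm, mask = mask),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series %dx%dx%d x %d vols, TR %.3g s, %d in-mask voxels>\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

n_volumes <- function(series) dim(series$data)[4]

#' Extract in-mask voxel time series as a matrix
#'
#' @param series A `bold_series`.
#' @return A t-by-v matrix, one column per in-mask voxel in array order.
#' @export
mask_matrix <- function(series) {
  spatial <- dim(series$data)[1:3]
  m <- matrix(series$data, prod(spatial), dim(series$data)[4])
  t(m[as.vector(series$mask), , drop = FALSE])
}

# Inverse of mask_matrix for 3D summaries: place a per-voxel vector back on
# the grid (zeros outside the mask).
unmask <- function(values, mask) {
  out <- array(0, dim(mask))
  out[mask] <- values
  out
}

#' Read / write BOLD volumes as NIfTI
#'
#' Round-trips the 4D data plus grid metadata (voxel size via pixdim, TR via
#' the 4th pixdim slot) through `.nii`/`.nii.gz`.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param mask Logical 3D array to attach on read; defaults to all finite,
#'   nonzero-variance voxels.
#' @return `read_bold()` returns a `bold_series`; `write_bold()` returns
#'   `path` invisibly.
#' @export
read_bold <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  bold_series(arr, tr_s = tr, voxel_size_mm = pd[1:3], mask = mask)
}

#' @param series A `bold_series`.
#' @rdname read_bold
#' @export
write_bold <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 3D map as NIfTI
#'
#' @param values Numeric 3D array.
#' @param voxel_size_mm Length-3 voxel size for the header.
#' @param path File path.
#' @return `read_map()` returns a numeric 3D array with a `voxel_size_mm`
#'   attribute; `write_map()` returns `path` invisibly.
#' @export
write_map <- function(values, path, voxel_size_mm = 3) {
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(out))))]
  out
}
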