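#' Named BOLD frequency bands
#'
#' The canonical partition of the 0--0.25 Hz BOLD fluctuation range into the
#' slow-2 ... slow-6 bands: slow-6 (0--0.01 Hz), slow-5 (0.01--0.027 Hz),
#' slow-4 (0.027--0.073 Hz), slow-3 (0.073--0.198 Hz) and slow-2
#' (0.198--0.25 Hz). 0.25 Hz is the Nyquist frequency at TR = 2 s.
#'
#' @format A named list of `band_spec` objects.
#' @export
slow_bands <- list(
  "slow-6" = list(name = "slow-6", f_low = 0.000, f_high = 0.010),
  "slow-5" = list(name = "slow-5", f_low = 0.010, f_high = 0.027),
  "slow-4" = list(name = "slow-4", f_low = 0.027, f_high = 0.073),
  "slow-3" = list(name = "slow-3", f_low = 0.073, f_high = 0.198),
  "slow-2" = list(name = "slow-2", f_low = 0.198, f_high = 0.250)
)

#' Construct a frequency band specification
#'
#' A `band_spec` is a named frequency interval controlling the ideal
#' band-pass filter. Bands may be given by canonical name (`"slow-5"`, ...)
#' or by explicit edges in Hz.
#'
#' A discrete-Fourier bin at frequency `f` belongs to the band iff
#' `f_low < f <= f_high` (with `f_low = 0` additionally excluding the DC
#' bin, which linear detrending removes anyway). Under this convention
#' adjacent named bands are disjoint and together tile `(0, 0.25]` Hz, so
#' band-limited variances add up to the total variance of the detrended
#' series; the shared printed edge (e.g. 0.01 Hz) is assigned to the lower
#' band.
#'
#' @param name Either a canonical band name (one of `names(slow_bands)`) or
#'   an arbitrary label when `f_low`/`f_high` are given.
#' @param f_low,f_high Band edges in Hz; ignored when `name` is canonical.
#' @return A `band_spec` object (list with `name`, `f_low`, `f_high`).
#' @examples
#' band_spec("slow-5")
#' band_spec("custom", 0.01, 0.08)
#' @export
band_spec <- function(name, f_low = NULL, f_high = NULL) {
  if (name %in% names(slow_bands) && is.null(f_low) && is.null(f_high)) {
    b <- slow_bands[[name]]
  } else {
    if (is.null(f_low) || is.null(f_high))
      stop("non-canonical band '", name, "' needs explicit f_low and f_high")
    b <- list(name = name, f_low = as.numeric(f_low), f_high = as.numeric(f_high))
  }
  if (!(b$f_low >= 0 && b$f_low < b$f_high))
    stop("band edges must satisfy 0 <= f_low < f_high")
  class(b) <- "band_spec"
  b
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: %.4g-%.4g Hz>\n", x$name, x$f_low, x$f_high))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1) return(band_spec(band))
  if (is.list(band)) return(band_spec(band$name, band$f_low, band$f_high))
  stop("cannot interpret 'band' as a band_spec")
}

#' Default analysis bands
#'
#' The four bands analyzed by default: slow-5, slow-4, slow-3 and slow-2.
#' slow-6 (0--0.01 Hz) mainly reflects very-low-frequency drift and is
#' excluded by default, but remains available through [band_spec()].
#'
#' @return Named list of `band_spec` objects.
#' @export
default_bands <- function() {
  lapply(slow_bands[c("slow-5", "slow-4", "slow-3", "slow-2")], as_band)
}
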