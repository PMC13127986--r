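#' Frequency band definition
#'
#' A band is a named half-axis interval `[f_lo, f_hi]` in Hz. The three
#' canonical bands used throughout the package are theta (4-10 Hz), low
#' gamma (30-55 Hz) and high gamma (55-100 Hz).
#'
#' @param name Band label, e.g. `"theta"`.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `nc_band`.
#' @examples
#' band("theta", 4, 10)
#' @export
band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_hi <= f_lo) {
    stop("invalid band: need 0 < f_lo < f_hi, got [", f_lo, ", ", f_hi, "]")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "nc_band")
}

#' @rdname band
#' @export
band_theta <- function() band("theta", 4, 10)

#' @rdname band
#' @export
band_low_gamma <- function() band("low_gamma", 30, 55)

#' @rdname band
#' @export
band_high_gamma <- function() band("high_gamma", 55, 100)

#' @export
print.nc_band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

# validate a band against a sampling rate (edges must sit below Nyquist)
check_band_fs <- function(band, fs) {
  stopifnot(inherits(band, "nc_band"))
  if (band$f_hi >= fs / 2) {
    stop("band '", band$name, "' upper edge ", band$f_hi,
         " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  invisible(band)
}
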