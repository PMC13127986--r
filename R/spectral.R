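#' Welch power spectral density estimate
#'
#' The signal is divided into Hann-windowed segments with the given
#' overlap; the squared-magnitude Fourier spectrum of each segment is
#' averaged. The one-sided density is normalised by the window power
#' (`fs * sum(w^2)`) so that the integral of the density over frequency
#' equals the variance of a stationary input (Parseval); a unit-amplitude
#' sine therefore integrates to 0.5.
#'
#' @param rec An [lfp_recording()].
#' @param seg_len Segment length in seconds (default 2 s, i.e. 0.5 Hz
#'   resolution).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return An object of class `psd_estimate`: list with `freqs` (Hz, from
#'   0 to Nyquist), `density` (matrix, one column per channel, uV^2/Hz),
#'   `seg_len`, `overlap`, `window = "hann"`, `n_segments`, `fs`.
#' @export
welch_psd <- function(rec, seg_len = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "lfp_recording"))
  stopifnot(seg_len > 0, overlap >= 0, overlap < 1)
  nseg <- round(seg_len * rec$fs)
  n <- n_samples(rec)
  if (n < nseg) {
    stop("epoch (", n / rec$fs, " s) is shorter than one segment (",
         seg_len, " s)")
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / nseg))   # periodic Hann
  scale <- 1 / (rec$fs * sum(w^2))
  nfreq <- nseg %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1) * rec$fs / nseg
  density <- matrix(0, nrow = nfreq, ncol = ncol(rec$samples),
                    dimnames = list(NULL, rec$channel_ids))
  for (ch in seq_len(ncol(rec$samples))) {
    acc <- numeric(nfreq)
    for (s in starts) {
      seg <- rec$samples[s:(s + nseg - 1L), ch] * w
      sp <- Mod(fft(seg)[seq_len(nfreq)])^2 * scale
      # one-sided: double everything except DC (and Nyquist if present)
      sp[-1] <- sp[-1] * 2
      if (nseg %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
      acc <- acc + sp
    }
    density[, ch] <- acc / length(starts)
  }
  structure(list(freqs = freqs, density = density, seg_len = seg_len,
                 overlap = overlap, window = "hann",
                 n_segments = length(starts), fs = rec$fs),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d freq bins (0-%g Hz, df = %g), %d segment(s) of %g s, %s window\n",
    length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1],
    x$n_segments, x$seg_len, x$window))
  invisible(x)
}

#' Mean band power from a PSD estimate
#'
#' The band value is the mean of the density over all frequency bins with
#' `f_lo <= f <= f_hi` (both edges inclusive), in uV^2/Hz.
#'
#' @param psd A [welch_psd()] estimate.
#' @param band A [band()] lying inside the PSD frequency range.
#' @param window Optional window label carried through to the output.
#' @return A tibble of class `band_power` with one row per channel:
#'   columns `channel`, `band`, `window`, `value`.
#' @export
band_power <- function(psd, band, window = NA_character_) {
  stopifnot(inherits(psd, "psd_estimate"), inherits(band, "nc_band"))
  sel <- psd$freqs >= band$f_lo & psd$freqs <= band$f_hi
  if (!any(sel)) {
    stop("band ", band$name, " [", band$f_lo, ", ", band$f_hi,
         "] Hz contains no PSD bins")
  }
  out <- tibble::tibble(
    channel = colnames(psd$density),
    band = band$name,
    window = window,
    value = colMeans(matrix(psd$density[sel, ], nrow = sum(sel))))
  class(out) <- c("band_power", class(out))
  out
}

#' Percent change of band power relative to an animal's own baseline
#'
#' The default convention is the signed percent difference
#' `100 * (post - baseline) / baseline` (0 = no change); the ratio
#' convention `100 * post / baseline` (100 = no change) is available via
#' `convention = "ratio"`.
#'
#' @param post,baseline [band_power()] tibbles for the same band and the
#'   same channels.
#' @param convention `"difference"` (default) or `"ratio"`.
#' @return A tibble with columns `channel`, `band`, `baseline`, `post`,
#'   `percent`.
#' @export
percent_change <- function(post, baseline,
                           convention = c("difference", "ratio")) {
  convention <- match.arg(convention)
  stopifnot(inherits(post, "band_power"), inherits(baseline, "band_power"))
  if (!identical(sort(post$channel), sort(baseline$channel)) ||
      !identical(unique(post$band), unique(baseline$band))) {
    stop("post and baseline must cover the same channels and band")
  }
  b <- baseline$value[match(post$channel, baseline$channel)]
  if (any(b <= 0)) stop("baseline band power must be positive")
  pct <- if (convention == "difference") 100 * (post$value - b) / b
         else 100 * post$value / b
  tibble::tibble(channel = post$channel, band = post$band,
                 baseline = b, post = post$value, percent = pct)
}

#' Time-frequency spectrogram
#'
#' Short-time spectra on a sliding Hamming window, restricted to a
#' frequency range of interest; column times are window centres. Density
#' normalisation matches [welch_psd()].
#'
#' @param rec An [lfp_recording()].
#' @param win Window length in seconds (default 1).
#' @param overlap Overlap fraction (default 0.75).
#' @param f_range Frequency range `c(lo, hi)` in Hz to retain
#'   (default 30-100).
#' @param channel Channel index or id (default first channel).
#' @return An object of class `lfp_spectrogram`: list with `times`
#'   (centres, s), `freqs` (Hz), `power` (matrix freq x time, uV^2/Hz).
#' @export
spectrogram_lfp <- function(rec, win = 1, overlap = 0.75,
                            f_range = c(30, 100), channel = 1) {
  stopifnot(inherits(rec, "lfp_recording"))
  nwin <- round(win * rec$fs)
  n <- n_samples(rec)
  if (n < nwin) {
    stop("epoch (", n / rec$fs, " s) is shorter than one window (", win, " s)")
  }
  if (is.character(channel)) channel <- match(channel, rec$channel_ids)
  x <- rec$samples[, channel]
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  k <- seq_len(nwin) - 1
  w <- 0.54 - 0.46 * cos(2 * pi * k / nwin)                  # periodic Hamming
  scale <- 1 / (rec$fs * sum(w^2))
  nfreq <- nwin %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1) * rec$fs / nwin
  keep <- freqs >= f_range[1] & freqs <= f_range[2]
  power <- vapply(starts, function(s) {
    sp <- Mod(fft(x[s:(s + nwin - 1L)] * w)[seq_len(nfreq)])^2 * scale
    sp[-1] <- sp[-1] * 2
    if (nwin %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
    sp[keep]
  }, numeric(sum(keep)))
  structure(list(times = rec$t0 + (starts - 1 + nwin / 2) / rec$fs,
                 freqs = freqs[keep],
                 power = matrix(power, nrow = sum(keep))),
            class = "lfp_spectrogram")
}

#' @export
print.lfp_spectrogram <- function(x, ...) {
  cat(sprintf("<lfp_spectrogram> %d freq bins (%g-%g Hz) x %d time columns\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times)))
  invisible(x)
}
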