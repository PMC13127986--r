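# analytic (Hilbert) signal via the frequency-domain construction:
# zero the negative frequencies, double the positive ones
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' The argument of the analytic (Hilbert) signal. Input must already be
#' band-limited; edge samples are distorted by the transform and should be
#' trimmed downstream.
#'
#' @param band_signal Numeric vector, band-pass filtered.
#' @return Phase series in radians, in `(-pi, pi]`.
#' @export
analytic_phase <- function(band_signal) {
  if (sd(band_signal) == 0) {
    stop("instantaneous phase is undefined for a constant signal")
  }
  Arg(analytic_signal(band_signal))
}

#' Instantaneous amplitude envelope of a band-limited signal
#'
#' The modulus of the analytic (Hilbert) signal.
#'
#' @param band_signal Numeric vector, band-pass filtered.
#' @return Envelope series (same units as the input).
#' @export
amplitude_envelope <- function(band_signal) {
  Mod(analytic_signal(band_signal))
}

#' Theta-gamma phase-amplitude coupling via the phase-locking value
#'
#' Pipeline per channel: band-pass the signal in the phase band and take
#' its Hilbert phase; band-pass in the amplitude band, take the amplitude
#' envelope, band-pass the envelope in the phase band (removing its large
#' DC component, without which the envelope phase is ill-defined) and take
#' the envelope's Hilbert phase. The coupling strength (PLV) is the
#' modulus of the mean unit phasor of the phase differences — the mean
#' vector length — and the preferred phase is its argument. An edge margin
#' is trimmed from each end before averaging to suppress filter and
#' Hilbert transients.
#'
#' @param rec An [lfp_recording()] (an extracted analysis epoch).
#' @param phase_band Low-frequency [band()] providing the phase
#'   (default theta, 4-10 Hz).
#' @param amp_band High-frequency [band()] providing the amplitude.
#' @param order Butterworth order of the band isolation filters
#'   (default 4).
#' @param margin_s Edge margin in seconds trimmed from each end
#'   (default 1).
#' @return A tibble of class `pac_result`, one row per channel: `channel`,
#'   `plv` in `[0, 1]`, `mean_phase` in `(-pi, pi]`, `n_samples`
#'   (effective samples after trimming). Attributes `phase_band` and
#'   `amp_band` carry the band definitions.
#' @export
plv_pac <- function(rec, phase_band = band_theta(), amp_band,
                    order = 4, margin_s = 1) {
  stopifnot(inherits(rec, "lfp_recording"))
  check_band_fs(phase_band, rec$fs)
  check_band_fs(amp_band, rec$fs)
  n <- n_samples(rec)
  trim <- round(margin_s * rec$fs)
  n_eff <- n - 2L * trim
  # require >= 10 slow-band cycles after trimming
  if (n_eff / rec$fs * phase_band$f_lo < 10) {
    stop("epoch too short: need at least 10 ", phase_band$name,
         " cycles after trimming ", margin_s, " s margins")
  }
  sos_phase <- butter_bandpass_sos(order, phase_band$f_lo, phase_band$f_hi,
                                   rec$fs)
  sos_amp <- butter_bandpass_sos(order, amp_band$f_lo, amp_band$f_hi,
                                 rec$fs)
  keep <- (trim + 1L):(n - trim)
  rows <- lapply(seq_len(ncol(rec$samples)), function(ch) {
    x <- rec$samples[, ch]
    ph_slow <- analytic_phase(sos_filtfilt(sos_phase, x))
    env <- amplitude_envelope(sos_filtfilt(sos_amp, x))
    ph_env <- analytic_phase(sos_filtfilt(sos_phase, env))
    z <- mean(exp(1i * (ph_slow[keep] - ph_env[keep])))
    tibble::tibble(channel = rec$channel_ids[ch], plv = Mod(z),
                   mean_phase = Arg(z), n_samples = length(keep))
  })
  out <- do.call(rbind, rows)
  attr(out, "phase_band") <- phase_band
  attr(out, "amp_band") <- amp_band
  class(out) <- c("pac_result", class(out))
  out
}

#' Surrogate (shuffle) null for the phase-locking value
#'
#' Optional diagnostic: randomly permutes the amplitude envelope in time,
#' destroying its temporal structure (and hence any phase-amplitude
#' relation) while preserving its value distribution, and recomputes the
#' PLV for each surrogate. Gives the chance floor against which an
#' observed PLV can be judged for a single recording.
#'
#' @inheritParams plv_pac
#' @param n_surrogates Number of surrogates (default 200).
#' @param channel Channel index or id (default first).
#' @param seed RNG seed for the shift draws.
#' @return Numeric vector of surrogate PLV values.
#' @export
plv_shuffle_null <- function(rec, phase_band = band_theta(), amp_band,
                             order = 4, margin_s = 1, n_surrogates = 200,
                             channel = 1, seed = 1) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.character(channel)) channel <- match(channel, rec$channel_ids)
  n <- n_samples(rec)
  trim <- round(margin_s * rec$fs)
  keep <- (trim + 1L):(n - trim)
  sos_phase <- butter_bandpass_sos(order, phase_band$f_lo, phase_band$f_hi,
                                   rec$fs)
  sos_amp <- butter_bandpass_sos(order, amp_band$f_lo, amp_band$f_hi,
                                 rec$fs)
  x <- rec$samples[, channel]
  ph_slow <- analytic_phase(sos_filtfilt(sos_phase, x))
  env <- amplitude_envelope(sos_filtfilt(sos_amp, x))
  set.seed(seed)
  vapply(seq_len(n_surrogates), function(i) {
    env_s <- env[sample.int(n)]
    ph_env <- analytic_phase(sos_filtfilt(sos_phase, env_s))
    Mod(mean(exp(1i * (ph_slow[keep] - ph_env[keep]))))
  }, numeric(1))
}
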