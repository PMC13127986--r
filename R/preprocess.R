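#' Session timeline: injection events and labeled analysis windows
#'
#' Recordings are anchored to a timeline of injection events and half-open
#' analysis windows `[start, end)` in seconds from recording start. The
#' timeline is data, not code: the home-cage, open-field and anesthesia
#' schedules are expressed as window tables.
#'
#' @param windows Data frame with columns `label`, `start`, `end` (seconds).
#' @param events Optional data frame with columns `label`, `time` (seconds),
#'   e.g. injections.
#' @param baseline_label Label of the baseline window (must appear in
#'   `windows`).
#' @return An object of class `session_timeline`.
#' @examples
#' tl <- session_timeline(
#'   windows = data.frame(label = c("baseline", "post"),
#'                        start = c(1200, 3600), end = c(1800, 4200)),
#'   events = data.frame(label = "injection", time = 1800),
#'   baseline_label = "baseline")
#' @export
session_timeline <- function(windows, events = NULL,
                             baseline_label = "baseline") {
  windows <- as.data.frame(windows)
  stopifnot(all(c("label", "start", "end") %in% names(windows)))
  if (any(windows$start >= windows$end)) {
    stop("every window needs start < end")
  }
  if (anyDuplicated(windows$label)) stop("window labels must be unique")
  if (!baseline_label %in% windows$label) {
    stop("baseline_label '", baseline_label, "' not among windows")
  }
  if (!is.null(events)) {
    events <- as.data.frame(events)
    stopifnot(all(c("label", "time") %in% names(events)))
  }
  structure(list(windows = windows, events = events,
                 baseline_label = baseline_label),
            class = "session_timeline")
}

#' @export
print.session_timeline <- function(x, ...) {
  cat("<session_timeline>\n")
  if (!is.null(x$events)) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  event %-12s @ %g s\n", x$events$label[i], x$events$time[i]))
  }
  for (i in seq_len(nrow(x$windows)))
    cat(sprintf("  window %-12s [%g, %g) s%s\n", x$windows$label[i],
                x$windows$start[i], x$windows$end[i],
                if (x$windows$label[i] == x$baseline_label) "  (baseline)" else ""))
  invisible(x)
}

#' Remove power-line noise with a zero-phase biquad notch cascade
#'
#' Applies second-order notch sections at the line frequency and its
#' harmonics, forward and backward so that the net phase shift is zero.
#' The default keeps harmonics up to 250 Hz, which covers the analysis
#' bands while each notch is narrow enough (Q = 30, about 1.7 Hz at 50 Hz)
#' to leave the 30-55 and 55-100 Hz gamma bands essentially untouched.
#'
#' @param rec An [lfp_recording()].
#' @param base_freq Line frequency in Hz (default 50).
#' @param n_harmonics Number of harmonics to notch (including the
#'   fundamental). Default: as many as fit below min(250 Hz, Nyquist).
#' @param q Notch quality factor (bandwidth is roughly `f0/q`).
#' @return The filtered [lfp_recording()], same length, with the notch
#'   parameters appended to `meta$notch`.
#' @export
remove_line_noise <- function(rec, base_freq = 50, n_harmonics = NULL,
                              q = 30) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.null(n_harmonics)) {
    n_harmonics <- max(1L, floor(min(250, rec$fs / 2 - 1e-9) / base_freq))
  }
  if (base_freq * n_harmonics >= rec$fs / 2) {
    stop("harmonic ", base_freq * n_harmonics,
         " Hz is at or above Nyquist (", rec$fs / 2, " Hz)")
  }
  sos <- do.call(rbind, lapply(seq_len(n_harmonics), function(k) {
    biquad_notch(base_freq * k, rec$fs, q)
  }))
  map_channels(rec, function(x) sos_filtfilt(sos, x),
               meta_add = list(notch = list(base_freq = base_freq,
                                            n_harmonics = n_harmonics, q = q)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band isolation for spectral and coupling analysis. The filter is a
#' Butterworth band-pass of the stated order, designed in zero-pole-gain
#' form and applied as a cascade of second-order sections forward and
#' backward (zero net phase shift); phase estimates downstream are
#' therefore not biased by filter delay. A 1 s edge margin should be
#' trimmed before phase/amplitude estimation (see [plv_pac()]).
#'
#' @param rec An [lfp_recording()].
#' @param band An [band()] with both edges inside `(0, fs/2)`.
#' @param order Butterworth order (default 4; the effective attenuation is
#'   doubled by the forward-backward pass).
#' @return Filtered [lfp_recording()] with `meta$bandpass` recording the
#'   design and the recommended edge-transient margin (`margin_s = 1`).
#' @export
bandpass <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "lfp_recording"))
  check_band_fs(band, rec$fs)
  sos <- butter_bandpass_sos(order, band$f_lo, band$f_hi, rec$fs)
  map_channels(rec, function(x) sos_filtfilt(sos, x),
               meta_add = list(bandpass = list(band = band$name,
                                               f_lo = band$f_lo,
                                               f_hi = band$f_hi,
                                               order = order,
                                               margin_s = 1)))
}

#' Extract a labeled analysis window from a recording
#'
#' Returns the samples falling in the half-open interval `[start, end)` of
#' the named timeline window, measured in seconds from the start of the
#' recording (`t0`). The sample count is `round((end - start) * fs)`.
#'
#' @param rec An [lfp_recording()].
#' @param timeline A [session_timeline()].
#' @param label Window label to extract.
#' @return An [lfp_recording()] covering the window, with `t0` set to the
#'   window start.
#' @export
extract_window <- function(rec, timeline, label) {
  stopifnot(inherits(rec, "lfp_recording"),
            inherits(timeline, "session_timeline"))
  w <- timeline$windows[timeline$windows$label == label, ]
  if (nrow(w) != 1L) stop("no window labeled '", label, "' in timeline")
  i0 <- round((w$start - rec$t0) * rec$fs)      # 0-based first sample
  i1 <- round((w$end - rec$t0) * rec$fs)        # 0-based one-past-last
  n <- n_samples(rec)
  if (i0 < 0 || i1 > n) {
    miss <- max(0, -i0) / rec$fs + max(0, i1 - n) / rec$fs
    stop(sprintf(
      "window '%s' [%g, %g) s extends %.3f s beyond the recording (%g s)",
      label, w$start, w$end, miss, n / rec$fs))
  }
  out <- rec
  out$samples <- rec$samples[(i0 + 1):i1, , drop = FALSE]
  out$t0 <- w$start
  out$meta <- c(rec$meta, list(window = label))
  out
}
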