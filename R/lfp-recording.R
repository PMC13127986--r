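#' Multichannel LFP recording
#'
#' Container for a uniformly sampled local field potential recording:
#' a samples matrix (one column per channel, microvolts), the sampling
#' rate, the recording start time, and a free-form metadata list used to
#' carry provenance (acquisition band, filter parameters applied, simulation
#' parameters, seeds).
#'
#' @param samples Numeric vector (single channel) or matrix with one column
#'   per channel, in microvolts.
#' @param fs Sampling rate in Hz, `> 0`.
#' @param channel_ids Character vector of channel labels; defaults to the
#'   matrix column names or `ch1, ch2, ...`.
#' @param t0 Recording start time in seconds (default 0).
#' @param meta Named list of provenance metadata.
#' @return An object of class `lfp_recording`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 7 * seq(0, 1, by = 1/500)), fs = 500)
#' rec
#' @export
lfp_recording <- function(samples, fs, channel_ids = NULL, t0 = 0,
                          meta = list()) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, ncol = 1)
  }
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (is.null(channel_ids)) {
    channel_ids <- colnames(samples)
    if (is.null(channel_ids)) {
      channel_ids <- paste0("ch", seq_len(ncol(samples)))
    }
  }
  if (length(channel_ids) != ncol(samples)) {
    stop("channel_ids length (", length(channel_ids),
         ") does not match channel count (", ncol(samples), ")")
  }
  colnames(samples) <- channel_ids
  structure(
    list(samples = samples, fs = fs, channel_ids = channel_ids,
         t0 = t0, meta = meta),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> %d channel(s) [%s], %d samples @ %g Hz (%.2f s), t0 = %g s\n",
    ncol(x$samples), paste(x$channel_ids, collapse = ", "),
    nrow(x$samples), x$fs, nrow(x$samples) / x$fs, x$t0))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples per channel
#' @param rec An [lfp_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  nrow(rec$samples)
}

#' Recording duration in seconds
#' @param rec An [lfp_recording()].
#' @return Duration in seconds (`n_samples / fs`).
#' @export
lfp_duration <- function(rec) n_samples(rec) / rec$fs

#' Sample times of a recording
#' @param rec An [lfp_recording()].
#' @return Numeric vector `t0 + (0:(n-1))/fs`.
#' @export
lfp_times <- function(rec) rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$fs

# apply a per-channel function (returning a same-length series) to every
# channel, preserving structure and appending to meta
map_channels <- function(rec, f, meta_add = NULL) {
  out <- rec
  out$samples <- apply(rec$samples, 2L, f)
  if (!is.matrix(out$samples)) out$samples <- matrix(out$samples, ncol = 1)
  colnames(out$samples) <- rec$channel_ids
  if (!is.null(meta_add)) out$meta <- c(out$meta, meta_add)
  out
}
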