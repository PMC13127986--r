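# Second-order-section (biquad) IIR machinery.
#
# High-order narrowband Butterworth designs are numerically unusable in
# single transfer-function (b, a) form at the normalized bandwidths this
# package needs (e.g. 4-10 Hz at fs = 2000 Hz), so all IIR filtering is done
# as a cascade of biquads, designed directly in zero-pole-gain form and
# factored into sections. Each sos row is c(b0, b1, b2, a0, a1, a2), a0 = 1.

# Butterworth band-pass design: analog prototype -> band transform ->
# bilinear transform -> conjugate-pole biquad sections.
butter_bandpass_sos <- function(order, f_lo, f_hi, fs) {
  stopifnot(order >= 1, f_lo > 0, f_hi > f_lo, f_hi < fs / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP poles
  # pre-warped analog band edges
  wl <- 2 * fs * tan(pi * f_lo / fs)
  wh <- 2 * fs * tan(pi * f_hi / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # lowpass -> bandpass: every prototype pole splits into two
  disc <- sqrt((proto * bw)^2 - 4 * w0^2)
  poles_s <- c((proto * bw + disc) / 2, (proto * bw - disc) / 2)
  gain_s <- bw^order                       # n analog zeros at s = 0
  # bilinear transform z = (2fs + s) / (2fs - s)
  fs2 <- 2 * fs
  poles_z <- (fs2 + poles_s) / (fs2 - poles_s)
  gain_z <- gain_s * Re(fs2^order / prod(fs2 - poles_s))
  # sections: one conjugate pole pair each; zeros distributed as (z-1)(z+1)
  pos <- poles_z[Im(poles_z) >= 0]
  pos <- pos[order(-Mod(pos))]
  if (length(pos) != order) stop("pole pairing failed; check band edges")
  sos <- t(vapply(pos, function(p) {
    c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }, numeric(6)))
  sos[1, 1:3] <- sos[1, 1:3] * gain_z
  sos
}

# RBJ audio-cookbook biquad notch at f0 with quality factor q
# (bandwidth ~ f0/q); one sos row.
biquad_notch <- function(f0, fs, q) {
  stopifnot(f0 > 0, f0 < fs / 2, q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  c(b / a[1], a / a[1])
}

# single biquad pass with steady-state initial conditions for a constant
# history equal to x[1]: a constant input passes with zero transient, which
# keeps edge artifacts of the forward-backward pass short.
biquad_apply <- function(b, a, x) {
  n <- length(x)
  # moving-average part with constant pre-history
  v <- stats::filter(c(x[1], x[1], x), b, method = "convolution",
                     sides = 1)[3:(n + 2)]
  # recursive part initialised at the constant-input steady state
  y_ss <- x[1] * sum(b) / sum(a)
  as.numeric(stats::filter(v, -a[2:3], method = "recursive",
                           init = c(y_ss, y_ss)))
}

# causal pass of a biquad cascade
sos_filter <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    x <- biquad_apply(sos[i, 1:3], sos[i, 4:6], x)
  }
  x
}

# zero-phase (forward-backward) pass; squared magnitude response, zero net
# group delay. Remaining edge transients are handled downstream by trimming
# a margin.
sos_filtfilt <- function(sos, x) {
  rev(sos_filter(sos, rev(sos_filter(sos, x))))
}
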