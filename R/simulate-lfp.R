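#' Parameters for the coupled-oscillation LFP simulator
#'
#' The synthetic signal model is
#' `a_theta * sin(2*pi*f_theta*t)` plus a gamma oscillation whose
#' instantaneous amplitude is
#' `a_gamma * (1 + kappa * cos(phi_theta - psi0)) / (1 + kappa)`,
#' plus pink (1/f power) background noise and a family of line-noise
#' sinusoids at 50 Hz and harmonics. `phi_theta` is the Hilbert-convention
#' instantaneous phase of the theta component, so a phase-amplitude
#' coupling estimator applied to the output should recover `psi0` as the
#' preferred phase and a coupling strength monotone in `kappa`. The
#' `(1 + kappa)` normalisation pins the envelope maximum, keeping mean
#' gamma power approximately `kappa`-invariant so power and coupling are
#' independently controllable.
#'
#' @param fs Sampling rate in Hz (default 2000, the acquisition rate the
#'   pipeline targets).
#' @param duration Signal duration in seconds.
#' @param f_theta Theta frequency in Hz, within 4-10 (default 7).
#' @param a_theta Theta amplitude in microvolts (default 50).
#' @param f_gamma Gamma frequency in Hz, within 30-100 (default 75).
#' @param a_gamma Gamma amplitude in microvolts (default 10).
#' @param kappa Coupling strength in `[0, 1]`; 0 = unmodulated gamma,
#'   1 = fully modulated.
#' @param psi0 Preferred coupling phase in radians (default 0).
#' @param pink_sigma Standard deviation of the pink-noise background in
#'   microvolts (default 0 = noise-free).
#' @param line_amp Named numeric vector of line-component amplitudes in
#'   microvolts, names = frequencies in Hz (default none). Components at
#'   or above Nyquist are rejected.
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   seed.
#' @return An object of class `lfp_sim_params`.
#' @export
lfp_sim_params <- function(fs = 2000, duration = 60, f_theta = 7,
                           a_theta = 50, f_gamma = 75, a_gamma = 10,
                           kappa = 0.5, psi0 = 0, pink_sigma = 0,
                           line_amp = NULL, seed = 1) {
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (f_theta < 4 || f_theta > 10) stop("f_theta must lie in [4, 10] Hz")
  if (f_gamma < 30 || f_gamma > 100) stop("f_gamma must lie in [30, 100] Hz")
  if (fs <= 2 * f_gamma) {
    stop("fs = ", fs, " Hz aliases the gamma component (need fs > ",
         2 * f_gamma, ")")
  }
  if (!is.null(line_amp)) {
    stopifnot(!is.null(names(line_amp)))
    if (any(as.numeric(names(line_amp)) >= fs / 2)) {
      stop("line components must lie below Nyquist")
    }
  }
  if (duration <= 0) stop("duration must be positive")
  structure(list(fs = fs, duration = duration, f_theta = f_theta,
                 a_theta = a_theta, f_gamma = f_gamma, a_gamma = a_gamma,
                 kappa = kappa, psi0 = psi0, pink_sigma = pink_sigma,
                 line_amp = line_amp, seed = as.integer(seed)),
            class = "lfp_sim_params")
}

# pink noise (power ~ 1/f) by spectrally shaping white Gaussian noise;
# no power below f_min, matching a 1 Hz acquisition high-pass edge
pink_noise <- function(n, fs, sigma, f_min = 1) {
  if (sigma <= 0) return(numeric(n))
  w <- fft(rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)                 # two-sided frequency axis
  shape <- ifelse(f_fold >= f_min, 1 / sqrt(f_fold), 0)
  shape[1] <- 0                             # no DC
  x <- Re(fft(w * shape, inverse = TRUE)) / n
  sigma * x / sd(x)
}

# gamma oscillation amplitude-modulated by the theta Hilbert phase
modulated_gamma <- function(t, f_gamma, a_gamma, kappa, psi0, phi_theta) {
  env <- a_gamma * (1 + kappa * cos(phi_theta - psi0)) / (1 + kappa)
  env * sin(2 * pi * f_gamma * t)
}

#' Generate a synthetic theta-modulated gamma LFP recording
#'
#' @param params An [lfp_sim_params()].
#' @return A single-channel [lfp_recording()]; `meta$sim` carries the
#'   full parameter set including the seed.
#' @examples
#' rec <- generate_coupled_lfp(lfp_sim_params(duration = 10, kappa = 1))
#' @export
generate_coupled_lfp <- function(params) {
  stopifnot(inherits(params, "lfp_sim_params"))
  p <- params
  n <- round(p$fs * p$duration)
  t <- (seq_len(n) - 1) / p$fs
  # Hilbert-convention phase of a_theta*sin(2*pi*f*t) is 2*pi*f*t - pi/2
  phi_theta <- 2 * pi * p$f_theta * t - pi / 2
  x <- p$a_theta * sin(2 * pi * p$f_theta * t) +
    modulated_gamma(t, p$f_gamma, p$a_gamma, p$kappa, p$psi0, phi_theta)
  set.seed(p$seed)
  if (p$pink_sigma > 0) x <- x + pink_noise(n, p$fs, p$pink_sigma)
  if (!is.null(p$line_amp)) {
    for (i in seq_along(p$line_amp)) {
      f0 <- as.numeric(names(p$line_amp)[i])
      x <- x + p$line_amp[[i]] * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
    }
  }
  lfp_recording(x, fs = p$fs, channel_ids = "sim",
                meta = list(sim = unclass(p)))
}
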