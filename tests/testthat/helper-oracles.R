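# Independent brute-force oracles and small fixture builders shared by the
# tests. These evaluate defining formulas directly and never call the
# package code paths they are used to check.

# one-way fixed-effects F from the sum-of-squares decomposition
brute_force_f <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  k <- length(groups); n <- length(all_v)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# tie-corrected Kruskal-Wallis H from the rank formula
brute_force_h <- function(groups) {
  v <- unlist(groups)
  n <- length(v)
  rk <- rank(v)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(rk, idx, mean)
  ni <- tapply(rk, idx, length)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# single-channel pure-sine recording
sine_rec <- function(f, fs = 2000, duration = 10, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  lfp_recording(amp * sin(2 * pi * f * t + phase), fs = fs)
}

# RMS amplitude of the interior of a (possibly edge-distorted) series
interior_amp <- function(x, frac = 0.2) {
  n <- length(x)
  keep <- seq(floor(n * frac), ceiling(n * (1 - frac)))
  sqrt(2 * mean(x[keep]^2))
}

# attenuation in dB of a filtered sine relative to unit amplitude
atten_db <- function(x, frac = 0.2) -20 * log10(interior_amp(x, frac))

# minimal DeepLabCut-style CSV fixture; returns the path
write_dlc_fixture <- function(path, x, y, lik, fps = 30,
                              bodypart = "center") {
  n <- length(x)
  con <- file(path, "w")
  writeLines(c(
    paste0("scorer,", paste(rep("model", 3), collapse = ",")),
    paste0("bodyparts,", paste(rep(bodypart, 3), collapse = ",")),
    "coords,x,y,likelihood"), con)
  writeLines(paste(0:(n - 1), x, y, lik, sep = ","), con)
  close(con)
  path
}
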