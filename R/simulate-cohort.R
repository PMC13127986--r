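#' Specification of a synthetic multi-animal cohort
#'
#' Emulates the design of a pharmacological LFP experiment: every animal
#' contributes a baseline epoch and a post-injection epoch generated from
#' the same animal-specific parameters; treatment effects are applied only
#' in the post epoch, as per-group multipliers on low-gamma power,
#' high-gamma power, and the theta-high-gamma coupling strength kappa.
#' Between-animal variability is lognormal on amplitudes and kappa.
#'
#' The default groups and sizes mirror a three-group design with unequal
#' n (7/5/5); the default treated-group effects are a 1.5x low-gamma power
#' increase and a 0.25x reduction of theta-high-gamma coupling — effect
#' directions matching an NMDA-antagonist phenotype (elevated low gamma,
#' disrupted theta-high-gamma coupling). The magnitudes are free
#' parameters of the simulator, documented as such.
#'
#' @param groups Named integer vector: animals per group, e.g.
#'   `c(saline = 7, mk801 = 5, ly_mk801 = 5)`.
#' @param multipliers Named list (by group label) of named numeric vectors
#'   with entries `low_gamma`, `high_gamma` (power multipliers, applied in
#'   the post epoch) and `kappa` (coupling multiplier). Groups without an
#'   entry are untreated (all multipliers 1).
#' @param between_sigma Lognormal sigma of between-animal variability on
#'   amplitudes and kappa (default 0.2).
#' @param fs Sampling rate in Hz for the simulated epochs (default 500 —
#'   sufficient for a 100 Hz upper analysis band while keeping cohort
#'   Monte-Carlo experiments cheap).
#' @param duration Epoch duration in seconds (default 60).
#' @param f_theta,a_theta Theta frequency (Hz) and amplitude (uV).
#' @param f_low_gamma,a_low_gamma Low-gamma oscillation frequency and
#'   amplitude (defaults 40 Hz, 15 uV).
#' @param f_high_gamma,a_high_gamma High-gamma oscillation frequency and
#'   amplitude (defaults 75 Hz, 10 uV).
#' @param kappa Baseline theta-high-gamma coupling strength (default 0.5).
#' @param kappa_low Theta-low-gamma coupling strength, identical in all
#'   groups and epochs (default 0.3).
#' @param psi0 Preferred coupling phase (rad).
#' @param pink_sigma Pink-noise sigma in uV (default 20).
#' @param line_amp Line-noise amplitudes as in [lfp_sim_params()]
#'   (default: 5 uV at 50 Hz, 2 uV at 100 Hz, 1 uV at 150 Hz).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c(saline = 7, mk801 = 5, ly_mk801 = 5),
                        multipliers = list(
                          mk801 = c(low_gamma = 1.5, high_gamma = 1,
                                    kappa = 0.25),
                          ly_mk801 = c(low_gamma = 1.5, high_gamma = 1,
                                       kappa = 0.25)),
                        between_sigma = 0.2, fs = 500, duration = 60,
                        f_theta = 7, a_theta = 50,
                        f_low_gamma = 40, a_low_gamma = 15,
                        f_high_gamma = 75, a_high_gamma = 10,
                        kappa = 0.5, kappa_low = 0.3, psi0 = 0,
                        pink_sigma = 20,
                        line_amp = c("50" = 5, "100" = 2, "150" = 1),
                        seed = 1) {
  stopifnot(!is.null(names(groups)), all(groups >= 1))
  if (missing(multipliers)) {
    # default treated-group effects only apply to groups actually present
    multipliers <- multipliers[names(multipliers) %in% names(groups)]
  }
  for (g in names(multipliers)) {
    if (!g %in% names(groups)) stop("multiplier for unknown group '", g, "'")
    if (any(multipliers[[g]] <= 0)) stop("multipliers must be positive")
  }
  if (fs <= 2 * f_high_gamma) stop("fs must exceed twice the highest band")
  structure(list(groups = groups, multipliers = multipliers,
                 between_sigma = between_sigma, fs = fs,
                 duration = duration, f_theta = f_theta, a_theta = a_theta,
                 f_low_gamma = f_low_gamma, a_low_gamma = a_low_gamma,
                 f_high_gamma = f_high_gamma, a_high_gamma = a_high_gamma,
                 kappa = kappa, kappa_low = kappa_low, psi0 = psi0,
                 pink_sigma = pink_sigma, line_amp = line_amp,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# one epoch: theta + coupled low gamma + coupled high gamma + pink + line
cohort_epoch <- function(sp, a_theta, a_low, a_high, k_low, k_high) {
  n <- round(sp$fs * sp$duration)
  t <- (seq_len(n) - 1) / sp$fs
  phi_theta <- 2 * pi * sp$f_theta * t - pi / 2
  x <- a_theta * sin(2 * pi * sp$f_theta * t) +
    modulated_gamma(t, sp$f_low_gamma, a_low, k_low, sp$psi0, phi_theta) +
    modulated_gamma(t, sp$f_high_gamma, a_high, k_high, sp$psi0, phi_theta)
  if (sp$pink_sigma > 0) x <- x + pink_noise(n, sp$fs, sp$pink_sigma)
  if (!is.null(sp$line_amp)) {
    for (i in seq_along(sp$line_amp)) {
      f0 <- as.numeric(names(sp$line_amp)[i])
      if (f0 < sp$fs / 2) {
        x <- x + sp$line_amp[[i]] * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
      }
    }
  }
  x
}

#' Generate a synthetic cohort of baseline/post LFP epoch pairs
#'
#' Draws animal-level parameters once per animal (shared between that
#' animal's baseline and post epochs) and applies the group multipliers
#' only in the post epoch: power multipliers scale the corresponding
#' oscillation amplitude by `sqrt(multiplier)`, the kappa multiplier
#' scales the coupling strength (clamped to `[0, 1]`). Deterministic for
#' a fixed `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `animals` (list of
#'   `list(id, group, baseline, post)` where `baseline` and `post` are
#'   [lfp_recording()]s) and `truth` (tibble of the drawn per-animal
#'   parameters), plus the `spec` itself.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  animals <- list()
  truth <- list()
  for (g in names(spec$groups)) {
    mult <- spec$multipliers[[g]]
    m_low <- if (!is.null(mult)) mult[["low_gamma"]] else 1
    m_high <- if (!is.null(mult)) mult[["high_gamma"]] else 1
    m_kappa <- if (!is.null(mult)) mult[["kappa"]] else 1
    for (i in seq_len(spec$groups[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      lf <- exp(rnorm(4, 0, spec$between_sigma))   # animal-level factors
      a_theta <- spec$a_theta * lf[1]
      a_low <- spec$a_low_gamma * lf[2]
      a_high <- spec$a_high_gamma * lf[3]
      k_high <- min(1, spec$kappa * lf[4])
      base <- cohort_epoch(spec, a_theta, a_low, a_high,
                           spec$kappa_low, k_high)
      post <- cohort_epoch(spec, a_theta, a_low * sqrt(m_low),
                           a_high * sqrt(m_high), spec$kappa_low,
                           min(1, k_high * m_kappa))
      mk_rec <- function(x, w) {
        lfp_recording(x, fs = spec$fs, channel_ids = "sim",
                      meta = list(animal = id, group = g, window = w,
                                  seed = spec$seed))
      }
      animals[[id]] <- list(id = id, group = g,
                            baseline = mk_rec(base, "baseline"),
                            post = mk_rec(post, "post"))
      truth[[id]] <- tibble::tibble(
        animal = id, group = g, a_theta = a_theta, a_low_gamma = a_low,
        a_high_gamma = a_high, kappa_high = k_high,
        kappa_high_post = min(1, k_high * m_kappa),
        mult_low_gamma = m_low, mult_high_gamma = m_high,
        mult_kappa = m_kappa)
    }
  }
  list(animals = animals, truth = do.call(rbind, truth), spec = spec)
}
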