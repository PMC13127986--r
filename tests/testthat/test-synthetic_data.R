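test_that("kappa = 0 with noise off gives a flat gamma envelope", {
  rec <- generate_coupled_lfp(lfp_sim_params(duration = 10, kappa = 0,
                                             a_theta = 0, pink_sigma = 0))
  env <- amplitude_envelope(rec$samples[, 1])
  interior <- env[2000:18000]
  expect_lt(sd(interior) / mean(interior), 0.01)
})

test_that("kappa = 1 envelope peaks at theta phase psi0", {
  psi0 <- 1.2
  p <- lfp_sim_params(duration = 20, kappa = 1, psi0 = psi0,
                      pink_sigma = 0)
  rec <- generate_coupled_lfp(p)
  fs <- rec$fs
  gamma <- bandpass(rec, band_high_gamma())$samples[, 1]
  env <- amplitude_envelope(gamma)
  t <- lfp_times(rec)
  phi_theta <- (2 * pi * p$f_theta * t - pi / 2)
  # local maxima of the envelope, away from the edges
  i <- which(diff(sign(diff(env))) == -2) + 1L
  i <- i[i > 2 * fs & i < length(env) - 2 * fs]
  # circular mean of theta phase at envelope peaks, weighted by height
  z <- sum(env[i] * exp(1i * phi_theta[i])) / sum(env[i])
  expect_lt(abs(Arg(z) - psi0), 0.05)
})

test_that("generator is deterministic for a fixed seed", {
  p <- lfp_sim_params(duration = 2, pink_sigma = 15,
                      line_amp = c("50" = 5), seed = 42)
  expect_identical(generate_coupled_lfp(p)$samples,
                   generate_coupled_lfp(p)$samples)
  sp <- cohort_spec(groups = c(a = 3, b = 3), duration = 10, seed = 9)
  c1 <- generate_cohort(sp); c2 <- generate_cohort(sp)
  expect_identical(c1$animals[[2]]$post$samples,
                   c2$animals[[2]]$post$samples)
  expect_identical(c1$truth, c2$truth)
})

test_that("generator parameter validation rejects aliasing and bad kappa", {
  expect_error(lfp_sim_params(fs = 150, f_gamma = 80), "alias")
  expect_error(lfp_sim_params(kappa = 1.5), "kappa")
  expect_error(lfp_sim_params(f_theta = 2), "f_theta")
})

test_that("PSD of generated LFP peaks at the programmed frequencies", {
  rec <- generate_coupled_lfp(lfp_sim_params(duration = 30, f_theta = 7,
                                             f_gamma = 75, pink_sigma = 5,
                                             seed = 2))
  psd <- welch_psd(rec)
  d <- psd$density[, 1]; f <- psd$freqs
  expect_equal(f[which.max(d * (f < 20))], 7, tolerance = 0.51)
  expect_equal(f[which.max(d * (f > 55 & f < 110))], 75, tolerance = 0.51)
})

test_that("cohort multipliers drive downstream group effects", {
  # low-gamma power multiplier 1.5 -> percent-of-baseline ~ +50 in treated
  sp <- cohort_spec(groups = c(ctrl = 4, trt = 4),
                    multipliers = list(trt = c(low_gamma = 1.5,
                                               high_gamma = 1, kappa = 1)),
                    between_sigma = 0.1, duration = 30, pink_sigma = 5,
                    line_amp = NULL, seed = 7)
  co <- generate_cohort(sp)
  pct <- vapply(co$animals, function(a) {
    b <- band_power(welch_psd(a$baseline), band_low_gamma())
    p <- band_power(welch_psd(a$post), band_low_gamma())
    mean(percent_change(p, b)$percent)
  }, numeric(1))
  grp <- vapply(co$animals, function(a) a$group, character(1))
  expect_equal(mean(pct[grp == "trt"]), 50, tolerance = 10)
  expect_lt(abs(mean(pct[grp == "ctrl"])), 10)
})

test_that("kappa multiplier lowers downstream PLV in the treated group", {
  hits <- vapply(1:6, function(s) {
    sp <- cohort_spec(groups = c(ctrl = 3, trt = 3),
                      multipliers = list(trt = c(low_gamma = 1,
                                                 high_gamma = 1,
                                                 kappa = 0.25)),
                      duration = 30, seed = s)
    co <- generate_cohort(sp)
    plv <- vapply(co$animals, function(a) {
      plv_pac(a$post, amp_band = band_high_gamma())$plv
    }, numeric(1))
    grp <- vapply(co$animals, function(a) a$group, character(1))
    mean(plv[grp == "trt"]) < mean(plv[grp == "ctrl"])
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("walk generator respects speed, bounds and stationarity", {
  # degenerate: zero mean speed never moves
  tr0 <- generate_walk(walk_params(mean_speed = 0, bounds = 70), 60, 0.1)
  expect_equal(path_length(tr0), 0)
  # mean speed recovered within 10 %
  tr <- generate_walk(walk_params(mean_speed = 10, bounds = 70, seed = 4),
                      300, 0.1)
  expect_equal(path_length(tr) / 300, 10, tolerance = 0.1)
  # never leaves the box (several seeds)
  for (s in 1:5) {
    trs <- generate_walk(walk_params(mean_speed = 25, bounds = 70,
                                     seed = s), 120, 0.05)
    expect_true(all(abs(trs$x) <= 35 + 1e-9 & abs(trs$y) <= 35 + 1e-9))
  }
  # disc bound
  trd <- generate_walk(walk_params(mean_speed = 20, bounds = 41,
                                   bound_shape = "disc", seed = 2), 120, 0.05)
  expect_true(all(sqrt(trd$x^2 + trd$y^2) <= 41 + 1e-9))
})

test_that("a disc-fixed point traces the circumference once per revolution", {
  ar <- arena_config()
  tr <- generate_walk(walk_params(mean_speed = 0, bounds = 41,
                                  bound_shape = "disc",
                                  mode = "stationary_arena",
                                  start = c(30, 0)),
                      duration = 60, dt = 0.05, arena = ar)
  expect_equal(path_length(tr), 2 * pi * 30, tolerance = 1e-3)
  expect_equal(sqrt(tr$x^2 + tr$y^2), rep(30, nrow(tr)), tolerance = 1e-9)
})

test_that("higher avoidance gain yields stochastically fewer entrances", {
  ar <- arena_config(session_length = 300)
  n_ent <- function(gain, seed) {
    tr <- generate_walk(walk_params(mean_speed = 12, bounds = 41,
                                    bound_shape = "disc",
                                    avoidance_gain = gain, seed = seed),
                        300, 0.1, arena = ar)
    nrow(detect_entrances(tr, ar))
  }
  seeds <- 1:10
  passive <- vapply(seeds, function(s) n_ent(0, s), numeric(1))
  avoider <- vapply(seeds, function(s) n_ent(40, s), numeric(1))
  expect_lt(mean(avoider), mean(passive))
})
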