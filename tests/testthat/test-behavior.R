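arena <- arena_config()

test_that("frame transform round-trips and preserves radius", {
  set.seed(3)
  n <- 500
  tr <- trajectory(seq(0, 49.9, by = 0.1), runif(n, -30, 30),
                   runif(n, -30, 30), frame = "room")
  back <- transform_frame(transform_frame(tr, arena, "arena"), arena, "room")
  expect_lt(max(abs(back$x - tr$x)), 1e-9)
  expect_lt(max(abs(back$y - tr$y)), 1e-9)
  ar_tr <- transform_frame(tr, arena, "arena")
  expect_equal(sqrt(ar_tr$x^2 + ar_tr$y^2), sqrt(tr$x^2 + tr$y^2),
               tolerance = 1e-12)
  # t = 0 is the identity
  expect_equal(ar_tr$x[1], tr$x[1], tolerance = 1e-12)
  # same-frame request is a warned no-op
  expect_warning(transform_frame(tr, arena, "room"), "already")
})

test_that("path length handles polygons, stationarity and jitter", {
  sq <- trajectory(0:4, c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0),
                   frame = "room")
  expect_equal(path_length(sq), 40)
  still <- trajectory(0:10, rep(1, 11), rep(2, 11), frame = "room")
  expect_equal(path_length(still), 0)
  # tracker jitter is suppressed by median smoothing plus the step floor
  set.seed(9)
  n <- 900
  jit <- trajectory(seq(0, by = 1, length.out = n),
                    rnorm(n, 0, 0.1), rnorm(n, 0, 0.1), frame = "room")
  expect_lt(path_length(jit, smooth_win = 5, jitter_floor = 0.5), 1)
  expect_gt(path_length(jit), 50)   # raw jitter would dominate
})

test_that("time in centre follows the concentric-square definition", {
  cfg <- open_field_config()  # 70 cm box, fraction 0.25 -> 35 cm square
  expect_equal(cfg$side * sqrt(cfg$center_zone_fraction), 35)
  centre <- trajectory(seq(0, 899, by = 1), rep(0, 900), rep(0, 900),
                       frame = "room")
  expect_equal(time_in_center(centre, cfg), 900)
  # exactly half the samples inside (alternating centre / corner)
  n <- 900
  x <- rep(c(0, 30), n / 2)
  half <- trajectory(seq(0, n - 1), x, x, frame = "room")
  expect_equal(time_in_center(half, cfg), n / 2)
})

test_that("disc-fixed point yields the sector-sweep entrance schedule", {
  # point at 30 cm radius on the rotating disc sweeps the 60-degree
  # room sector once per 60 s revolution, dwelling 1/6 of the period
  a0 <- (-90 + 0.5) * pi / 180
  tr <- generate_walk(
    walk_params(mean_speed = 0, bounds = 41, bound_shape = "disc",
                mode = "stationary_arena",
                start = 30 * c(cos(a0), sin(a0))),
    duration = 1200, dt = 0.05, arena = arena)
  ent <- detect_entrances(tr, arena)
  expect_equal(nrow(ent), 20)
  expect_equal(ent$dwell, rep(10, 20), tolerance = 0.02)
  shocks <- count_shocks(ent, arena)
  expect_equal(nrow(shocks), 240)                    # 12 per dwell
  expect_equal(unname(table(shocks$entrance)[1]), 12)
  # room-frame path length: 20 revolutions of a 30 cm circle
  expect_equal(path_length(tr), 20 * 2 * pi * 30, tolerance = 0.001 * 3770)
  # in the arena frame the point is stationary
  expect_lt(path_length(transform_frame(tr, arena, "arena")), 1e-6)
})

test_that("entrance and shock edge cases behave by definition", {
  # never in sector
  far <- trajectory(seq(0, 10, by = 0.1),
                    rep(-20, 101), rep(0, 101), frame = "room")
  ar0 <- arena_config(sector_center = 0)
  expect_equal(nrow(detect_entrances(far, ar0)), 0)
  expect_equal(nrow(count_shocks(detect_entrances(far, ar0), ar0)), 0)
  # single in-out crossing = one entrance
  th <- seq(-60, 60, by = 1) * pi / 180
  cross <- trajectory(seq_along(th) - 1, 30 * cos(th), 30 * sin(th),
                      frame = "room")
  ent <- detect_entrances(cross, ar0)
  expect_equal(nrow(ent), 1)
  # a dwell of 2.0 s earns shocks at offsets 0, 0.9, 1.8
  ent1 <- tibble::tibble(enter = 5, exit = 7, dwell = 2)
  sh <- count_shocks(ent1, ar0)
  expect_equal(sh$t, c(5, 5.9, 6.8))
  # shocks >= entrances whenever the sector is visited
  expect_gte(nrow(sh), nrow(ent1))
  # hysteresis merges rapid re-entries
  t <- seq(0, 20, by = 0.1)
  az <- ifelse(t %% 4 < 3, 0, 90) * pi / 180   # 3 s in, 1 s out, repeat
  wig <- trajectory(t, 30 * cos(az), 30 * sin(az), frame = "room")
  expect_gt(nrow(detect_entrances(wig, ar0)), 1)
  expect_equal(nrow(detect_entrances(wig, ar0, min_outside = 2)), 1)
})

test_that("binned metrics respect the session grid and sum to totals", {
  set.seed(11)
  tr <- generate_walk(walk_params(mean_speed = 10, bounds = 70, seed = 11),
                      duration = 1200, dt = 0.1)
  b4 <- bin_metric(tr, 300, "distance")        # 20 min / 5 min = 4 bins
  expect_equal(nrow(b4), 4)
  expect_equal(sum(b4$value), path_length(tr), tolerance = 1e-9)
  tr15 <- generate_walk(walk_params(mean_speed = 10, bounds = 70, seed = 2),
                        duration = 900, dt = 0.1)
  b60 <- bin_metric(tr15, 60, "distance")      # 15 min / 1 min = 15 bins
  expect_equal(nrow(b60), 15)
  # centre time bins sum to the total
  cfg <- open_field_config()
  bc <- bin_metric(tr15, 300, "center_time", cfg = cfg)
  expect_equal(sum(bc$value), time_in_center(tr15, cfg), tolerance = 0.2)
  # entrance bins sum to the total count
  a0 <- (-90 + 0.5) * pi / 180
  disc <- generate_walk(
    walk_params(mean_speed = 0, bounds = 41, bound_shape = "disc",
                mode = "stationary_arena", start = 30 * c(cos(a0), sin(a0))),
    duration = 1200, dt = 0.05, arena = arena)
  be <- bin_metric(disc, 300, "entrances", arena = arena)
  expect_equal(sum(be$value), 20)
  bs <- bin_metric(disc, 300, "shocks", arena = arena)
  expect_equal(sum(bs$value), 240)
  expect_error(bin_metric(tr15, 77, "distance"), "does not divide")
})

test_that("room and arena distances differ by at most the passive transport", {
  set.seed(13)
  tr <- generate_walk(walk_params(mean_speed = 8, bounds = 41,
                                  bound_shape = "disc", seed = 13),
                      duration = 600, dt = 0.1)
  d_room <- path_length(tr)
  d_arena <- path_length(transform_frame(tr, arena, "arena"))
  bound <- 2 * pi * arena$radius * (600 / arena$rotation_period)
  expect_lt(abs(d_room - d_arena), bound)
})
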