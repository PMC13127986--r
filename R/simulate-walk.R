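#' Parameters for the confined random-walk trajectory simulator
#'
#' Locomotion is modelled as an Ornstein-Uhlenbeck velocity process
#' (persistent random walk) reflected at the enclosure boundary — a box of
#' side `bounds` or a disc of radius `bounds`. An optional avoidance drift
#' steers the walker away from a room-frame sector (used to emulate active
#' place avoidance): whenever the walker is inside the sector dilated by
#' 15 degrees, a tangential acceleration of magnitude `avoidance_gain`
#' (cm/s^2) pushes it out the nearer edge. Two degenerate modes generate
#' reference fixtures: `stationary_room` (a point fixed in the room) and
#' `stationary_arena` (a point fixed on the rotating disc, expressed in
#' room coordinates).
#'
#' @param mean_speed Target mean speed in cm/s (`>= 0`).
#' @param persistence Velocity autocorrelation time in seconds
#'   (default 1).
#' @param bounds Box side or disc radius in cm.
#' @param bound_shape `"box"` or `"disc"`.
#' @param avoidance_gain Avoidance drift in cm/s^2; 0 = passive walker.
#' @param mode `"stochastic"`, `"stationary_room"` or `"stationary_arena"`.
#' @param start Optional starting position `c(x, y)` in cm (default: the
#'   centre for stochastic walks; must be given for stationary modes).
#' @param seed Integer RNG seed.
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(mean_speed, persistence = 1, bounds,
                        bound_shape = c("box", "disc"),
                        avoidance_gain = 0,
                        mode = c("stochastic", "stationary_room",
                                 "stationary_arena"),
                        start = NULL, seed = 1) {
  mode <- match.arg(mode)
  bound_shape <- match.arg(bound_shape)
  stopifnot(mean_speed >= 0, persistence > 0, bounds > 0,
            avoidance_gain >= 0)
  if (mode != "stochastic" && is.null(start)) {
    stop("stationary modes need an explicit start position")
  }
  structure(list(mean_speed = mean_speed, persistence = persistence,
                 bounds = bounds, bound_shape = bound_shape,
                 avoidance_gain = avoidance_gain, mode = mode,
                 start = start, seed = as.integer(seed)),
            class = "walk_params")
}

# smallest signed angular difference a - b in degrees, in (-180, 180]
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Generate a confined random-walk trajectory
#'
#' Output is always expressed in the room frame. For
#' `mode = "stationary_arena"` the point is fixed on the rotating disc, so
#' its room-frame path is a circle traversed once per arena revolution
#' (`arena` must be supplied). For stochastic walks the per-component OU
#' stationary standard deviation is chosen so that the mean of the speed
#' modulus (Rayleigh mean) equals `mean_speed`.
#'
#' @param params A [walk_params()].
#' @param duration Session length in seconds.
#' @param dt Sampling interval in seconds (`> 0`).
#' @param arena An [arena_config()]; required for `stationary_arena` and
#'   for `avoidance_gain > 0`.
#' @return A [trajectory()] in the room frame.
#' @export
generate_walk <- function(params, duration, dt, arena = NULL) {
  stopifnot(inherits(params, "walk_params"), dt > 0, duration > 0)
  p <- params
  t <- seq(0, duration, by = dt)
  n <- length(t)

  if (p$mode == "stationary_room") {
    return(trajectory(t, rep(p$start[1], n), rep(p$start[2], n),
                      frame = "room"))
  }
  if (p$mode == "stationary_arena") {
    if (is.null(arena)) stop("stationary_arena mode needs an arena config")
    s <- if (arena$rotation_sign == "ccw") 1 else -1
    th <- s * 2 * pi * t / arena$rotation_period
    x0 <- p$start[1]; y0 <- p$start[2]
    return(trajectory(t, x0 * cos(th) - y0 * sin(th),
                      x0 * sin(th) + y0 * cos(th), frame = "room"))
  }

  set.seed(p$seed)
  if (p$avoidance_gain > 0 && is.null(arena)) {
    stop("avoidance_gain > 0 needs an arena config")
  }
  # per-component OU sd giving E|v| = mean_speed for a 2-D isotropic OU
  sd_v <- p$mean_speed / sqrt(pi / 2)
  tau <- p$persistence
  x <- numeric(n); y <- numeric(n)
  pos <- if (is.null(p$start)) c(0, 0) else p$start
  vel <- c(0, 0)
  x[1] <- pos[1]; y[1] <- pos[2]
  noise_scale <- sd_v * sqrt(2 * dt / tau)
  for (i in seq_len(n - 1L)) {
    drift <- c(0, 0)
    if (p$avoidance_gain > 0) {
      az <- atan2(pos[2], pos[1]) * 180 / pi
      off <- ang_diff_deg(az, arena$sector_center)
      if (abs(off) <= arena$sector_halfwidth + 15) {
        # push tangentially out of the nearer sector edge
        dir <- if (off >= 0) 1 else -1
        tang <- c(-pos[2], pos[1]) / max(sqrt(sum(pos^2)), 1e-9)
        drift <- p$avoidance_gain * dir * tang
      }
    }
    vel <- vel + (-vel / tau + drift) * dt + noise_scale * rnorm(2)
    pos <- pos + vel * dt
    # reflect at the boundary
    if (p$bound_shape == "box") {
      half <- p$bounds / 2
      for (k in 1:2) {
        if (pos[k] > half) { pos[k] <- 2 * half - pos[k]; vel[k] <- -vel[k] }
        if (pos[k] < -half) { pos[k] <- -2 * half - pos[k]; vel[k] <- -vel[k] }
      }
    } else {
      r <- sqrt(sum(pos^2))
      if (r > p$bounds) {
        u <- pos / r
        pos <- u * (2 * p$bounds - r)
        vr <- sum(vel * u)
        vel <- vel - 2 * vr * u
      }
    }
    x[i + 1L] <- pos[1]; y[i + 1L] <- pos[2]
  }
  trajectory(t, x, y, frame = "room")
}
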