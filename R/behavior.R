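#' Rotating-arena (active place avoidance) configuration
#'
#' Geometry and rules of the carousel task: a disc of 82 cm diameter
#' rotating at one revolution per minute, with an unmarked 60-degree
#' room-stable sector in which the animal receives footshocks — one at
#' entrance and one per 900 ms of continuous occupancy. Shock current is
#' metadata only (events are modelled as instantaneous points).
#'
#' @param radius Arena radius in cm (default 41).
#' @param rotation_period Rotation period in seconds (default 60, i.e.
#'   1 rpm).
#' @param rotation_sign `"ccw"` (default) or `"cw"`.
#' @param sector_center Room-frame azimuth of the sector centre in
#'   degrees (default 0).
#' @param sector_halfwidth Sector half-width in degrees (default 30, a
#'   60-degree sector).
#' @param shock_interval Interval between successive shocks while inside
#'   the sector, in seconds (default 0.9).
#' @param shock_current Shock current in mA (metadata, default 0.4).
#' @param session_length Session length in seconds (default 1200).
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(radius = 41, rotation_period = 60,
                         rotation_sign = c("ccw", "cw"),
                         sector_center = 0, sector_halfwidth = 30,
                         shock_interval = 0.9, shock_current = 0.4,
                         session_length = 1200) {
  rotation_sign <- match.arg(rotation_sign)
  stopifnot(radius > 0, rotation_period > 0, shock_interval > 0)
  if (sector_halfwidth <= 0 || sector_halfwidth >= 180) {
    stop("sector_halfwidth must lie in (0, 180) degrees")
  }
  structure(list(radius = radius, rotation_period = rotation_period,
                 rotation_sign = rotation_sign,
                 sector_center = sector_center,
                 sector_halfwidth = sector_halfwidth,
                 shock_interval = shock_interval,
                 shock_current = shock_current,
                 session_length = session_length),
            class = "arena_config")
}

#' Open-field configuration
#'
#' @param side Box side in cm (default 70).
#' @param center_zone_fraction Fraction of the box area defining the
#'   centre zone (default 0.25, i.e. a concentric 35 cm square for a
#'   70 cm box).
#' @param session_length Session length in seconds (default 900).
#' @return An object of class `open_field_config`.
#' @export
open_field_config <- function(side = 70, center_zone_fraction = 0.25,
                              session_length = 900) {
  stopifnot(side > 0, session_length > 0)
  if (center_zone_fraction <= 0 || center_zone_fraction >= 1) {
    stop("center_zone_fraction must lie in (0, 1)")
  }
  structure(list(side = side, center_zone_fraction = center_zone_fraction,
                 session_length = session_length),
            class = "open_field_config")
}

#' Transform a trajectory between room and arena reference frames
#'
#' The arena floor rotates by `theta(t) = 2*pi*t/rotation_period` (sign
#' set by `rotation_sign`); arena coordinates map to room coordinates by
#' rotation through `+theta(t)` and back by `-theta(t)`. The transform
#' preserves radial distance exactly and round-trips to identity.
#'
#' @param traj A [trajectory()] centred on the arena centre.
#' @param arena An [arena_config()].
#' @param target `"room"` or `"arena"`.
#' @return The transformed [trajectory()] (a warning and no-op if the
#'   trajectory is already in the target frame).
#' @export
transform_frame <- function(traj, arena, target = c("room", "arena")) {
  target <- match.arg(target)
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena_config"))
  if (traj_frame(traj) == target) {
    warning("trajectory is already in the ", target, " frame")
    return(traj)
  }
  s <- if (arena$rotation_sign == "ccw") 1 else -1
  th <- s * 2 * pi * traj$t / arena$rotation_period
  if (target == "arena") th <- -th          # room -> arena: unrotate
  trajectory(traj$t,
             traj$x * cos(th) - traj$y * sin(th),
             traj$x * sin(th) + traj$y * cos(th),
             frame = target,
             likelihood = traj[["likelihood"]])
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean steps after optional running-median smoothing of the
#' coordinates; steps shorter than `jitter_floor` are ignored, which
#' suppresses apparent distance from tracker jitter around a stationary
#' animal.
#'
#' @param traj A [trajectory()] with at least 2 samples.
#' @param smooth_win Odd running-median window in samples (1 = no
#'   smoothing, the default).
#' @param jitter_floor Minimal step in cm that counts as movement
#'   (default 0).
#' @return Path length in cm.
#' @export
path_length <- function(traj, smooth_win = 1, jitter_floor = 0) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj) >= 2)
  x <- traj$x; y <- traj$y
  if (smooth_win > 1) {
    x <- as.numeric(stats::runmed(x, smooth_win))
    y <- as.numeric(stats::runmed(y, smooth_win))
  }
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  sum(steps[steps >= jitter_floor])
}

# per-sample dwell times: each sample owns the interval to the next one;
# the last sample gets the median interval
sample_dt <- function(t) {
  if (length(t) < 2) return(rep(0, length(t)))
  c(diff(t), median(diff(t)))
}

#' Time spent in the centre zone of the open field
#'
#' The centre zone is the concentric square of area
#' `center_zone_fraction * side^2` (side `sqrt(fraction) * side`), with
#' the box centred on the origin.
#'
#' @param traj A room-frame [trajectory()] inside the box.
#' @param cfg An [open_field_config()].
#' @return Time in the centre zone, in seconds.
#' @export
time_in_center <- function(traj, cfg) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "open_field_config"))
  half <- cfg$side * sqrt(cfg$center_zone_fraction) / 2
  inside <- abs(traj$x) <= half & abs(traj$y) <= half
  sum(sample_dt(traj$t)[inside])
}

#' Detect entrances into the room-frame avoidance sector
#'
#' An entrance is a maximal interval during which the room-frame azimuth
#' lies within `sector_center +/- sector_halfwidth`. Consecutive
#' entrances separated by less than `min_outside` seconds are merged
#' (default 0: every sector exit ends an entrance).
#'
#' @param traj A room-frame [trajectory()].
#' @param arena An [arena_config()].
#' @param min_outside Hysteresis in seconds (default 0).
#' @return A tibble with columns `enter`, `exit`, `dwell` (seconds), one
#'   row per entrance.
#' @export
detect_entrances <- function(traj, arena, min_outside = 0) {
  stopifnot(inherits(traj, "trajectory"), inherits(arena, "arena_config"))
  if (traj_frame(traj) != "room") {
    stop("entrance detection needs a room-frame trajectory; ",
         "use transform_frame() first")
  }
  az <- atan2(traj$y, traj$x) * 180 / pi
  inside <- abs(ang_diff_deg(az, arena$sector_center)) <=
    arena$sector_halfwidth
  if (!any(inside)) {
    return(tibble::tibble(enter = numeric(0), exit = numeric(0),
                          dwell = numeric(0)))
  }
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- sample_dt(traj$t)
  in_runs <- which(r$values)
  enter <- traj$t[starts[in_runs]]
  exit <- ifelse(ends[in_runs] < nrow(traj),
                 traj$t[pmin(ends[in_runs] + 1L, nrow(traj))],
                 traj$t[ends[in_runs]] + dt[ends[in_runs]])
  # merge entrances separated by less than min_outside
  if (min_outside > 0 && length(enter) > 1) {
    keep_e <- enter[1]; out_e <- numeric(0); out_x <- numeric(0)
    cur_exit <- exit[1]
    for (i in seq_along(enter)[-1]) {
      if (enter[i] - cur_exit < min_outside) {
        cur_exit <- exit[i]
      } else {
        out_e <- c(out_e, keep_e); out_x <- c(out_x, cur_exit)
        keep_e <- enter[i]; cur_exit <- exit[i]
      }
    }
    enter <- c(out_e, keep_e); exit <- c(out_x, cur_exit)
  }
  tibble::tibble(enter = enter, exit = exit, dwell = exit - enter)
}

#' Shock schedule from entrance intervals
#'
#' One shock at each entrance onset, then one every `shock_interval`
#' seconds of continuous occupancy: a dwell of `d` seconds yields the
#' number of `k >= 0` with `k * shock_interval < d` shocks.
#'
#' @param entrances Entrance table from [detect_entrances()].
#' @param arena An [arena_config()].
#' @return A tibble with columns `entrance` (index) and `t` (shock time,
#'   seconds); the shock count is `nrow()` of the result.
#' @export
count_shocks <- function(entrances, arena) {
  stopifnot(inherits(arena, "arena_config"))
  iv <- arena$shock_interval
  if (!nrow(entrances)) {
    return(tibble::tibble(entrance = integer(0), t = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(entrances)), function(i) {
    d <- entrances$dwell[i]
    nk <- floor(d / iv - 1e-9) + 1L       # number of k >= 0 with k*iv < d
    tibble::tibble(entrance = i,
                   t = entrances$enter[i] + (seq_len(nk) - 1L) * iv)
  })
  do.call(rbind, rows)
}

#' Per-bin behavioral metric
#'
#' Computes a metric per half-open time bin `[k*bin_s, (k+1)*bin_s)`.
#' `bin_s` must divide the session within one sample interval. Binned
#' distances sum to the total path length (each step is attributed to the
#' bin of its starting sample).
#'
#' @param traj A [trajectory()] (room frame for sector metrics).
#' @param bin_s Bin width in seconds.
#' @param metric One of `"distance"`, `"entrances"`, `"shocks"`,
#'   `"center_time"`.
#' @param arena An [arena_config()] (needed for `entrances`/`shocks`).
#' @param cfg An [open_field_config()] (needed for `center_time`).
#' @param ... Passed to [path_length()] (`smooth_win`, `jitter_floor`) or
#'   [detect_entrances()] (`min_outside`).
#' @return A tibble with columns `bin_start`, `bin_end`, `value`.
#' @export
bin_metric <- function(traj, bin_s,
                       metric = c("distance", "entrances", "shocks",
                                  "center_time"),
                       arena = NULL, cfg = NULL, ...) {
  metric <- match.arg(metric)
  stopifnot(inherits(traj, "trajectory"), bin_s > 0)
  t0 <- traj$t[1]
  session <- traj$t[nrow(traj)] - t0
  dt_med <- median(diff(traj$t))
  n_bins <- round(session / bin_s)
  if (abs(session - n_bins * bin_s) > dt_med) {
    stop("bin width ", bin_s, " s does not divide the ", session,
         " s session within one sample")
  }
  edges <- t0 + bin_s * (0:n_bins)
  bin_of <- function(tt) pmin(n_bins, findInterval(tt, edges,
                                                   rightmost.closed = FALSE))
  value <- numeric(n_bins)
  if (metric == "distance") {
    args <- list(...)
    jf <- if (!is.null(args$jitter_floor)) args$jitter_floor else 0
    x <- traj$x; y <- traj$y
    if (!is.null(args$smooth_win) && args$smooth_win > 1) {
      x <- as.numeric(stats::runmed(x, args$smooth_win))
      y <- as.numeric(stats::runmed(y, args$smooth_win))
    }
    steps <- sqrt(diff(x)^2 + diff(y)^2)
    steps[steps < jf] <- 0
    b <- bin_of(traj$t[-nrow(traj)])
    for (k in seq_len(n_bins)) value[k] <- sum(steps[b == k])
  } else if (metric %in% c("entrances", "shocks")) {
    if (is.null(arena)) stop("metric '", metric, "' needs an arena config")
    ent <- detect_entrances(traj, arena, ...)
    if (metric == "entrances") {
      b <- bin_of(ent$enter)
    } else {
      b <- bin_of(count_shocks(ent, arena)$t)
    }
    for (k in seq_len(n_bins)) value[k] <- sum(b == k)
  } else {
    if (is.null(cfg)) stop("metric 'center_time' needs an open-field config")
    half <- cfg$side * sqrt(cfg$center_zone_fraction) / 2
    inside <- abs(traj$x) <= half & abs(traj$y) <= half
    dts <- sample_dt(traj$t)
    b <- bin_of(traj$t)
    for (k in seq_len(n_bins)) value[k] <- sum(dts[inside & b == k])
  }
  tibble::tibble(bin_start = edges[-length(edges)], bin_end = edges[-1],
                 value = value)
}
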