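#' Animal trajectory
#'
#' Timestamped positions in centimetres, in a declared reference frame:
#' `"room"` (laboratory-fixed) or `"arena"` (disc-fixed, rotating with the
#' carousel floor). Times must be strictly increasing; positions finite.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param x,y Positions in cm (arena/box centre at the origin).
#' @param frame `"room"` or `"arena"`.
#' @param likelihood Optional per-sample tracking confidence in `[0, 1]`.
#' @return An object of class `trajectory` (a tibble with attributes).
#' @export
trajectory <- function(t, x, y, frame = c("room", "arena"),
                       likelihood = NULL) {
  frame <- match.arg(frame)
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (length(t) && any(diff(t) <= 0)) {
    stop("trajectory timestamps must be strictly increasing")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("trajectory positions must be finite")
  }
  out <- tibble::tibble(t = as.numeric(t), x = as.numeric(x),
                        y = as.numeric(y))
  if (!is.null(likelihood)) out$likelihood <- as.numeric(likelihood)
  structure(out, frame = frame, class = c("trajectory", class(out)))
}

#' Reference frame of a trajectory
#' @param traj A [trajectory()].
#' @return `"room"` or `"arena"`.
#' @export
traj_frame <- function(traj) attr(traj, "frame")

#' Read a tracked trajectory from CSV
#'
#' Two dialects are accepted. `"plain"` expects columns `t, x, y`
#' (+ optional `likelihood`). `"dlc"` expects a DeepLabCut-style export:
#' three header rows (scorer / bodyparts / coords), a leading frame-index
#' column, and `x, y, likelihood` triplets per bodypart; frame indices are
#' converted to seconds with `fps`, and samples whose likelihood falls
#' below `likelihood_min` are replaced by linear interpolation from their
#' confident neighbours.
#'
#' @param path CSV file.
#' @param dialect `"plain"` or `"dlc"`.
#' @param frame Reference frame of the coordinates.
#' @param bodypart For `"dlc"`: which bodypart to extract (default: the
#'   first one in the file).
#' @param fps For `"dlc"`: camera frame rate used to convert frame index
#'   to seconds (default 30).
#' @param likelihood_min For `"dlc"`: confidence threshold below which a
#'   sample is interpolated (default 0.9).
#' @return A [trajectory()].
#' @export
read_tracking <- function(path, dialect = c("plain", "dlc"),
                          frame = c("room", "arena"), bodypart = NULL,
                          fps = 30, likelihood_min = 0.9) {
  dialect <- match.arg(dialect)
  frame <- match.arg(frame)
  if (!file.exists(path)) stop("no such file: ", path)

  if (dialect == "plain") {
    df <- read.csv(path)
    stopifnot(all(c("t", "x", "y") %in% names(df)))
    return(trajectory(df$t, df$x, df$y, frame = frame,
                      likelihood = df[["likelihood"]]))
  }

  hdr <- read.csv(path, header = FALSE, nrows = 3,
                  colClasses = "character")
  body <- read.csv(path, header = FALSE, skip = 3)
  parts <- as.character(hdr[2, -1])
  coords <- as.character(hdr[3, -1])
  if (is.null(bodypart)) bodypart <- parts[1]
  sel <- which(parts == bodypart)
  if (!length(sel)) stop("bodypart '", bodypart, "' not found in ", path)
  get_col <- function(cc) {
    i <- sel[coords[sel] == cc]
    if (!length(i)) stop("no '", cc, "' column for bodypart '", bodypart, "'")
    as.numeric(body[[i[1] + 1L]])
  }
  x <- get_col("x"); y <- get_col("y"); lik <- get_col("likelihood")
  t <- as.numeric(body[[1]]) / fps
  if (any(diff(t) <= 0)) stop("trajectory timestamps must be strictly increasing")
  interp_low <- function(v) {
    ok <- lik >= likelihood_min & is.finite(v)
    if (!any(ok)) stop("no sample of bodypart '", bodypart,
                       "' reaches likelihood ", likelihood_min)
    approx(t[ok], v[ok], xout = t, rule = 2)$y
  }
  trajectory(t, interp_low(x), interp_low(y), frame = frame,
             likelihood = lik)
}

#' Write a trajectory as plain tracking CSV
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path (columns `t, x, y` + optional `likelihood`).
#' @return `path`, invisibly.
#' @export
write_tracking <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
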