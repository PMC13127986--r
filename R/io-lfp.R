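#' Read an LFP recording from CSV or flat float32 binary plus JSON sidecar
#'
#' The interchange format is deliberately neutral: a data file that is
#' either a CSV (header row = channel ids, one column per channel, one row
#' per sample) or a flat little-endian float32 binary (sample-major, i.e.
#' channels interleaved per time point), together with a JSON sidecar
#' declaring at least the sampling rate and channel ids:
#' `{"fs": 2000, "channels": ["L", "R"], "dtype": "float32",
#'   "units": "uV", "t0": 0}`.
#' All sidecar fields are preserved in `meta`.
#'
#' @param path Data file (`.csv` or `.f32`).
#' @param sidecar JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return An [lfp_recording()].
#' @seealso [write_lfp()]
#' @export
read_lfp <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar does not declare fs")
  channels <- meta$channels
  if (is.null(channels)) stop("sidecar does not declare channels")
  channels <- as.character(channels)

  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path, check.names = FALSE)
    if (ncol(df) != length(channels)) {
      stop("sidecar declares ", length(channels), " channel(s) but ",
           path, " has ", ncol(df), " column(s)")
    }
    samples <- as.matrix(df)
  } else {
    raw <- readBin(path, what = "numeric", size = 4L, endian = "little",
                   n = file.info(path)$size / 4L)
    if (length(raw) %% length(channels) != 0L) {
      stop("binary length ", length(raw),
           " is not a multiple of the declared channel count ",
           length(channels))
    }
    samples <- matrix(raw, ncol = length(channels), byrow = TRUE)
  }
  lfp_recording(samples, fs = as.numeric(meta$fs), channel_ids = channels,
                t0 = if (is.null(meta$t0)) 0 else as.numeric(meta$t0),
                meta = meta)
}

#' Write an LFP recording to CSV or flat float32 binary plus JSON sidecar
#'
#' @param rec An [lfp_recording()].
#' @param path Output data file; extension `.csv` selects CSV, anything
#'   else flat little-endian float32.
#' @param sidecar JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(rec, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(rec, "lfp_recording"))
  csv <- grepl("\\.csv$", path, ignore.case = TRUE)
  if (csv) {
    # 17 significant digits so the decimal representation round-trips
    # to the identical double on read
    chr <- matrix(formatC(rec$samples, digits = 17, format = "g"),
                  ncol = ncol(rec$samples))
    con <- file(path, "w")
    writeLines(paste(sprintf('"%s"', rec$channel_ids), collapse = ","), con)
    writeLines(apply(chr, 1L, paste, collapse = ","), con)
    close(con)
  } else {
    # sample-major interleave; float32 round-trips exactly through readBin
    writeBin(as.numeric(t(rec$samples)), path, size = 4L, endian = "little")
  }
  side <- c(list(fs = rec$fs, channels = rec$channel_ids,
                 dtype = if (csv) "csv" else "float32",
                 units = "uV", t0 = rec$t0),
            rec$meta[setdiff(names(rec$meta),
                             c("fs", "channels", "dtype", "units", "t0"))])
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
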