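#' Per-animal session analysis
#'
#' End-to-end electrophysiology analysis for one animal: line-noise
#' removal, per-window Welch band power, percent-of-baseline change, and
#' theta-gamma phase-locking values, with per-animal values formed as the
#' arithmetic mean over valid electrodes (the two-electrode averaging
#' rule).
#'
#' Input is either a continuous recording plus a [session_timeline()]
#' (windows are extracted by label, with the timeline's baseline window
#' as reference) or pre-extracted `baseline` / `post` epoch recordings.
#'
#' @param recording An [lfp_recording()] covering the whole session
#'   (with `timeline`), or `NULL` when passing epochs directly.
#' @param timeline A [session_timeline()] (with `recording`).
#' @param baseline,post Pre-extracted epoch [lfp_recording()]s
#'   (alternative input form).
#' @param animal_id Animal label carried into the output.
#' @param bands Named list with elements `theta`, `low_gamma`,
#'   `high_gamma` (defaults: the canonical bands).
#' @param notch Named list of [remove_line_noise()] arguments, or `NULL`
#'   to skip line-noise removal.
#' @param seg_len Welch segment length in seconds (default 2).
#' @param margin_s PAC edge margin in seconds (default 1).
#' @param order Butterworth order for PAC band isolation (default 4).
#' @return A tibble with columns `animal`, `window`, `metric`, `value`.
#'   Metrics: `psd_low_gamma`, `psd_high_gamma` (uV^2/Hz, every window),
#'   `pct_low_gamma`, `pct_high_gamma` (percent of baseline, non-baseline
#'   windows), `plv_theta_low`, `plv_theta_high` (every window).
#' @export
run_session <- function(recording = NULL, timeline = NULL,
                        baseline = NULL, post = NULL, animal_id = "animal",
                        bands = list(theta = band_theta(),
                                     low_gamma = band_low_gamma(),
                                     high_gamma = band_high_gamma()),
                        notch = list(base_freq = 50, q = 30),
                        seg_len = 2, margin_s = 1, order = 4) {
  if (!is.null(recording)) {
    stopifnot(inherits(recording, "lfp_recording"),
              inherits(timeline, "session_timeline"))
    labels <- timeline$windows$label
    epochs <- lapply(labels, function(l) extract_window(recording, timeline, l))
    names(epochs) <- labels
    base_label <- timeline$baseline_label
  } else {
    stopifnot(inherits(baseline, "lfp_recording"),
              inherits(post, "lfp_recording"))
    epochs <- list(baseline = baseline, post = post)
    base_label <- "baseline"
  }
  if (!is.null(notch)) {
    epochs <- lapply(epochs, function(e) {
      do.call(remove_line_noise, c(list(rec = e), notch))
    })
  }
  per_window <- lapply(names(epochs), function(lab) {
    e <- epochs[[lab]]
    psd <- welch_psd(e, seg_len = seg_len)
    bp_low <- band_power(psd, bands$low_gamma, window = lab)
    bp_high <- band_power(psd, bands$high_gamma, window = lab)
    plv_low <- plv_pac(e, phase_band = bands$theta,
                       amp_band = bands$low_gamma,
                       order = order, margin_s = margin_s)
    plv_high <- plv_pac(e, phase_band = bands$theta,
                        amp_band = bands$high_gamma,
                        order = order, margin_s = margin_s)
    list(label = lab, bp_low = bp_low, bp_high = bp_high,
         plv_low = plv_low, plv_high = plv_high)
  })
  names(per_window) <- names(epochs)
  base <- per_window[[base_label]]
  rows <- lapply(per_window, function(w) {
    out <- tibble::tibble(
      animal = animal_id, window = w$label,
      metric = c("psd_low_gamma", "psd_high_gamma",
                 "plv_theta_low", "plv_theta_high"),
      value = c(mean(w$bp_low$value), mean(w$bp_high$value),
                mean(w$plv_low$plv), mean(w$plv_high$plv)))
    if (w$label != base_label) {
      out <- rbind(out, tibble::tibble(
        animal = animal_id, window = w$label,
        metric = c("pct_low_gamma", "pct_high_gamma"),
        value = c(mean(percent_change(w$bp_low, base$bp_low)$percent),
                  mean(percent_change(w$bp_high, base$bp_high)$percent))))
    }
    out
  })
  do.call(rbind, unname(rows))
}

#' Cohort-level analysis: per-animal sessions plus group statistics
#'
#' Runs [run_session()] for every animal of a cohort (e.g. the output of
#' [generate_cohort()]), assembles a tidy group table, and applies the
#' normality-gated comparison chain ([compare_groups()]) to each
#' requested metric. A per-animal failure is caught and reported without
#' stopping the remaining animals; groups with fewer than 3 animals make
#' the statistics for that metric be skipped with a warning.
#'
#' @param cohort A list with an `animals` element as produced by
#'   [generate_cohort()]: each entry has `id`, `group`, `baseline`,
#'   `post`.
#' @param metrics Metrics (from the [run_session()] output) to test
#'   across groups, evaluated in the `post` window (percent-change
#'   metrics are baseline-referenced by construction).
#' @param alpha Significance level of the chain (default 0.05).
#' @param ... Passed to [run_session()].
#' @return A list with `table` (tidy per-animal tibble: `animal`,
#'   `group`, `window`, `metric`, `value`), `reports` (named list of
#'   `stat_report`s, one per metric), and `errors` (named list of
#'   per-animal error messages, empty on a clean run).
#' @export
run_cohort <- function(cohort,
                       metrics = c("pct_low_gamma", "pct_high_gamma",
                                   "plv_theta_low", "plv_theta_high"),
                       alpha = 0.05, ...) {
  stopifnot(is.list(cohort), !is.null(cohort$animals))
  groups_of <- vapply(cohort$animals, function(a) a$group, character(1))
  if (length(unique(groups_of)) < 2L) {
    stop("cohort statistics need at least 2 groups")
  }
  errors <- list()
  tabs <- list()
  for (a in cohort$animals) {
    res <- tryCatch(
      run_session(baseline = a$baseline, post = a$post,
                  animal_id = a$id, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[a$id]] <- conditionMessage(res)
    } else {
      res$group <- a$group
      tabs[[a$id]] <- res
    }
  }
  table <- do.call(rbind, unname(tabs))
  table <- table[, c("animal", "group", "window", "metric", "value")]
  reports <- list()
  for (m in metrics) {
    sl <- table[table$metric == m & table$window == "post", ]
    n_per <- table(sl$group)
    if (length(n_per) < 2L || any(n_per < 3L)) {
      warning("metric '", m, "': a group has fewer than 3 animals; ",
              "statistics skipped")
      next
    }
    reports[[m]] <- compare_groups(sl$value, sl$group, alpha = alpha)
  }
  list(table = table, reports = reports, errors = errors)
}
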