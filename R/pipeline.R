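#' Analysis configuration
#'
#' All tunable parameters of the track -> metrics -> nonlinear pipeline in
#' one echo-able list. Every field is stored verbatim in each run report so
#' that a report can be reproduced from its own parameter block.
#'
#' @param fps,um_per_px acquisition defaults (overridden per sample by a
#'   manifest).
#' @param block_size,search_radius,subpixel block-matching parameters.
#' @param min_prominence_frac,min_separation_s,label_rule peak detection.
#' @param tau `"auto"` (ACF 1/e rule) or an integer delay in samples.
#' @param m_values embedding dimensions for the correlation dimension.
#' @param bins,log_bins,min_region_len,theiler correlation-integral
#'   parameters.
#' @param variogram_tau_max largest variogram lag (`NULL`: N/4).
#' @return A `cardiodyn_config` list.
#' @export
cardiodyn_config <- function(fps = 100, um_per_px = 1,
                             block_size = 16L, search_radius = 7L,
                             subpixel = FALSE,
                             min_prominence_frac = 0.15,
                             min_separation_s = 0.1,
                             label_rule = "first",
                             tau = "auto", m_values = 2:12,
                             bins = 32L, log_bins = TRUE,
                             min_region_len = 8L, theiler = 0L,
                             variogram_tau_max = NULL) {
  structure(list(fps = fps, um_per_px = um_per_px, block_size = block_size,
                 search_radius = search_radius, subpixel = subpixel,
                 min_prominence_frac = min_prominence_frac,
                 min_separation_s = min_separation_s,
                 label_rule = label_rule, tau = tau, m_values = m_values,
                 bins = bins, log_bins = log_bins,
                 min_region_len = min_region_len, theiler = theiler,
                 variogram_tau_max = variogram_tau_max),
            class = "cardiodyn_config")
}

ms_or_na <- function(x) if (is.null(x)) list(mean = NA_real_, sd = NA_real_) else x

#' Run the full analysis on one recording
#'
#' Executes the applicable stages in order: motion tracking (skipped when the
#' input already is a waveform), peak detection and linear beat metrics,
#' variogram capacity dimension, and Grassberger-Procaccia correlation
#' dimension. Stage failures (e.g. degenerate constant waveforms) are
#' recorded as flags in the report rather than raised, so batch runs survive
#' dead samples. Deterministic given input and config.
#'
#' @param input a [motion_waveform()], [frame_sequence()], or a path
#'   (waveform CSV, or frame files for [read_frames()]).
#' @param config a [cardiodyn_config()].
#' @param sample_id label stored in the report.
#' @return A list of class `run_report`: `sample_id`, `input`, `n_samples`,
#'   `metrics`, `variogram`, `correlation`, `warnings`, `params`, `version`.
#' @export
run_single <- function(input, config = cardiodyn_config(),
                       sample_id = "sample") {
  stopifnot(inherits(config, "cardiodyn_config"))
  warns <- character(0)
  note <- function(w) warns <<- c(warns, w)
  src <- "waveform"
  if (is.character(input)) {
    if (length(input) == 1L && file.exists(input) &&
        grepl("\\.csv$", input, ignore.case = TRUE) &&
        is_waveform_csv(input)) {
      input <- read_waveform_csv(input)
    } else {
      input <- read_frames(input, fps = config$fps,
                           um_per_px = config$um_per_px)
    }
  }
  if (inherits(input, "frame_sequence")) {
    src <- "video"
    w <- track_video(input, block_size = config$block_size,
                     search_radius = config$search_radius,
                     subpixel = config$subpixel)
  } else {
    w <- as_waveform(input)
  }

  metrics <- withCallingHandlers(
    beat_metrics(w, detect_peaks(w,
                                 min_prominence_frac = config$min_prominence_frac,
                                 min_separation_s = config$min_separation_s,
                                 label_rule = config$label_rule)),
    warning = function(cnd) { note(conditionMessage(cnd))
                              invokeRestart("muffleWarning") })

  vg <- tryCatch(withCallingHandlers(
    capacity_dimension(variogram(w, tau_max = config$variogram_tau_max)),
    warning = function(cnd) { note(conditionMessage(cnd))
                              invokeRestart("muffleWarning") }),
    error = function(e) { note(conditionMessage(e)); NULL })

  cr <- tryCatch(withCallingHandlers(
    correlation_dimension(w, tau = config$tau, m_values = config$m_values,
                          bins = config$bins, log_bins = config$log_bins,
                          min_region_len = config$min_region_len,
                          theiler = config$theiler),
    warning = function(cnd) { note(conditionMessage(cnd))
                              invokeRestart("muffleWarning") }),
    error = function(e) { note(conditionMessage(e)); NULL })

  structure(list(
    sample_id = sample_id,
    input = src,
    n_samples = length(w$S),
    metrics = list(
      beat_rate_bpm = metrics$beat_rate_bpm,
      pp_interval_s = metrics$pp_interval_s,
      contraction_velocity_um_s = metrics$contraction_velocity_um_s,
      relaxation_velocity_um_s = metrics$relaxation_velocity_um_s,
      n_beats = metrics$n_beats,
      undefined = metrics$undefined),
    variogram = if (is.null(vg)) list(degenerate = TRUE) else list(
      P = null_na(vg$P), D_capacity = null_na(vg$D_capacity),
      D_capacity_mean = null_na(vg$D_capacity_mean),
      degenerate = vg$degenerate, clipped = vg$clipped),
    correlation = if (is.null(cr)) list(degenerate = TRUE) else list(
      tau = cr$tau, m_values = cr$m_values, D_m = cr$slopes,
      D_steady = cr$D_steady, plateau = cr$plateau,
      failed_m = cr$failed_m, degenerate = FALSE),
    warnings = warns,
    params = unclass(config),
    version = as.character(utils::packageVersion("cardiodyn"))),
    class = "run_report")
}

null_na <- function(x) if (is.null(x)) NA_real_ else x

is_waveform_csv <- function(path) {
  hd <- tryCatch(readLines(path, n = 1L), error = function(e) "")
  grepl("time_s", hd) && grepl("speed_um_per_s", hd)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (%s, %d samples)\n", x$sample_id, x$input,
              x$n_samples))
  cat(sprintf("  beat rate %.2f BPM | D_capacity_mean %.3f | D_steady %.3f\n",
              x$metrics$beat_rate_bpm$mean, x$variogram$D_capacity_mean,
              x$correlation$D_steady))
  invisible(x)
}

#' Read a batch manifest
#'
#' Delimited table (TSV/CSV, header required) with columns `path`,
#' `sample_id`, `group` and optionally `timepoint`, `fps`, `um_per_px`.
#'
#' @param path manifest file.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(data.table::fread(path))
  need <- c("path", "sample_id", "group")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m
}

#' Run a batch of recordings with group summaries
#'
#' Applies [run_single()] to every manifest row and summarises each linear
#' and nonlinear metric as mean +/- sd per group, and per group x timepoint
#' when a `timepoint` column is present (the two grouping axes of
#' sample-vs-time designs). Singleton groups report `sd = NA`. Summaries are
#' plain recomputations from the per-sample values -- no weighting.
#'
#' @param manifest data.frame (see [read_manifest()]) or path to one.
#' @param config a [cardiodyn_config()].
#' @return List of class `batch_report`: `reports` (per sample),
#'   `samples` (per-sample metric table), `by_group`, and `by_group_timepoint`
#'   (when applicable).
#' @export
run_batch <- function(manifest, config = cardiodyn_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!nrow(manifest)) stop("empty manifest")
  reports <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cfg <- config
    if ("fps" %in% names(manifest) && is.finite(manifest$fps[i]))
      cfg$fps <- manifest$fps[i]
    if ("um_per_px" %in% names(manifest) && is.finite(manifest$um_per_px[i]))
      cfg$um_per_px <- manifest$um_per_px[i]
    reports[[i]] <- run_single(manifest$path[i], cfg,
                               sample_id = manifest$sample_id[i])
  }
  samples <- data.table::rbindlist(lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.table::data.table(
      sample_id = r$sample_id,
      group = manifest$group[i],
      timepoint = if ("timepoint" %in% names(manifest))
        manifest$timepoint[i] else NA,
      beat_rate_bpm = r$metrics$beat_rate_bpm$mean,
      pp_interval_s = r$metrics$pp_interval_s$mean,
      contraction_velocity_um_s = r$metrics$contraction_velocity_um_s$mean,
      relaxation_velocity_um_s = r$metrics$relaxation_velocity_um_s$mean,
      D_capacity = null_na(r$variogram$D_capacity),
      D_capacity_mean = null_na(r$variogram$D_capacity_mean),
      D_steady = if (is.null(r$correlation$D_steady)) NA_real_
                 else r$correlation$D_steady)
  }))
  metric_cols <- setdiff(names(samples), c("sample_id", "group", "timepoint"))
  summarise <- function(by) {
    samples[, unlist(lapply(.SD, function(x)
      list(mean = mean(x, na.rm = TRUE),
           sd = if (sum(is.finite(x)) > 1) stats::sd(x, na.rm = TRUE)
                else NA_real_)), recursive = FALSE),
      by = by, .SDcols = metric_cols]
  }
  by_group <- summarise("group")
  by_gt <- if (!all(is.na(samples$timepoint)))
    summarise(c("group", "timepoint")) else NULL
  structure(list(reports = reports, samples = samples, by_group = by_group,
                 by_group_timepoint = by_gt),
            class = "batch_report")
}

#' Serialise a report to JSON
#'
#' @param report a `run_report` or `batch_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (inherits(x, "data.table") || inherits(x, "data.frame"))
    return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}
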