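#' Contraction-motion waveform
#'
#' The central container of the package: a uniformly sampled scalar time
#' series of mean tissue motion speed (micrometres per second), as produced by
#' motion tracking of a beating cardiomyocyte video or by the synthetic
#' generators. Beating tissue shows two speed peaks per beat -- one for the
#' contraction stroke and one for the relaxation stroke.
#'
#' @param S numeric vector of motion speeds (um/s), length >= 2, finite.
#' @param fps sampling rate in frames per second (> 0).
#' @param t optional time grid in seconds; defaults to `(0:(N-1))/fps`.
#' @param meta named list of provenance (source file or simulator parameters).
#' @return An object of class `motion_waveform`: a list with elements `t`,
#'   `S`, `fps` and `meta`.
#' @examples
#' w <- motion_waveform(abs(sin(2 * pi * (0:199) / 50)), fps = 100)
#' w
#' @export
motion_waveform <- function(S, fps, t = NULL, meta = list()) {
  S <- as.numeric(S)
  if (length(S) < 2L) stop("motion waveform needs at least 2 samples")
  if (!all(is.finite(S))) stop("motion waveform values must be finite")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a finite positive scalar")
  if (is.null(t)) t <- (seq_along(S) - 1) / fps
  if (length(t) != length(S)) stop("'t' and 'S' must have equal length")
  structure(list(t = as.numeric(t), S = S, fps = as.numeric(fps),
                 meta = meta),
            class = "motion_waveform")
}

#' @export
print.motion_waveform <- function(x, ...) {
  cat(sprintf(
    "<motion_waveform> %d samples @ %g fps (%.2f s), speed %.2f-%.2f um/s\n",
    length(x$S), x$fps, length(x$S) / x$fps, min(x$S), max(x$S)))
  invisible(x)
}

#' @export
length.motion_waveform <- function(x) length(x$S)

as_waveform <- function(x) {
  if (inherits(x, "motion_waveform")) return(x)
  stop("expected a 'motion_waveform'")
}

#' Read / write a waveform CSV
#'
#' CSV layout: header `time_s,speed_um_per_s`, one row per frame. On read the
#' frame rate is inferred from the median time step unless given.
#'
#' @param path file path.
#' @param fps optional frame rate; inferred from the time column when `NULL`.
#' @return `read_waveform_csv()` returns a [motion_waveform()];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path, fps = NULL) {
  d <- data.table::fread(path)
  need <- c("time_s", "speed_um_per_s")
  if (!all(need %in% names(d)))
    stop("waveform CSV must have columns time_s, speed_um_per_s")
  if (is.null(fps)) {
    dt <- stats::median(diff(d$time_s))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer fps from time column")
    fps <- 1 / dt
  }
  motion_waveform(d$speed_um_per_s, fps = fps, t = d$time_s,
                  meta = list(source = path))
}

#' @rdname read_waveform_csv
#' @param w a [motion_waveform()].
#' @export
write_waveform_csv <- function(w, path) {
  w <- as_waveform(w)
  data.table::fwrite(data.table::data.table(time_s = w$t,
                                            speed_um_per_s = w$S), path)
  invisible(path)
}
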