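#' Detect and label contraction/relaxation peaks
#'
#' Local maxima of the motion waveform are filtered by topographic
#' prominence (at least `min_prominence_frac` of the signal range) and by a
#' minimum pairwise separation, higher peaks winning. Retained peaks are
#' grouped into beat cycles by splitting the inter-peak gaps into
#' within-beat and between-beat classes (1-D 2-means on the gap lengths,
#' applied when the gap spread is bimodal, i.e. `max/min > 1.8`); within
#' each cycle peaks are labelled alternately, the first one `contraction`
#' (the contraction stroke precedes relaxation within a beat). With
#' `label_rule = "larger"` the taller peak of each cycle is labelled
#' `contraction` instead.
#'
#' @param w a [motion_waveform()] (N >= 3).
#' @param min_prominence_frac prominence threshold as a fraction of
#'   `max(S) - min(S)`, in (0, 1).
#' @param min_separation_s minimum peak separation in seconds.
#' @param label_rule `"first"` (default) or `"larger"`.
#' @return A data.frame of class `peak_list` with columns `index`, `time_s`,
#'   `speed_um_per_s`, `beat`, `label`; attribute `no_peaks` is TRUE when
#'   nothing qualified (returned empty with a warning, not an error).
#' @export
detect_peaks <- function(w, min_prominence_frac = 0.15,
                         min_separation_s = 0.1,
                         label_rule = c("first", "larger")) {
  w <- as_waveform(w)
  label_rule <- match.arg(label_rule)
  if (length(w$S) < 3) stop("peak detection needs at least 3 samples")
  if (min_prominence_frac <= 0 || min_prominence_frac >= 1)
    stop("'min_prominence_frac' must be in (0, 1)")
  S <- w$S
  empty <- function() {
    warning("no peaks found")
    structure(data.frame(index = integer(), time_s = numeric(),
                         speed_um_per_s = numeric(), beat = integer(),
                         label = character()),
              no_peaks = TRUE, class = c("peak_list", "data.frame"))
  }
  rng <- max(S) - min(S)
  if (rng == 0) return(empty())
  cand <- local_maxima(S)
  if (!length(cand)) return(empty())
  prom <- vapply(cand, function(i) prominence(S, i), numeric(1))
  cand <- cand[prom >= min_prominence_frac * rng]
  if (!length(cand)) return(empty())
  # greedy separation filter, higher peaks first (earlier wins ties)
  ord <- cand[order(-S[cand], cand)]
  kept <- integer(0)
  min_sep <- min_separation_s * w$fps
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  kept <- sort(kept)
  beat <- assign_beats(w$t[kept])
  lab <- character(length(kept))
  for (b in unique(beat)) {
    idx <- which(beat == b)
    if (label_rule == "larger" && length(idx) >= 2) {
      lab[idx] <- "relaxation"
      lab[idx[which.max(S[kept[idx]])]] <- "contraction"
    } else {
      lab[idx] <- rep(c("contraction", "relaxation"),
                      length.out = length(idx))
    }
  }
  structure(data.frame(index = kept, time_s = w$t[kept],
                       speed_um_per_s = S[kept], beat = beat, label = lab,
                       stringsAsFactors = FALSE),
            no_peaks = FALSE, class = c("peak_list", "data.frame"))
}

# Strict local maxima; plateaus contribute their first index.
local_maxima <- function(S) {
  n <- length(S)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (S[i] > S[i - 1L]) {
      j <- i
      while (j < n && S[j + 1L] == S[i]) j <- j + 1L
      if (j < n && S[j + 1L] < S[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Topographic prominence: height above the higher of the two key saddles
# (lowest point between the peak and the nearest higher ground on each side,
# or the boundary minimum when no higher ground exists).
prominence <- function(S, i) {
  n <- length(S)
  left <- if (i == 1L) S[i] else {
    higher <- which(S[1:(i - 1L)] > S[i])
    lo <- if (length(higher)) (max(higher) + 1L) else 1L
    min(S[lo:i])
  }
  right <- if (i == n) S[i] else {
    higher <- which(S[(i + 1L):n] > S[i])
    hi <- if (length(higher)) (i + min(higher) - 1L) else n
    min(S[i:hi])
  }
  S[i] - max(left, right)
}

# Split peak times into beat cycles from the inter-peak gap structure.
assign_beats <- function(times) {
  n <- length(times)
  if (n <= 1L) return(rep(1L, n))
  g <- diff(times)
  if (max(g) / min(g) <= 1.8) return(seq_len(n)) # unimodal: one peak per beat
  lo <- min(g); hi <- max(g)
  for (it in 1:50) { # 1-D 2-means on gap lengths
    assign_hi <- abs(g - hi) < abs(g - lo)
    lo2 <- mean(g[!assign_hi]); hi2 <- mean(g[assign_hi])
    if (isTRUE(all.equal(c(lo2, hi2), c(lo, hi)))) break
    lo <- lo2; hi <- hi2
  }
  thr <- (lo + hi) / 2
  cumsum(c(TRUE, g > thr))
}

#' Linear beat metrics
#'
#' Beat rate, peak-to-peak (PP) interval and stroke velocities from a
#' labelled peak list. PP intervals are successive contraction-peak time
#' differences; the per-interval rate is `60 / PP` and the reported beat
#' rate its mean +/- sd. Contraction (relaxation) velocity is the mean +/-
#' sd of the waveform value at the corresponding peaks. A trailing
#' contraction without relaxation still counts for rate/PP but not for the
#' relaxation statistics.
#'
#' @param w a [motion_waveform()].
#' @param peaks a [detect_peaks()] result (computed from `w` when omitted).
#' @return Object of class `beat_metrics`: `beat_rate_bpm`, `pp_interval_s`,
#'   `contraction_velocity_um_s`, `relaxation_velocity_um_s` (each a list
#'   `mean`/`sd`), `n_beats`, `peaks`, and `undefined` (TRUE when fewer than
#'   2 contraction peaks exist; rate/PP are then NaN, not an error).
#' @export
beat_metrics <- function(w, peaks = NULL) {
  w <- as_waveform(w)
  if (is.null(peaks)) peaks <- detect_peaks(w)
  ct <- peaks$time_s[peaks$label == "contraction"]
  cv <- peaks$speed_um_per_s[peaks$label == "contraction"]
  rv <- peaks$speed_um_per_s[peaks$label == "relaxation"]
  ms <- function(x) {
    if (!length(x)) return(list(mean = NaN, sd = NaN))
    list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  undefined <- length(ct) < 2
  pp <- if (undefined) numeric(0) else diff(ct)
  structure(list(
    beat_rate_bpm = ms(60 / pp),
    pp_interval_s = ms(pp),
    contraction_velocity_um_s = ms(cv),
    relaxation_velocity_um_s = ms(rv),
    n_beats = length(ct),
    peaks = peaks,
    undefined = undefined), class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  f <- function(l) sprintf("%.3f +/- %s", l$mean,
                           ifelse(is.na(l$sd), "NA", sprintf("%.3f", l$sd)))
  cat("<beat_metrics>",
      if (x$undefined) "[undefined: < 2 contraction peaks]", "\n")
  cat("  beat rate (BPM):      ", f(x$beat_rate_bpm), "\n")
  cat("  PP interval (s):      ", f(x$pp_interval_s), "\n")
  cat("  contraction v (um/s): ", f(x$contraction_velocity_um_s), "\n")
  cat("  relaxation v (um/s):  ", f(x$relaxation_velocity_um_s), "\n")
  invisible(x)
}
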