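#' Beat-simulation specification
#'
#' Parameters of the synthetic contraction-motion generator. Each beat is a
#' Gaussian contraction speed pulse followed by a Gaussian relaxation pulse
#' offset by `relax_offset_frac` of the beat period, mimicking the twin-peak
#' shape of tracked cardiomyocyte motion. Defaults correspond to a typical
#' spontaneously beating hiPSC-CM cluster: 60 BPM, 20 s recorded at 100 fps,
#' contraction speed 20 um/s, relaxation 15 um/s (published speeds run roughly
#' 12-25 um/s and rates 30-120 BPM).
#'
#' Arrhythmia-like aberrations are phenomenological: whole beats dropped with
#' probability `missed_beat_prob`, per-beat amplitude jitter uniform in
#' `+/- amp_jitter_frac`, and spurious narrow spikes inserted with per-beat
#' probability `spike_prob`.
#'
#' @param bpm beat rate (beats/minute); `period_s` may be given instead.
#' @param period_s inter-beat period in seconds (overrides `bpm`).
#' @param duration_s record length (s).
#' @param fps sampling rate (frames/s).
#' @param contraction_amp,relaxation_amp peak speeds (um/s), > 0.
#' @param peak_width_s Gaussian pulse sigma (s).
#' @param relax_offset_frac relaxation-pulse delay as a fraction of the period.
#' @param noise_sd additive Gaussian noise sigma (um/s).
#' @param missed_beat_prob,spike_prob,amp_jitter_frac aberration parameters,
#'   probabilities in `[0, 1]`.
#' @param seed RNG seed (noise and aberrations are fully reproducible).
#' @return A `beat_sim_spec` list.
#' @export
beat_sim_spec <- function(bpm = 60, period_s = NULL, duration_s = 20,
                          fps = 100, contraction_amp = 20,
                          relaxation_amp = 15, peak_width_s = 0.03,
                          relax_offset_frac = 0.3, noise_sd = 0,
                          missed_beat_prob = 0, spike_prob = 0,
                          amp_jitter_frac = 0, seed = 1L) {
  if (is.null(period_s)) period_s <- 60 / bpm
  spec <- list(period_s = period_s, bpm = 60 / period_s,
               duration_s = duration_s, fps = fps,
               contraction_amp = contraction_amp,
               relaxation_amp = relaxation_amp,
               peak_width_s = peak_width_s,
               relax_offset_frac = relax_offset_frac,
               noise_sd = noise_sd, missed_beat_prob = missed_beat_prob,
               spike_prob = spike_prob, amp_jitter_frac = amp_jitter_frac,
               seed = as.integer(seed))
  with(spec, {
    if (contraction_amp <= 0 || relaxation_amp <= 0)
      stop("pulse amplitudes must be positive")
    for (p in c(missed_beat_prob, spike_prob))
      if (p < 0 || p > 1) stop("aberration probabilities must be in [0, 1]")
    if (fps * duration_s < 2 * fps * period_s)
      stop("record must cover at least 2 beats")
    # pulses must not merge: the tightest gap is the contraction->relaxation
    # offset inside a beat
    if (4 * peak_width_s >= relax_offset_frac * period_s)
      stop("peak_width_s too large for this beat rate: pulses would overlap")
  })
  class(spec) <- "beat_sim_spec"
  spec
}

gauss_pulse <- function(t, center, amp, sigma)
  amp * exp(-(t - center)^2 / (2 * sigma^2))

#' Simulate a contraction-motion waveform with known ground truth
#'
#' Deterministic under `spec$seed`; the exact peak times, amplitudes and
#' labels actually used (after aberrations) are returned alongside the
#' waveform so downstream peak detection can be validated against truth.
#'
#' @param spec a [beat_sim_spec()].
#' @return A list of class `sim_waveform`: `waveform` ([motion_waveform()]),
#'   `truth` (data.frame `beat`, `label`, `time_s`, `amp_um_s`), `spec`.
#' @examples
#' sim <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 10))
#' nrow(sim$truth)  # 10 beats x 2 peaks
#' @export
simulate_waveform <- function(spec) {
  stopifnot(inherits(spec, "beat_sim_spec"))
  N <- round(spec$fps * spec$duration_s)
  t <- (seq_len(N) - 1) / spec$fps
  T_ <- spec$period_s
  K <- floor(spec$duration_s / T_)
  c_times <- (seq_len(K) - 1) * T_ + 0.25 * T_
  r_times <- c_times + spec$relax_offset_frac * T_
  set.seed(spec$seed)
  miss <- stats::runif(K) < spec$missed_beat_prob
  jit_c <- 1 + spec$amp_jitter_frac * stats::runif(K, -1, 1)
  jit_r <- 1 + spec$amp_jitter_frac * stats::runif(K, -1, 1)
  spike <- stats::runif(K) < spec$spike_prob
  spike_t <- (seq_len(K) - 1) * T_ + stats::runif(K) * T_
  noise <- if (spec$noise_sd > 0) stats::rnorm(N, 0, spec$noise_sd) else 0
  S <- numeric(N)
  truth <- vector("list", K)
  for (k in seq_len(K)) {
    if (miss[k]) next
    ac <- spec$contraction_amp * jit_c[k]
    ar <- spec$relaxation_amp * jit_r[k]
    S <- S + gauss_pulse(t, c_times[k], ac, spec$peak_width_s) +
      gauss_pulse(t, r_times[k], ar, spec$peak_width_s)
    truth[[k]] <- data.frame(beat = k, label = c("contraction", "relaxation"),
                             time_s = c(c_times[k], r_times[k]),
                             amp_um_s = c(ac, ar))
    if (spike[k])
      S <- S + gauss_pulse(t, spike_t[k], 1.5 * spec$contraction_amp,
                           spec$peak_width_s / 2)
  }
  S <- pmax(S + noise, 0)
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(beat = integer(), label = character(),
                        time_s = numeric(), amp_um_s = numeric())
  structure(list(
    waveform = motion_waveform(S, fps = spec$fps, t = t,
                               meta = c(list(generator = "simulate_waveform"),
                                        unclass(spec))),
    truth = truth, spec = spec), class = "sim_waveform")
}

#' Fractional Brownian motion by Davies-Harte circulant embedding
#'
#' Generates fractional Gaussian noise with the exact target autocovariance
#' via circulant embedding of the covariance matrix, then cumulates it into
#' fBm. Used as the analytic oracle for the variogram capacity-dimension
#' estimator: an fBm trace with Hurst exponent H has semivariogram
#' `gamma(tau) ~ tau^(2H)`, hence capacity dimension `2 - H`.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n series length (>= 256).
#' @param seed RNG seed.
#' @return Numeric vector of length `n` (the fBm trace, unit-variance
#'   increments at unit spacing).
#' @export
simulate_fbm <- function(H, n, seed = 1L) {
  if (!is.finite(H) || H <= 0 || H >= 1)
    stop("'H' must be strictly inside (0, 1)")
  if (n < 256) stop("'n' must be at least 256")
  set.seed(seed)
  acov <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                               abs(k - 1)^(2 * H))
  cvec <- c(acov(0:n), acov((n - 1):1)) # circulant first row, length 2n
  lam <- Re(stats::fft(cvec))
  lam[lam < 0] <- 0 # tiny negative rounding eigenvalues
  m2 <- 2 * n
  V <- complex(length.out = m2)
  V[1] <- stats::rnorm(1)
  V[n + 1] <- stats::rnorm(1)
  z1 <- stats::rnorm(n - 1)
  z2 <- stats::rnorm(n - 1)
  V[2:n] <- (z1 + 1i * z2) / sqrt(2)
  V[m2:(n + 2)] <- Conj(V[2:n])
  fgn <- Re(stats::fft(sqrt(lam) * V))[1:n] / sqrt(m2)
  cumsum(fgn)
}

#' Lorenz-system x-coordinate series
#'
#' Fixed-step 4th-order Runge-Kutta integration of the Lorenz system
#' (sigma = 10, rho = 28, beta = 8/3); the canonical low-dimensional chaotic
#' oracle for the correlation-dimension estimator (D2 ~ 2.05).
#'
#' @param n number of samples returned (>= 5000).
#' @param dt integration step, in `[0.005, 0.05]`.
#' @param init initial state (length-3 numeric).
#' @param transient leading steps discarded.
#' @param seed optional; when given, the initial state is jittered
#'   reproducibly so independent realisations can be drawn.
#' @return Numeric vector: the x-coordinate after the transient.
#' @export
simulate_lorenz <- function(n, dt = 0.02, init = c(1, 1, 1),
                            transient = 1000L, seed = NULL) {
  if (n < 5000) stop("'n' must be at least 5000")
  if (dt < 0.005 || dt > 0.05) stop("'dt' must be in [0.005, 0.05]")
  if (!is.null(seed)) {
    set.seed(seed)
    init <- init + stats::runif(3, -0.5, 0.5)
  }
  f <- function(s) c(10 * (s[2] - s[1]),
                     s[1] * (28 - s[3]) - s[2],
                     s[1] * s[2] - (8 / 3) * s[3])
  s <- init
  out <- numeric(n)
  for (i in seq_len(n + transient)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > transient) out[i - transient] <- s[1]
  }
  out
}

gaussian_blur_fft <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  gy <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = sigma)
  gx <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = sigma)
  ker <- outer(gy, gx)
  ker <- ker / sum(ker)
  Re(stats::fft(stats::fft(m) * stats::fft(ker), inverse = TRUE)) / (nr * nc)
}

#' Render a synthetic beating video with known motion
#'
#' A band-limited random texture (Gaussian noise blurred to a few pixels of
#' correlation length, so macroblocks are uniquely matchable) is translated
#' rigidly according to an integer position schedule; the per-frame-pair
#' displacements are returned as ground truth for validating the block
#' matcher.
#'
#' @param positions n_frames x 2 matrix of (row, col) window positions in
#'   pixels; rounded to integers. Must satisfy
#'   `max(abs(positions)) <= min(frame_shape)/4`.
#' @param frame_shape frame dimensions (rows, cols), each >= 64.
#' @param texture_seed seed for the texture.
#' @param fps,um_per_px acquisition metadata attached to the sequence.
#' @param smooth_px texture correlation length (px).
#' @return List of class `rendered_video`: `seq` ([frame_sequence()]),
#'   `positions` (integer matrix) and `displacements`
#'   ((n_frames-1) x 2 matrix, row k = motion from frame k to k+1).
#' @export
render_video <- function(positions, frame_shape = c(96, 96), texture_seed = 1L,
                         fps = 100, um_per_px = 1, smooth_px = 4) {
  positions <- round(as.matrix(positions))
  if (ncol(positions) != 2L) stop("'positions' must be an n x 2 matrix")
  if (any(frame_shape < 64)) stop("'frame_shape' must be at least 64 x 64")
  if (max(abs(positions)) > min(frame_shape) / 4)
    stop("displacement exceeds frame_shape/4")
  marg <- max(abs(positions)) + 1L
  H <- frame_shape[1]; W <- frame_shape[2]
  set.seed(texture_seed)
  canvas <- matrix(stats::rnorm((H + 2 * marg) * (W + 2 * marg)),
                   nrow = H + 2 * marg)
  canvas <- gaussian_blur_fft(canvas, sigma = smooth_px / 2)
  frames <- lapply(seq_len(nrow(positions)), function(k) {
    # content moves BY positions[k, ]: crop window moves the opposite way
    canvas[(marg + 1:H) - positions[k, 1], (marg + 1:W) - positions[k, 2],
           drop = FALSE]
  })
  structure(list(
    seq = frame_sequence(frames, fps = fps, um_per_px = um_per_px),
    positions = positions,
    displacements = diff(positions)), class = "rendered_video")
}

#' Render a beating-tissue video from a beat specification
#'
#' Builds a signed tissue velocity (contraction stroke positive along the
#' column axis, relaxation stroke negative, with pulse areas matched so the
#' tissue returns to baseline each beat), integrates it to an integer pixel
#' position schedule, and renders it with [render_video()]. Defaults are
#' chosen so the per-frame displacement spans a few pixels (peak speed
#' `contraction_amp / (um_per_px * fps)` px/frame).
#'
#' @param spec a [beat_sim_spec()]; its `fps` is the video frame rate.
#' @param um_per_px pixel size of the rendered video.
#' @inheritParams render_video
#' @return List of class `beat_video`: `video` ([render_video()] output),
#'   `waveform_true` (analytic speed waveform, um/s),
#'   `waveform_quant` (speed waveform implied by the integer schedule --
#'   what a perfect tracker reports), `truth` (ground-truth peak table),
#'   `spec`.
#' @export
simulate_beat_video <- function(spec = beat_sim_spec(bpm = 60, duration_s = 8,
                                                     fps = 25,
                                                     contraction_amp = 24,
                                                     relaxation_amp = 16,
                                                     peak_width_s = 0.05),
                                um_per_px = 0.25, frame_shape = c(96, 96),
                                texture_seed = 1L, smooth_px = 4) {
  stopifnot(inherits(spec, "beat_sim_spec"))
  N <- round(spec$fps * spec$duration_s)
  t <- (seq_len(N) - 1) / spec$fps
  T_ <- spec$period_s
  K <- floor(spec$duration_s / T_)
  c_times <- (seq_len(K) - 1) * T_ + 0.25 * T_
  r_times <- c_times + spec$relax_offset_frac * T_
  sig_c <- spec$peak_width_s
  sig_r <- sig_c * spec$contraction_amp / spec$relaxation_amp # equal areas
  if (4 * sig_r >= (1 - spec$relax_offset_frac) * T_)
    stop("relaxation pulse too wide for this beat rate")
  v <- numeric(N) # signed velocity, um/s
  for (k in seq_len(K)) {
    v <- v + gauss_pulse(t, c_times[k], spec$contraction_amp, sig_c) -
      gauss_pulse(t, r_times[k], spec$relaxation_amp, sig_r)
  }
  pos_px <- round(cumsum(v) / spec$fps / um_per_px)
  positions <- cbind(0L, pos_px) # motion along the column (x) axis
  vid <- render_video(positions, frame_shape = frame_shape,
                      texture_seed = texture_seed, fps = spec$fps,
                      um_per_px = um_per_px, smooth_px = smooth_px)
  speed_q <- c(abs(diff(pos_px))[1], abs(diff(pos_px))) * um_per_px * spec$fps
  truth <- data.frame(beat = rep(seq_len(K), each = 2),
                      label = rep(c("contraction", "relaxation"), K),
                      time_s = as.vector(rbind(c_times, r_times)),
                      amp_um_s = rep(c(spec$contraction_amp,
                                       spec$relaxation_amp), K))
  structure(list(video = vid,
                 waveform_true = motion_waveform(abs(v), fps = spec$fps, t = t,
                                                 meta = list(generator = "simulate_beat_video")),
                 waveform_quant = motion_waveform(speed_q, fps = spec$fps,
                                                  t = t),
                 truth = truth, spec = spec), class = "beat_video")
}
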