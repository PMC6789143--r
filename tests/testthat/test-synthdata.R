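test_that("waveform generator: beat count, determinism, degenerate cases", {
  sim <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 20,
                                         fps = 100, seed = 1))
  expect_identical(nrow(sim$truth), 40L) # 20 contraction + 20 relaxation
  expect_identical(length(sim$waveform$S), 2000L)
  # bit-identical under the same seed
  sim2 <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 20,
                                          fps = 100, seed = 1))
  expect_identical(sim$waveform$S, sim2$waveform$S)
  # all beats removed -> flat waveform
  flat <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 10,
                                          fps = 100, missed_beat_prob = 1,
                                          seed = 1))
  expect_true(all(flat$waveform$S == 0))
  expect_identical(nrow(flat$truth), 0L)
  # overlapping pulses are an invalid spec
  expect_error(beat_sim_spec(bpm = 120, peak_width_s = 0.1), "overlap")
  expect_error(beat_sim_spec(missed_beat_prob = 1.5), "probabilities")
})

test_that("aberrations are seeded and reflected in the ground truth", {
  spec <- beat_sim_spec(bpm = 60, duration_s = 20, fps = 100, noise_sd = 1,
                        missed_beat_prob = 0.2, spike_prob = 0.3,
                        amp_jitter_frac = 0.3, seed = 123)
  a <- simulate_waveform(spec)
  b <- simulate_waveform(spec)
  expect_identical(a$waveform$S, b$waveform$S)
  expect_identical(a$truth, b$truth)
  expect_lt(nrow(a$truth), 40L) # some beats missed at p = 0.2
  # jitter moved amplitudes off their nominal values
  expect_gt(stats::sd(a$truth$amp_um_s[a$truth$label == "contraction"]), 0)
})

test_that("fBm generator has the exact fGn covariance structure", {
  x <- simulate_fbm(0.5, 4096, seed = 1)
  inc <- diff(x)
  # H = 0.5 is ordinary Brownian motion: iid increments
  expect_lt(abs(stats::acf(inc, plot = FALSE)$acf[2]), 0.05)
  # increment variance within 5% of the analytic unit variance
  expect_equal(stats::var(inc), 1, tolerance = 0.05)
  expect_identical(x, simulate_fbm(0.5, 4096, seed = 1))
  expect_error(simulate_fbm(1.2, 1024), "inside")
  expect_error(simulate_fbm(0.5, 100), "256")
})

test_that("fBm H = 0.7 shows the analytic variogram slope ~ 2H", {
  B <- simulate_fbm(0.7, 4096, seed = 11)
  cd <- suppressWarnings(capacity_dimension(variogram(B)))
  expect_equal(cd$P, 1.4, tolerance = 0.15)
})

test_that("Lorenz trajectory is bounded and integrator-robust", {
  x <- simulate_lorenz(8000, dt = 0.02, seed = 1)
  expect_true(all(abs(x) < 25))
  d1 <- correlation_dimension(x, m_values = 2:6)
  # doubling the trajectory length leaves D_steady in place
  x2 <- simulate_lorenz(16000, dt = 0.02, seed = 1)
  d2 <- correlation_dimension(x2, m_values = 2:6)
  expect_equal(d2$D_steady, d1$D_steady, tolerance = 0.1)
  # halved integration step, compared on a common 0.02 sampling grid so the
  # check isolates the integrator from the estimator's sampling geometry
  # (chaotic divergence makes the two runs independent realisations, so the
  # comparison needs the longer series to keep estimator spread below the
  # tolerance)
  x3 <- simulate_lorenz(32000, dt = 0.01, seed = 1)[seq(2, 32000, by = 2)]
  d3 <- correlation_dimension(x3, m_values = 2:6)
  expect_equal(d3$D_steady, d2$D_steady, tolerance = 0.1)
  expect_error(simulate_lorenz(1000), "5000")
  expect_error(simulate_lorenz(6000, dt = 0.1), "dt")
})

test_that("rendered video: zero schedule, exact recovery, determinism", {
  z <- render_video(matrix(0, 5, 2), texture_seed = 2)
  for (k in 2:5) expect_identical(z$seq$frames[[k]], z$seq$frames[[1]])
  # constant (0,2) px/frame drift
  pos <- cbind(0, 2 * (0:9))
  vid <- render_video(pos, texture_seed = 3)
  fl <- compute_motion_fields(vid$seq)[[1]]
  int_r <- 2:(nrow(fl$dx) - 1); int_c <- 2:(ncol(fl$dx) - 1)
  expect_true(all(fl$dx[int_r, int_c] == 2))
  expect_true(all(fl$dy[int_r, int_c] == 0))
  # determinism and bounds
  vid2 <- render_video(pos, texture_seed = 3)
  expect_identical(vid$seq$frames, vid2$seq$frames)
  expect_error(render_video(cbind(0, c(0, 90)), frame_shape = c(96, 96)),
               "frame_shape/4")
  expect_error(render_video(matrix(0, 3, 2), frame_shape = c(32, 32)),
               "64")
})

test_that("ground-truth peaks round-trip through the metrics stage", {
  # 75 BPM = 0.8 s period = an integer number of samples at 100 fps, so
  # every PP interval is exact
  sim <- simulate_waveform(beat_sim_spec(bpm = 75, duration_s = 20,
                                         fps = 100, seed = 5))
  bm <- beat_metrics(sim$waveform)
  expect_equal(bm$beat_rate_bpm$mean, 75, tolerance = 1e-9)
  expect_identical(bm$n_beats, as.integer(nrow(sim$truth) / 2))
})
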