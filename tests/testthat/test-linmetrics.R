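test_that("constant signal yields an empty, flagged peak list", {
  w <- motion_waveform(rep(5, 100), fps = 100)
  expect_warning(p <- detect_peaks(w), "no peaks")
  expect_identical(nrow(p), 0L)
  expect_true(attr(p, "no_peaks"))
})

test_that("clean twin-peak waveform: all generator peaks found and labelled", {
  sim <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 20,
                                         fps = 100, seed = 4))
  p <- detect_peaks(sim$waveform)
  expect_identical(sum(p$label == "contraction"), 20L)
  expect_identical(sum(p$label == "relaxation"), 20L)
  # detected times match the generator's ground truth to one sample
  for (lab in c("contraction", "relaxation")) {
    got <- p$time_s[p$label == lab]
    want <- sim$truth$time_s[sim$truth$label == lab]
    expect_equal(got, want, tolerance = 1 / 100 + 1e-9)
  }
})

test_that("a deleted beat drops exactly one contraction/relaxation pair", {
  # seed 8 deletes exactly one of 20 beats at this probability
  spec <- beat_sim_spec(bpm = 60, duration_s = 20, fps = 100,
                        missed_beat_prob = 0.05, seed = 8)
  sim <- simulate_waveform(spec)
  expect_identical(nrow(sim$truth), 38L)
  p <- detect_peaks(sim$waveform)
  expect_identical(sum(p$label == "contraction"), 19L)
  expect_identical(sum(p$label == "relaxation"), 19L)
})

test_that("beat metrics match generator parameters exactly on clean input", {
  sim <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 20, fps = 100,
                                         contraction_amp = 20,
                                         relaxation_amp = 15, seed = 1))
  bm <- beat_metrics(sim$waveform)
  expect_equal(bm$beat_rate_bpm$mean, 60, tolerance = 1e-10)
  expect_equal(bm$pp_interval_s$mean, 1.0, tolerance = 1e-10)
  expect_equal(bm$contraction_velocity_um_s$mean, 20, tolerance = 1e-6)
  expect_equal(bm$relaxation_velocity_um_s$mean, 15, tolerance = 1e-6)
  expect_false(bm$undefined)
  expect_identical(bm$n_beats, 20L)
})

test_that("pacing at 2 Hz and 1 Hz yields 120 and 60 BPM", {
  for (cfg in list(list(period = 0.5, bpm = 120), list(period = 1, bpm = 60))) {
    sim <- simulate_waveform(beat_sim_spec(period_s = cfg$period,
                                           duration_s = 20, fps = 100,
                                           seed = 1))
    bm <- beat_metrics(sim$waveform)
    expect_equal(bm$beat_rate_bpm$mean, cfg$bpm, tolerance = 1e-9)
  }
})

test_that("amplitude scaling moves velocities only; rate and PP unchanged", {
  sim <- simulate_waveform(beat_sim_spec(bpm = 45, duration_s = 20,
                                         fps = 100, seed = 2))
  w <- sim$waveform
  w2 <- motion_waveform(3 * w$S, fps = w$fps)
  a <- beat_metrics(w); b <- beat_metrics(w2)
  expect_equal(b$beat_rate_bpm$mean, a$beat_rate_bpm$mean)
  expect_equal(b$pp_interval_s$mean, a$pp_interval_s$mean)
  expect_equal(b$contraction_velocity_um_s$mean,
               3 * a$contraction_velocity_um_s$mean)
  expect_equal(b$relaxation_velocity_um_s$mean,
               3 * a$relaxation_velocity_um_s$mean)
})

test_that("time reversal swaps labels but preserves rate and PP", {
  sim <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 20,
                                         fps = 100, seed = 3))
  w <- sim$waveform
  wr <- motion_waveform(rev(w$S), fps = w$fps)
  a <- beat_metrics(w); b <- beat_metrics(wr)
  expect_equal(b$beat_rate_bpm$mean, a$beat_rate_bpm$mean, tolerance = 1e-9)
  expect_equal(b$pp_interval_s$mean, a$pp_interval_s$mean, tolerance = 1e-9)
  # the reversed waveform's "contraction" peaks are the original relaxations
  expect_equal(b$contraction_velocity_um_s$mean,
               a$relaxation_velocity_um_s$mean, tolerance = 1e-6)
})

test_that("larger-peak labelling rule picks the taller peak per beat", {
  sim <- simulate_waveform(beat_sim_spec(bpm = 60, duration_s = 10, fps = 100,
                                         contraction_amp = 12,
                                         relaxation_amp = 25, seed = 1))
  p <- detect_peaks(sim$waveform, label_rule = "larger")
  con <- p[p$label == "contraction", ]
  rel <- p[p$label == "relaxation", ]
  expect_true(all(con$speed_um_per_s > 20))
  expect_true(all(rel$speed_um_per_s < 15))
})

test_that("fewer than two contraction peaks flags metrics undefined", {
  t <- (0:299) / 100
  w <- motion_waveform(gauss_pulse_test(t, 1.5, 20, 0.05), fps = 100)
  bm <- beat_metrics(w)
  expect_true(bm$undefined)
  expect_true(is.nan(bm$beat_rate_bpm$mean))
  expect_true(is.nan(bm$pp_interval_s$mean))
  # the single peak still reports a contraction velocity
  expect_equal(bm$contraction_velocity_um_s$mean, 20, tolerance = 1e-6)
})
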