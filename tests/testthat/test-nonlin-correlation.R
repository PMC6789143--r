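test_that("correlation integral agrees exactly with the naive pair count", {
  # a lighter version of acceptance criterion 4 (which runs 20 embeddings)
  set.seed(7)
  for (m in c(1, 2, 4)) {
    S <- stats::rnorm(120)
    X <- embed_series(S, m = m, tau = 2)
    ci <- correlation_integral(X)
    expect_equal(ci$C, naive_corr_C(unclass(X), ci$r))
    expect_equal(ci$C[length(ci$C)], 1) # last edge covers every pair
    expect_true(all(diff(ci$C) >= 0)) # monotone in r
    expect_true(all(ci$C >= 0 & ci$C <= 1))
  }
})

test_that("correlation sums are anti-monotone in m at fixed radii", {
  set.seed(11)
  S <- stats::rnorm(300)
  r_grid <- seq(0.5, 4, length.out = 8)
  C_prev <- NULL
  for (m in 2:4) {
    Cm <- naive_corr_C(unclass(embed_series(S, m, 1))[1:280, ], r_grid)
    if (!is.null(C_prev)) expect_true(all(Cm <= C_prev + 1e-12))
    C_prev <- Cm
  }
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(correlation_integral(matrix(1, 40, 2)), "identical")
  expect_error(correlation_integral(matrix(stats::rnorm(20), 10)), "32")
})

test_that("uniform clouds recover their dimension within 0.2", {
  set.seed(13)
  for (d in 1:3) {
    n <- if (d < 3) 500 else 1000
    X <- matrix(stats::runif(n * d), ncol = d)
    ci <- correlation_integral(X)
    fit <- cardiodyn:::fit_scaling_region(ci)
    expect_equal(fit$slope, d, tolerance = 0.2 / d,
                 label = sprintf("slope for d=%d cloud", d))
  }
})

test_that("a sine wave has correlation dimension ~1 with a plateau", {
  cr <- correlation_dimension(sin(2 * pi * (1:2000) / 97.3), m_values = 2:8)
  expect_true(cr$plateau)
  expect_equal(cr$D_steady, 1, tolerance = 0.15)
  expect_true(all(abs(cr$slopes - 1) < 0.15))
})

test_that("iid noise: D(m) grows with m and no plateau is detected", {
  set.seed(17)
  cr <- correlation_dimension(stats::runif(2000), tau = 1, m_values = 2:8)
  expect_false(cr$plateau)
  expect_true(all(diff(cr$slopes) > 0))
  expect_gt(cr$slopes[length(cr$slopes)], 4)
})

test_that("correlation dimension is amplitude-invariant", {
  S <- simulate_waveform(beat_sim_spec(bpm = 50, duration_s = 15, fps = 100,
                                       noise_sd = 0.5, seed = 6))$waveform$S
  a <- correlation_dimension(S, m_values = 2:5)
  b <- correlation_dimension(5 * S, tau = a$tau, m_values = 2:5)
  expect_equal(b$slopes, a$slopes, tolerance = 1e-8)
})

test_that("steady_value implements the plateau rule", {
  st <- steady_value(c(1.0, 1.5, 1.9, 2.0, 2.02, 2.01))
  expect_true(st$plateau)
  expect_equal(st$value, mean(c(2.0, 2.02, 2.01)))
  # strictly increasing curve: no plateau, last value reported
  st2 <- steady_value(1:6)
  expect_false(st2$plateau)
  expect_equal(st2$value, 6)
  st3 <- steady_value(rep(1.4, 5))
  expect_true(st3$plateau)
  expect_equal(st3$value, 1.4)
  expect_error(steady_value(c(1, 2)), "at least 3")
})

test_that("manual fit window and linear binning are honoured", {
  set.seed(19)
  X <- matrix(stats::runif(400 * 2), ncol = 2)
  ci_lin <- correlation_integral(X, log_bins = FALSE)
  expect_equal(diff(ci_lin$r), rep(diff(ci_lin$r)[1], 31), tolerance = 1e-9)
  cr <- correlation_dimension(stats::runif(500), tau = 1, m_values = 2:4,
                              fit_window = c(10, 20))
  for (w in cr$regions[!vapply(cr$regions, is.null, TRUE)])
    expect_equal(w, c(10, 20))
})

test_that("failing embedding dimensions are dropped with a warning", {
  S <- stats::rnorm(60) # too short for m = 15 at tau = 4
  expect_warning(cr <- correlation_dimension(S, tau = 4, m_values = c(2, 15)),
                 "dropped")
  expect_identical(cr$failed_m, 15)
  expect_false(is.na(cr$slopes[1]))
})
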