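test_that("identical frames give exactly zero motion and a zero waveform", {
  f <- textured_frame(seed = 3)
  seq <- frame_sequence(list(f, f, f), fps = 100, um_per_px = 0.5)
  fields <- compute_motion_fields(seq)
  for (fl in fields) {
    expect_true(all(fl$dy == 0L))
    expect_true(all(fl$dx == 0L))
  }
  w <- fields_to_waveform(fields, fps = 100, um_per_px = 0.5)
  expect_identical(w$S, rep(0, 3))
})

test_that("integer translations within the search radius are recovered exactly", {
  f <- textured_frame(128, 128, seed = 11)
  for (shift in list(c(2, 0), c(0, 3), c(-2, 2), c(5, -4), c(7, 7))) {
    g <- circshift(f, shift[1], shift[2])
    seq <- frame_sequence(list(f, g), fps = 100, um_per_px = 1)
    fl <- compute_motion_fields(seq, block_size = 16, search_radius = 7)[[1]]
    # interior blocks: search window and true match fully inside both frames
    gr <- nrow(fl$dy); gc <- ncol(fl$dy)
    int_r <- 2:(gr - 1); int_c <- 2:(gc - 1)
    expect_true(all(fl$dy[int_r, int_c] == shift[1]),
                label = sprintf("dy for shift (%d,%d)", shift[1], shift[2]))
    expect_true(all(fl$dx[int_r, int_c] == shift[2]))
  }
})

test_that("shifting both frames together leaves interior vectors unchanged", {
  f <- textured_frame(128, 128, seed = 5)
  g <- circshift(f, 1, 2)
  base <- compute_motion_fields(frame_sequence(list(f, g), 100, 1))[[1]]
  f2 <- circshift(f, 3, 3); g2 <- circshift(g, 3, 3)
  moved <- compute_motion_fields(frame_sequence(list(f2, g2), 100, 1))[[1]]
  # equivariance holds where no border effect enters either computation
  int_r <- 3:(nrow(base$dy) - 2); int_c <- 3:(ncol(base$dy) - 2)
  expect_equal(moved$dy[int_r, int_c], base$dy[int_r, int_c])
  expect_equal(moved$dx[int_r, int_c], base$dx[int_r, int_c])
})

test_that("invalid frame input is rejected", {
  f <- textured_frame(seed = 1)
  expect_error(frame_sequence(list(f), 100, 1), "at least 2")
  expect_error(frame_sequence(list(f, f[1:50, ]), 100, 1), "same dimensions")
  expect_error(frame_sequence(list(f, f), fps = 0, um_per_px = 1), "positive")
  seq <- frame_sequence(list(f, f), 100, 1)
  expect_error(compute_motion_fields(seq, block_size = 2), "block_size")
  expect_error(compute_motion_fields(seq, search_radius = 0), "search_radius")
})

test_that("fields_to_waveform applies the documented reduction", {
  zero <- structure(list(dy = matrix(0L, 4, 4), dx = matrix(0L, 4, 4),
                         block_size = 16L, search_radius = 7L),
                    class = "motion_field")
  two <- structure(list(dy = matrix(0L, 4, 4), dx = matrix(2L, 4, 4),
                        block_size = 16L, search_radius = 7L),
                   class = "motion_field")
  w0 <- fields_to_waveform(list(zero, zero), fps = 100, um_per_px = 1)
  expect_identical(w0$S, rep(0, 3))
  w2 <- fields_to_waveform(list(two, two), fps = 100, um_per_px = 1)
  expect_identical(w2$S, rep(200, 3)) # 2 px * 1 um/px * 100 /s
  expect_equal(length(w2$S), 3) # first inter-frame speed duplicated
  expect_error(fields_to_waveform(list(), 100, 1), "non-empty")
})

test_that("sinusoidal rendered video: displacement recovered within 0.5 px", {
  n <- 40
  pos <- cbind(0, round(3 * sin(2 * pi * seq_len(n) / n)))
  vid <- render_video(pos, frame_shape = c(96, 96), texture_seed = 7,
                      fps = 50, um_per_px = 1)
  fields <- compute_motion_fields(vid$seq, block_size = 16, search_radius = 7)
  rec <- vapply(fields, function(f) mean(f$dx), numeric(1))
  truth <- vid$displacements[, 2]
  expect_true(all(abs(rec - truth) <= 0.5))
  w <- fields_to_waveform(fields, fps = 50, um_per_px = 1)
  expect_gt(stats::cor(w$S[-1], abs(truth)), 0.95)
})

test_that("subpixel refinement stays within half a pixel of integer truth", {
  f <- textured_frame(128, 128, seed = 21)
  g <- circshift(f, 0, 3)
  seq <- frame_sequence(list(f, g), 100, 1)
  fl <- compute_motion_fields(seq, subpixel = TRUE)[[1]]
  int_r <- 2:(nrow(fl$dx) - 1); int_c <- 2:(ncol(fl$dx) - 1)
  expect_true(all(abs(fl$dx[int_r, int_c] - 3) <= 0.5))
  expect_true(all(abs(fl$dy[int_r, int_c]) <= 0.5))
})
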