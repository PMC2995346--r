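test_that("grating profile follows the sine definition", {
  spec <- stimulus_spec(isi_duration = 0.04)
  v <- make_grating_profile(0, spec, default_grid)
  expect_length(v, default_grid$nx)

  # zero wherever sf * x is an integer (phase 0)
  idx <- which(abs((1.6 * default_grid$x) %% 1) < 1e-9)
  expect_gt(length(idx), 0)
  expect_equal(v[idx], rep(0, length(idx)), tolerance = 1e-12)

  # amplitude is the default contrast of 0.5 (up to sampling of the peak)
  expect_lte(max(abs(v)), 0.5)
  expect_equal(max(abs(v)), 0.5, tolerance = 0.01)

  # phase 90 equals phase 0 displaced by a quarter spatial period
  # (sf 1.25 cpd -> quarter period = 0.2 deg = 4 samples)
  spec2 <- stimulus_spec(0.04, spatial_frequency = 1.25)
  v0 <- make_grating_profile(0, spec2, default_grid)
  v90 <- make_grating_profile(90, spec2, default_grid)
  n <- default_grid$nx
  expect_equal(v90[1:(n - 4)], v0[5:n], tolerance = 1e-12)

  expect_error(stimulus_spec(0.04, spatial_frequency = 0))
  expect_error(stimulus_spec(0.04, phase_step = 45), "phase_step")
  expect_error(stimulus_spec(0.04, contrast = 0), "contrast")
})

test_that("single-cycle two-stroke sequence has the specified timing", {
  s0 <- make_two_stroke_xt(stimulus_spec(0), default_grid)
  act0 <- which(colSums(abs(s0$values)) > 0)
  # isi = 0: active duration 5 x 40 ms = 0.200 s = 40 samples
  expect_equal(diff(range(act0)) + 1, 40)

  s315 <- make_two_stroke_xt(stimulus_spec(0.315), default_grid)
  act <- which(colSums(abs(s315$values)) > 0)
  # 0.200 + 2 x 0.315 = 0.830 s = 166 samples, fits in 1.5 s
  expect_equal(diff(range(act)) + 1, 166)
  # the two ISI epochs are exactly blank: 2 x 63 zero columns in the span
  span <- seq(min(act), max(act))
  expect_equal(sum(colSums(abs(s315$values[, span])) == 0), 2 * 63)
  # centred in the window, ties toward earlier onset
  expect_equal(min(act) - 1, (default_grid$nt - 166) %/% 2)
  # contrast bound
  expect_lte(max(abs(s315$values)), 0.5)

  # a sequence longer than the window is an error
  short <- sampling_grid(t_extent = 0.5)
  expect_error(make_two_stroke_xt(stimulus_spec(0.2), short), "fit")
})

test_that("exact 120 Hz frame timing spans 208-841 ms across the ISI range", {
  # display frames are 5 refreshes at 120 Hz (~42 ms); ISIs 0 and 38 refreshes
  g <- sampling_grid(dx = 0.05, x_extent = 1, dt = 1 / 1200, t_extent = 1.2)
  frame <- 5 / 120
  durations <- vapply(c(0, 38), function(isi_frames) {
    sp <- stimulus_spec(isi_frames / 120, frame_duration = frame)
    s <- make_two_stroke_xt(sp, g)
    act <- which(colSums(abs(s$values)) > 0)
    (diff(range(act)) + 1) * g$dt * 1000
  }, numeric(1))
  expect_equal(floor(durations), c(208, 841))
})

test_that("repeating stimulus tiles the seven-epoch cycle from t = 0", {
  r <- make_repeating_xt(stimulus_spec(0.04, mode = "repeating"),
                         default_grid)
  expect_equal(dim(r$values), c(default_grid$nx, default_grid$nt))

  # cycle = 5x40 + 2x40 ms = 0.280 s = 56 samples; >= 5 full cycles in 1.5 s
  expect_gte(default_grid$nt %/% 56, 5)
  # periodic tiling, final partial cycle truncated
  expect_equal(r$values[, 57:112], r$values[, 1:56])
  expect_equal(r$values[, 281:300], r$values[, 1:20])

  # first cycle equals the single-cycle stimulus placed at t = 0
  s <- make_two_stroke_xt(stimulus_spec(0.04), default_grid)
  act <- which(colSums(abs(s$values)) > 0)
  expect_equal(r$values[, 1:56],
               s$values[, min(act):(min(act) + 55)])

  # ISI columns are background (all-zero)
  expect_equal(sum(colSums(abs(r$values[, 1:56])) == 0), 2 * 8)

  expect_error(make_repeating_xt(stimulus_spec(0.04), default_grid), "mode")
  expect_error(make_two_stroke_xt(stimulus_spec(0.04, mode = "repeating"),
                                  default_grid), "mode")
})

test_that("stimuli are background-relative: zero mean over whole periods", {
  # sf = 2 cpd -> 16 whole periods across the 8 deg window
  s <- make_two_stroke_xt(stimulus_spec(0.085, spatial_frequency = 2),
                          default_grid)
  expect_lt(max(abs(colMeans(s$values))), 1e-14)
})

test_that("reversing the phase step mirrors the stimulus spatially", {
  # sf = 2 cpd: the window is mirror-closed (circular flip about x = 0,
  # then a half-period shift, maps +90-step onto -90-step exactly)
  p <- make_two_stroke_xt(
    stimulus_spec(0.085, spatial_frequency = 2, phase_step = 90),
    default_grid)$values
  m <- make_two_stroke_xt(
    stimulus_spec(0.085, spatial_frequency = 2, phase_step = -90),
    default_grid)$values
  mir <- p[c(1, rev(2:nrow(p))), ]
  half_period <- 5L
  shifted <- mir[((seq_len(nrow(mir)) - 1L + half_period) %% nrow(mir)) + 1L, ]
  expect_equal(shifted, m, tolerance = 1e-12)
})

test_that("drifting grating is a travelling wave", {
  d <- make_drifting_grating_xt(1.25, 5, 1, 0.5, default_grid)
  # sf*dx*4 = 0.25 = tf*dt*10: shifting (4 samples, 10 samples) is identity
  expect_equal(d$values[5:160, 11:300], d$values[1:156, 1:290],
               tolerance = 1e-12)

  # tf = 0: stationary, every time column identical
  s <- make_drifting_grating_xt(1.25, 0, 1, 0.5, default_grid)
  expect_true(all(s$values == s$values[, 1]))

  # direction flip equals time reversal of the matrix (window chosen so
  # tf * (nt - 1) * dt is a whole number of cycles)
  g <- sampling_grid(t_extent = 1.405)
  a <- make_drifting_grating_xt(1.25, 10, 1, 0.5, g)$values
  b <- make_drifting_grating_xt(1.25, 10, -1, 0.5, g)$values
  expect_equal(a[, rev(seq_len(ncol(a)))], b, tolerance = 1e-9)

  # aliased parameters are rejected
  expect_error(make_drifting_grating_xt(12, 5, 1, 0.5, default_grid),
               "Nyquist")
  expect_error(make_drifting_grating_xt(1.25, 150, 1, 0.5, default_grid),
               "Nyquist")
})
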