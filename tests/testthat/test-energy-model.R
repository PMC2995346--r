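bank110 <- build_sensors(
  spatial_filter_spec(),
  temporal_filter_spec(110, n = 6),
  temporal_filter_spec(110, n = 9)
)

test_that("sensor bank has the prescribed algebraic structure", {
  se <- spatial_even(bank110$spatial)
  tf <- temporal_response(bank110$fast)

  # R1 + L1 = 2 * SE (x) TF
  expect_equal(bank110$R1 + bank110$L1, 2 * outer(se, tf), tolerance = 1e-12)

  # each oriented filter is rank 2 (sum of two outer products)
  expect_equal(qr(bank110$R1)$rank, 2)
  expect_equal(qr(bank110$L2)$rank, 2)

  # spatial flip maps rightward onto leftward filters (mirror-paired rows)
  expect_equal(bank110$R1[rev(2:80), ], bank110$L1[2:80, ], tolerance = 1e-12)
  expect_equal(bank110$R2[rev(2:80), ], -bank110$L2[2:80, ], tolerance = 1e-12)

  # mismatched sampling grids are rejected
  other <- make_drifting_grating_xt(1.1, 5, grid = sampling_grid(dx = 0.1))
  expect_error(energy_summary(other, bank110), "grid")
})

test_that("drift calibration: motion toward +x gives strongly positive ne", {
  right <- make_drifting_grating_xt(1.1, 8, 1, 0.5, default_grid)
  left <- make_drifting_grating_xt(1.1, 8, -1, 0.5, default_grid)
  expect_gt(energy_summary(right, bank110)$ne, 0.9)
  expect_lt(energy_summary(left, bank110)$ne, -0.9)
})

test_that("stationary gratings and blank stimuli carry no net energy", {
  still <- make_drifting_grating_xt(1.1, 0, 1, 0.5, default_grid)
  expect_lt(abs(energy_summary(still, bank110)$ne), 1e-12)

  blank <- with_values(still, matrix(0, default_grid$nx, default_grid$nt))
  expect_warning(es <- energy_summary(blank, bank110), "flicker")
  expect_equal(es$ne, 0)
})

test_that("opponent energy is antisymmetric under time reversal and mirror", {
  spec <- stimulus_spec(0.085, mode = "repeating")
  stim <- make_repeating_xt(spec, default_grid)
  es <- energy_summary(stim, bank110)

  rev_t <- with_values(stim, stim$values[, rev(seq_len(ncol(stim$values)))])
  expect_lt(abs(es$ne + energy_summary(rev_t, bank110)$ne), 1e-10)

  rev_x <- with_values(stim, stim$values[rev(seq_len(nrow(stim$values))), ])
  expect_lt(abs(es$ne + energy_summary(rev_x, bank110)$ne), 1e-10)

  # flicker energy is invariant under both
  expect_equal(energy_summary(rev_t, bank110)$flicker, es$flicker,
               tolerance = 1e-10)
})

test_that("ne is bounded and contrast-invariant for arbitrary stimuli", {
  bank <- build_sensors(
    spatial_filter_spec(dx = small_grid$dx),
    temporal_filter_spec(80, n = 6, dt = small_grid$dt),
    temporal_filter_spec(80, n = 9, dt = small_grid$dt)
  )
  proto <- make_drifting_grating_xt(1.1, 5, grid = small_grid)
  set.seed(101)
  for (i in 1:8) {
    vals <- matrix(stats::runif(small_grid$nx * small_grid$nt, -0.5, 0.5),
                   small_grid$nx, small_grid$nt)
    es <- energy_summary(with_values(proto, vals), bank)
    expect_gte(es$e_R, 0)
    expect_gte(es$e_L, 0)
    expect_gte(es$ne, -1)
    expect_lte(es$ne, 1)
    # scaling the contrast leaves ne unchanged (energies scale by c^2)
    es3 <- energy_summary(with_values(proto, 3 * vals), bank)
    expect_equal(es3$ne, es$ne, tolerance = 1e-12)
    expect_equal(es3$flicker, 9 * es$flicker, tolerance = 1e-9)
  }
})

test_that("the zero-ISI two-stroke stimulus is directionally balanced", {
  # with no ISI the sequence is a mirror-symmetric two-position oscillation
  for (k in c(50, 110)) {
    ne0 <- model_curve("dd", k, isi = 0)$ne
    expect_lt(abs(ne0), 1e-10)
  }
})

test_that("reversing the phase step negates the model curve", {
  isi <- c(0.04, 0.165, 0.315)
  plus <- model_curve("dd", 110, isi = isi, cfg = default_cfg)$ne
  minus <- model_curve("dd", 110, isi = isi,
                       cfg = model_config(phase_step = -90))$ne
  # windowing (12.8 grating periods across 8 deg) leaves a small residual
  expect_lt(max(abs(plus + minus)), 0.02)
  expect_true(all(sign(minus[plus > 0.1]) == -1))
})

test_that("smaller k moves the optimal ISI to longer values", {
  for (task in c("dd", "mae")) {
    c110 <- model_curve(task, 110, cfg = default_cfg)
    c50 <- model_curve(task, 50, cfg = default_cfg)
    expect_gt(c50$isi[which.max(c50$ne)], c110$isi[which.max(c110$ne)])
  }
})

test_that("the adaptor curve peaks at an interior ISI then declines", {
  for (k in c(50, 110)) {
    curve <- model_curve("mae", k, cfg = default_cfg)
    peak <- which.max(curve$ne)
    expect_gt(peak, 1)
    expect_lt(peak, length(curve$ne))
    # every long-ISI value sits below the peak
    late <- curve$ne[curve$isi >= 0.2]
    expect_true(all(late < curve$ne[peak]))
  }
})

test_that("model_curve_grid agrees with individual model_curve calls", {
  isi <- c(0.04, 0.125)
  grid_ne <- model_curve_grid("dd", c(60, 110), isi = isi, cfg = default_cfg)
  expect_equal(grid_ne["60", ], model_curve("dd", 60, isi, default_cfg)$ne,
               tolerance = 1e-12)
  expect_equal(grid_ne["110", ], model_curve("dd", 110, isi, default_cfg)$ne,
               tolerance = 1e-12)
})
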