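test_that("tube phantom matches its analytic ground truth", {
  ph <- tube_002()
  vv <- voxel_volume_mm3(ph$mask)
  expect_equal(sum(ph$mask$voxels) * vv, pi * 0.5^2 * 10, tolerance = 0.02)
  # any axial slice has the analytic disc area
  d <- dim(ph$mask$voxels)
  for (k in round(d[3] * c(0.25, 0.5, 0.75))) {
    a <- sum(ph$mask$voxels[, , k]) * prod(ph$mask$spacing_mm[1:2])
    expect_equal(a, pi * 0.5^2, tolerance = 0.02)
  }
  expect_equal(ph$truth$length_true_mm, 10)
  expect_s3_class(ph$truth, "phantom_truth")
})

test_that("tube phantom validates arguments and warns on coarse grids", {
  expect_error(make_tube_phantom(-1, 10, 0.05), "must all be > 0")
  expect_error(make_tube_phantom(0.5, 0, 0.05), "must all be > 0")
  expect_warning(make_tube_phantom(0.5, 2, 0.25), "voxels span")
})

test_that("venturi phantom has its minimum area inside the throat", {
  expect_error(make_venturi_phantom(0.4, 0.4), "smaller")
  vp <- venturi_004()
  tr <- vp$truth$area_profile_true
  expect_equal(min(tr$area_mm2), pi * 0.4^2, tolerance = 1e-9)
  # non-increasing through the inlet taper, non-decreasing through the outlet
  ks <- vp$truth$extra$knots_s
  inlet_taper <- tr[tr$s_mm >= ks[2] & tr$s_mm <= ks[3], ]
  outlet_taper <- tr[tr$s_mm >= ks[4] & tr$s_mm <= ks[5], ]
  expect_true(all(diff(inlet_taper$area_mm2) <= 1e-12))
  expect_true(all(diff(outlet_taper$area_mm2) >= -1e-12))
})

test_that("every phantom ground truth is self-consistent (area integrates to volume)", {
  for (ph in list(tube_005(), venturi_004(), mouse_008(),
                  make_curved_tube_phantom(5, 0.5, 90, spacing_mm = 0.1))) {
    tr <- ph$truth
    s <- tr$area_profile_true$s_mm
    a <- tr$area_profile_true$area_mm2
    v_int <- sum(diff(s) * (head(a, -1) + tail(a, -1)) / 2)
    # tube profiles cover the full length; integration must recover volume
    expect_equal(v_int, tr$volume_true_mm3, tolerance = 0.01)
    expect_true(all(diff(s) > 0))
    expect_true(all(a > 0))
  }
})

test_that("mouse airway phantom places all landmarks inside the lumen", {
  ph <- mouse_008()
  inside <- sample_nearest(ph$mask,
                           as.matrix(ph$landmarks[, c("x_mm", "y_mm", "z_mm")]),
                           fill = FALSE)
  expect_true(all(inside))
  expect_setequal(ph$landmarks$name,
                  c("nostril_left", "nostril_right", "meatus_merge",
                    "hard_palate_edge", "epiglottis", "arytenoid"))
})

test_that("cross-section scaling multiplies ground-truth areas by scale^2", {
  base <- mouse_008()$truth
  scaled <- mouse_008_scaled()$truth
  ratio <- scaled$area_profile_true$area_mm2 / base$area_profile_true$area_mm2
  expect_equal(ratio, rep(0.64, length(ratio)), tolerance = 1e-9)
  # lengths unchanged
  expect_equal(scaled$length_true_mm, base$length_true_mm)
  expect_equal(scaled$extra$pharyngeal_length_true_mm,
               base$extra$pharyngeal_length_true_mm)
})

test_that("phantom generators are pure functions of their configuration", {
  a <- make_mouse_airway_phantom(mouse_airway_config(), spacing_mm = 0.15)
  b <- make_mouse_airway_phantom(mouse_airway_config(), spacing_mm = 0.15)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_identical(a$volume$voxels, b$volume$voxels)
})

test_that("breath traces realise the analytic waveform parameters", {
  sp <- breath_spec(tidal_volume_ml = 0.15, rate_bpm = 150, ti_fraction = 0.5,
                    duration_s = 10, noise_sd = 0, seed = 7)
  tr <- make_breath_trace(sp)
  # peak-to-trough of the integrated volume is the tidal volume
  expect_equal(max(tr$volume_ml) - min(tr$volume_ml), 0.15, tolerance = 0.01)
  # peak inspiratory flow of a half-sine lobe: pi * TV / (2 * Ti), Ti = 0.2 s
  expect_equal(max(tr$flow_ml_s), pi * 0.15 / (2 * 0.2), tolerance = 0.01)
  # identical seeds give bit-identical traces
  expect_identical(tr, make_breath_trace(sp))
  # movement channel marks the configured epochs
  sp2 <- breath_spec(duration_s = 10, movement_epochs = list(c(2, 4)), seed = 1)
  tr2 <- make_breath_trace(sp2)
  expect_true(all(tr2$movement[tr2$time_s >= 2 & tr2$time_s <= 4]))
  expect_false(any(tr2$movement[tr2$time_s < 2 | tr2$time_s > 4]))
})

test_that("breath spec rejects invalid parameters", {
  expect_error(breath_spec(tidal_volume_ml = 0), "tidal_volume_ml")
  expect_error(breath_spec(ti_fraction = 1))
  expect_error(breath_spec(rate_bpm = 300, sampling_hz = 50), "20x")
})

test_that("morphometry cohorts reproduce the specified moments at large n", {
  sp <- cohort_spec(
    tibble::tibble(measure = c("b", "z"),
                   mean_g1 = c(7.93, 2.79), sd_g1 = c(0.17, 0.12),
                   mean_g2 = c(7.33, 2.79), sd_g2 = c(0.20, 0.13)),
    n_g1 = 10000, n_g2 = 10000, seed = 11
  )
  coh <- make_morphometry_cohort(sp)
  expect_lt(abs(mean(coh$g1$b) - 7.93), 0.01)
  expect_lt(abs(mean(coh$g2$b) - 7.33), 0.01)
  expect_lt(abs(sd(coh$g1$z) - 0.12), 0.01)
  # reproducible under seed
  coh2 <- make_morphometry_cohort(sp)
  expect_identical(coh$g1, coh2$g1)
})
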