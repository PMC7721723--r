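test_that("straight-tube centerline recovers length and stays on axis", {
  ph <- tube_005()
  cl <- extract_centerline(ph$mask, c(0, 0, 0), c(0, 0, 10))
  expect_equal(max(cl$s_mm), 10, tolerance = 0.02)
  # maximum perpendicular deviation from the true axis under one voxel
  dev <- sqrt(cl$x_mm^2 + cl$y_mm^2)
  expect_lt(max(dev), 0.05)
  # every point lies inside the mask
  inside <- sample_nearest(ph$mask, as.matrix(cl[, c("x_mm", "y_mm", "z_mm")]),
                           fill = FALSE)
  expect_true(all(inside))
})

test_that("quarter-torus centerline length matches the analytic arc", {
  ct <- make_curved_tube_phantom(5, 0.5, 90, spacing_mm = 0.05)
  cl <- extract_centerline(ct$mask, ct$truth$landmark_truth$start,
                           ct$truth$landmark_truth$end)
  expect_equal(max(cl$s_mm), pi * 5 / 2, tolerance = 0.03)
})

test_that("degenerate and disconnected centerline requests fail loudly", {
  ph <- tube_005()
  expect_error(extract_centerline(ph$mask, c(0, 0, 5), c(0, 0, 5)), "path error")
  # two disjoint tubes in one grid
  vox <- array(FALSE, c(30, 10, 40))
  vox[3:8, 3:8, ] <- TRUE
  vox[20:25, 3:8, ] <- TRUE
  m <- binary_mask(vox, 0.1)
  expect_error(
    extract_centerline(m, c(0.4, 0.4, 1), c(2.2, 0.4, 1)),
    "path error"
  )
  expect_error(centerline_from_points(matrix(c(1, 2, 3), 1)), "path error")
})

test_that("perpendicular cross-sections measure the true disc area", {
  ph <- tube_002()
  cl <- centerline_from_points(cbind(0, 0, seq(0, 10, by = 0.05)))
  cs <- cross_section_at(ph$mask, cl, 5)
  expect_equal(cs$area_mm2, pi * 0.25, tolerance = 0.02)
  expect_equal(as.numeric(cs$plane_normal), c(0, 0, 1), tolerance = 1e-6)
  expect_error(cross_section_at(ph$mask, cl, 99), "range error")
})

test_that("a 30-degree tilted cylinder still yields the perpendicular area", {
  ph <- tube_002_tilted()
  axis <- c(0, sin(pi / 6), cos(pi / 6))
  cl <- centerline_from_points(outer(seq(0, 6, by = 0.05), axis))
  cs <- cross_section_at(ph$mask, cl, 3)
  true_area <- pi * 0.25
  oblique_area <- true_area / cos(pi / 6)
  expect_equal(cs$area_mm2, true_area, tolerance = 0.03)
  # clearly distinguishes the perpendicular from the oblique axial section
  expect_lt(abs(cs$area_mm2 - true_area), 0.3 * abs(oblique_area - true_area))
})

test_that("planes clipped by the volume boundary warn and truncate", {
  ph <- tube_005()
  # crop the grid through the lumen so the section plane leaves the volume
  m <- ph$mask$voxels
  xs <- seq_len(dim(m)[1])
  x0 <- ph$mask$origin_mm[1] + (xs - 1) * 0.05
  keep <- which(x0 >= -0.3)
  cropped <- binary_mask(m[keep, , , drop = FALSE], ph$mask$spacing_mm,
                         ph$mask$origin_mm + c((keep[1] - 1) * 0.05, 0, 0))
  cl <- centerline_from_points(cbind(0, 0, seq(0, 10, by = 0.05)))
  expect_warning(cs <- cross_section_at(cropped, cl, 5), "clipped")
  expect_true(cs$truncated)
  expect_gt(cs$area_mm2, 0)
  expect_lt(cs$area_mm2, pi * 0.25) # only the in-volume part is counted
})

test_that("the default station battery has nine stations rostral to caudal", {
  ph <- tube_002()
  cl <- centerline_from_points(cbind(0, 0, seq(0, 10, by = 0.05)))
  prof <- area_profile(ph$mask, cl, s_anchor_mm = 5)
  expect_equal(nrow(prof), 9)
  expect_equal(prof$station_label_mm, c(3, 2, 1, 0, -1, -2, -3, -4, -5))
  expect_equal(prof$s_mm, 5 - prof$station_label_mm)
  expect_false(any(prof$missing))
  # uniform cylinder: all areas equal the disc area
  expect_equal(prof$area_mm2, rep(pi * 0.25, 9), tolerance = 0.02)
})

test_that("stations beyond the centerline are flagged missing, others kept", {
  ph <- tube_005()
  cl <- centerline_from_points(cbind(0, 0, seq(0, 10, by = 0.05)))
  prof <- area_profile(ph$mask, cl, s_anchor_mm = 1) # +3..+1 fall below s=0
  expect_true(all(prof$missing[prof$station_label_mm > 1]))
  expect_false(any(prof$missing[prof$station_label_mm <= 1]))
  expect_equal(nrow(prof), 9)
})

test_that("venturi area profile bottoms out at the throat-centred anchor", {
  vp <- venturi_004()
  cl <- extract_centerline(vp$mask, c(0, 0, 0), c(0, 0, vp$truth$length_true_mm))
  throat_s <- vp$truth$landmark_truth$throat_centre[3]
  prof <- area_profile(vp$mask, cl, s_anchor_mm = throat_s,
                       offsets_mm = seq(3, -3, by = -1))
  expect_equal(prof$station_label_mm[which.min(prof$area_mm2)], 0)
  # measured areas track the analytic profile within 3%
  truth_at <- approx(vp$truth$area_profile_true$s_mm,
                     vp$truth$area_profile_true$area_mm2, xout = prof$s_mm)$y
  expect_equal(prof$area_mm2, truth_at, tolerance = 0.03)
})

test_that("scaled airway cross-sections scale areas by k^2 (similarity)", {
  g_base <- mouse_geometry()
  ph_s <- mouse_008_scaled()
  cl_b <- g_base$centerline
  prof_b <- area_profile(g_base$phantom$mask, cl_b,
                         s_anchor_mm = g_base$segments$s_hard_palate,
                         offsets_mm = c(2, 0, -2))
  lm_s <- setNames(
    lapply(seq_len(nrow(ph_s$landmarks)),
           function(i) as.numeric(ph_s$landmarks[i, c("x_mm", "y_mm", "z_mm")])),
    ph_s$landmarks$name
  )
  cl_s <- extract_centerline(ph_s$mask,
                             (lm_s$nostril_left + lm_s$nostril_right) / 2,
                             lm_s$arytenoid)
  segs_s <- partition_segments(cl_s, ph_s$landmarks)
  prof_s <- area_profile(ph_s$mask, cl_s, s_anchor_mm = segs_s$s_hard_palate,
                         offsets_mm = c(2, 0, -2))
  # 0.08 mm working grid: individual areas carry a few percent of
  # voxelisation error, so the ratio is checked to 8%
  expect_equal(prof_s$area_mm2 / prof_b$area_mm2, rep(0.64, 3), tolerance = 0.08)
})
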