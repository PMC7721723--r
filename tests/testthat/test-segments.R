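test_that("segment boundaries are recovered from phantom landmarks", {
  g <- mouse_geometry()
  cf <- g$phantom$truth$extra$config
  h <- g$phantom$mask$spacing_mm[1]
  # projection error bounded by about one voxel (centerline start offset aside)
  expect_lt(abs(g$segments$s_meatus_merge - cf$s_meatus_merge), 3 * h)
  expect_lt(abs(g$segments$s_hard_palate - cf$s_hard_palate), 3 * h)
  expect_lt(abs(g$segments$s_epiglottis - cf$s_epiglottis), 3 * h)
})

test_that("equally spaced landmarks on a cylinder give equal segment spans", {
  cl <- centerline_from_points(cbind(0, 0, seq(0, 10, by = 0.05)))
  lm <- list(meatus_merge = c(0, 0, 2.5),
             hard_palate_edge = c(0, 0, 5),
             epiglottis = c(0, 0, 7.5))
  segs <- partition_segments(cl, lm)
  spans <- c(segs$s_meatus_merge - 0,
             segs$s_hard_palate - segs$s_meatus_merge,
             segs$s_epiglottis - segs$s_hard_palate)
  expect_equal(spans, c(2.5, 2.5, 2.5), tolerance = 1e-6)
  expect_equal(segs$s_end, min(10, segs$s_hard_palate + 5))
})

test_that("out-of-order landmarks raise an ordering error", {
  cl <- centerline_from_points(cbind(0, 0, seq(0, 10, by = 0.05)))
  lm <- list(meatus_merge = c(0, 0, 2.5),
             hard_palate_edge = c(0, 0, 7.5),
             epiglottis = c(0, 0, 5)) # epiglottis rostral to hard palate
  expect_error(partition_segments(cl, lm), "ordering error")
  expect_error(partition_segments(cl, list(meatus_merge = c(0, 0, 1))),
               "must include")
})

test_that("segment volumes partition the mask exactly", {
  g <- mouse_geometry()
  vols <- segment_volumes(g$phantom$mask, g$centerline, g$segments)
  expect_identical(vols$v_total_mm3, vols$v_nasal_mm3 + vols$v_pharyngeal_mm3)
  # against generator ground truth within 3%
  expect_equal(vols$v_nasal_mm3, g$phantom$truth$extra$v_nasal_true_mm3,
               tolerance = 0.03)
  expect_equal(vols$v_pharyngeal_mm3, g$phantom$truth$extra$v_pharyngeal_true_mm3,
               tolerance = 0.03)
})

test_that("a cylinder split at its midpoint yields equal halves", {
  # length chosen as an even number of voxel layers so a mid-plane between
  # layers splits them exactly
  ph <- make_tube_phantom(0.5, 9.95, spacing_mm = 0.05)
  cl <- centerline_from_points(cbind(0, 0, seq(0, 9.95, by = 0.05)))
  lm <- list(meatus_merge = c(0, 0, 2), hard_palate_edge = c(0, 0, 4.975),
             epiglottis = c(0, 0, 9))
  segs <- partition_segments(cl, lm)
  vols <- segment_volumes(ph$mask, cl, segs)
  expect_equal(vols$v_nasal_mm3, vols$v_pharyngeal_mm3, tolerance = 0.01)
})

test_that("pharyngeal length is the arclength between its stations", {
  g <- mouse_geometry()
  lm <- g$landmarks
  cl <- g$centerline
  s_aryt <- cl$s_mm[which.min(colSums((t(as.matrix(cl[, c("x_mm", "y_mm", "z_mm")])) -
                                         lm$arytenoid)^2))]
  plen <- pharyngeal_length(cl, g$segments$s_hard_palate, s_aryt)
  expect_equal(plen, g$phantom$truth$extra$pharyngeal_length_true_mm,
               tolerance = 3 * g$phantom$mask$spacing_mm[1] / 5.8)
  expect_equal(pharyngeal_length(cl, 5, 5), 0)
  expect_error(pharyngeal_length(cl, 6, 5), "ordering error")
  expect_error(pharyngeal_length(cl, -2, 50), "range error")
  # straight tube: arclength difference equals Euclidean distance
  cls <- centerline_from_points(cbind(0, 0, seq(0, 10, by = 0.05)))
  expect_equal(pharyngeal_length(cls, 2, 8), 6)
})
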