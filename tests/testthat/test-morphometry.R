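make_landmark_set <- function(coords, ids = seq_len(nrow(coords))) {
  tibble::tibble(id = ids, x_mm = coords[, 1], y_mm = coords[, 2],
                 z_mm = coords[, 3])
}

test_that("landmark distances are Euclidean and the battery has 26 measures", {
  lm <- make_landmark_set(rbind(c(0, 0, 0), c(1, 1, 1)))
  d <- measure_distances(lm, tibble::tibble(measure = "d", id_a = 1, id_b = 2))
  expect_equal(d$distance_mm, sqrt(3), tolerance = 1e-12)
  pairs <- default_landmark_pairs()
  expect_equal(nrow(pairs), 26)
  expect_setequal(pairs$measure, c(letters[1:23], "x", "y", "z"))
})

test_that("the distance battery is invariant under rigid motion", {
  set.seed(3)
  coords <- matrix(rnorm(28 * 3, sd = 4), ncol = 3)
  lm <- make_landmark_set(coords, ids = 1:28)
  base <- measure_distances(lm)
  # random rotation (QR of a random matrix) + translation
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  moved <- make_landmark_set(coords %*% qr_q +
                               matrix(c(5, -3, 11), 28, 3, byrow = TRUE),
                             ids = 1:28)
  rotated <- measure_distances(moved)
  expect_equal(rotated$distance_mm, base$distance_mm, tolerance = 1e-9)
})

test_that("missing landmarks yield recorded missing values, not errors", {
  lm <- make_landmark_set(rbind(c(0, 0, 0), c(1, 0, 0)), ids = c(1, 3))
  suppressMessages(
    d <- measure_distances(lm, tibble::tibble(measure = c("a", "b"),
                                              id_a = c(1, 1), id_b = c(3, 6)))
  )
  expect_equal(d$distance_mm[1], 1)
  expect_true(is.na(d$distance_mm[2]))
})

test_that("hyoid metrics follow the 17/27/28 triangle", {
  lm <- make_landmark_set(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                          ids = c(17, 27, 28))
  hm <- hyoid_metrics(lm)
  expect_equal(c(hm$x_mm, hm$y_mm, hm$z_mm), c(4, 3, 5))
  # collinear: x = y + z
  lmc <- make_landmark_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                           ids = c(17, 27, 28))
  hmc <- hyoid_metrics(lmc)
  expect_equal(hmc$x_mm, hmc$y_mm + hmc$z_mm)
  # a missing landmark propagates NA
  suppressMessages(hm_na <- hyoid_metrics(make_landmark_set(rbind(c(0, 0, 0)),
                                                            ids = 17)))
  expect_true(all(is.na(c(hm_na$x_mm, hm_na$y_mm, hm_na$z_mm))))
})

test_that("identical groups compare with p = 1 across the board", {
  g <- tibble::tibble(subject_id = sprintf("s%d", 1:5),
                      a = c(1, 2, 3, 4, 5), b = c(2, 2, 3, 3, 4))
  cmp <- cohort_compare(g, g)
  expect_equal(cmp$p_value, rep(1, 2))
  expect_equal(cmp$t_statistic, rep(0, 2))
})

test_that("missing values are excluded per measure, not per subject", {
  sp <- cohort_spec(
    tibble::tibble(measure = c("q", "r"), mean_g1 = c(5, 6), sd_g1 = c(1, 1),
                   mean_g2 = c(5, 6), sd_g2 = c(1, 1)),
    n_g1 = 6, n_g2 = 6, seed = 2
  )
  coh <- make_morphometry_cohort(sp)
  coh$g2$q[1] <- NA # one subject unusable for measure q only
  cmp <- cohort_compare(coh$g1, coh$g2)
  expect_equal(cmp$n2[cmp$measure == "q"], 5)
  expect_equal(cmp$n2[cmp$measure == "r"], 6)
  expect_false(any(cmp$untestable))
})

test_that("groups with fewer than two valid subjects are flagged untestable", {
  g1 <- tibble::tibble(subject_id = c("a", "b", "c"), m = c(1, 2, 3))
  g2 <- tibble::tibble(subject_id = c("d", "e"), m = c(1, NA))
  cmp <- cohort_compare(g1, g2)
  expect_true(cmp$untestable)
  expect_true(is.na(cmp$p_value))
})

test_that("cohort_compare agrees exactly with the summary-statistic engine", {
  sp <- cohort_spec(
    tibble::tibble(measure = "b", mean_g1 = 7.93, sd_g1 = 0.17,
                   mean_g2 = 7.33, sd_g2 = 0.20),
    n_g1 = 8, n_g2 = 7, seed = 5
  )
  coh <- make_morphometry_cohort(sp)
  cmp <- cohort_compare(coh$g1, coh$g2)
  w <- welch_from_summary(mean(coh$g1$b), sd(coh$g1$b), 8,
                          mean(coh$g2$b), sd(coh$g2$b), 7)
  expect_identical(cmp$p_value, w$p_two_sided)
  expect_identical(cmp$t_statistic, w$t_statistic)
})

test_that("landmark CSVs round-trip", {
  lm <- make_landmark_set(rbind(c(0, 1, 2), c(3, 4, 5)))
  lm$subject_id <- "s1"
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$x_mm, lm$x_mm)
  expect_error(read_landmarks({
    p <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), p, row.names = FALSE)
    p
  }), "x_mm")
})
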