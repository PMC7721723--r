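test_that("quiet epochs are maximal movement-free runs with inclusive threshold", {
  t <- seq(0, 30, by = 0.01)
  # movement everywhere -> no epochs
  tr_all <- tibble::tibble(time_s = t, flow_ml_s = 0, volume_ml = 0,
                           movement = TRUE)
  expect_equal(nrow(select_quiet_epochs(tr_all)), 0)
  # one 12 s quiet gap
  mv <- t < 10 | t > 22
  tr <- tibble::tibble(time_s = t, flow_ml_s = 0, volume_ml = 0, movement = mv)
  ep <- select_quiet_epochs(tr)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_s, 12, tolerance = 0.011)
  # quiet gaps of 4.9 s and 5.0 s: only the 5.0 s gap survives (inclusive)
  mv2 <- !((t >= 2 & t <= 6.9) | (t >= 10 & t <= 15))
  tr2 <- tibble::tibble(time_s = t, flow_ml_s = 0, volume_ml = 0, movement = mv2)
  ep2 <- select_quiet_epochs(tr2)
  expect_equal(nrow(ep2), 1)
  expect_equal(ep2$start_s, 10)
  expect_equal(ep2$duration_s, 5)
})

test_that("clean traces are segmented into the constructed breaths", {
  tr <- make_breath_trace(breath_spec(tidal_volume_ml = 0.15, rate_bpm = 150,
                                      ti_fraction = 0.5, duration_s = 60,
                                      noise_sd = 0, seed = 1))
  br <- detect_breaths(tr)
  expect_gte(nrow(br), 148)
  expect_lte(nrow(br), 151)
  expect_equal(mean(br$ti_ms), 200, tolerance = 0.005)
  expect_equal(mean(br$te_ms), 200, tolerance = 0.005)
  expect_equal(mean(br$tidal_volume_ml), 0.15, tolerance = 0.01)
})

test_that("asymmetric inspiratory fraction is recovered in Ti/Te", {
  tr <- make_breath_trace(breath_spec(tidal_volume_ml = 0.2, rate_bpm = 120,
                                      ti_fraction = 0.3, duration_s = 30,
                                      seed = 2))
  br <- detect_breaths(tr)
  expect_equal(mean(br$ti_ms) / mean(br$te_ms), 3 / 7, tolerance = 0.02)
})

test_that("flat traces yield empty breath tables", {
  t <- seq(0, 20, by = 0.001)
  tr <- tibble::tibble(time_s = t, flow_ml_s = 0, volume_ml = 0,
                       movement = FALSE)
  expect_equal(nrow(detect_breaths(tr)), 0)
})

test_that("breaths crossing movement epochs are discarded whole", {
  base <- make_breath_trace(breath_spec(duration_s = 60, seed = 3))
  n_base <- nrow(detect_breaths(base))
  with_mv <- make_breath_trace(breath_spec(duration_s = 60, seed = 3,
                                           movement_epochs = list(c(20, 26))))
  n_mv <- nrow(detect_breaths(with_mv))
  expect_lt(n_mv, n_base)
  # adding movement never increases the breath count
  expect_lte(n_mv, n_base)
})

test_that("tidal-volume filtering applies strict exclusion bounds", {
  tb <- tibble::tibble(onset_s = 1:5, tidal_volume_ml = c(0.03, 0.15, 2.5, 0.05, 2.0),
                       ti_ms = 200, te_ms = 200, pif_ml_s = 1, pef_ml_s = 1,
                       epoch_id = 1L)
  kept <- filter_breaths(tb)
  expect_setequal(kept$tidal_volume_ml, c(0.15, 0.05, 2.0))
  # idempotent
  expect_identical(filter_breaths(kept)$tidal_volume_ml, kept$tidal_volume_ml)
  # empty in, empty out
  expect_equal(nrow(filter_breaths(tb[0, ])), 0)
})

test_that("respiratory summaries follow their defining formulas", {
  tb <- tibble::tibble(onset_s = seq(0, 59.6, by = 0.4),
                       tidal_volume_ml = 0.15, ti_ms = 200, te_ms = 200,
                       pif_ml_s = 1.18, pef_ml_s = 1.18, epoch_id = 1L)
  s <- summarize_respiration(tb, extracted_time_s = 60)
  expect_equal(s$rr_per_min, 150)
  expect_equal(s$minute_volume_ml_min, 0.15 * 150)
  expect_equal(s$n_breaths, 150)
  expect_error(summarize_respiration(tb[0, ]), "empty-summary")
})

test_that("undersampled traces trigger a warning", {
  tr <- make_breath_trace(breath_spec(rate_bpm = 120, duration_s = 20, seed = 1))
  # decimate to ~15 Hz, well under 10x the 2 Hz breathing frequency
  coarse <- tr[seq(1, nrow(tr), by = 66), ]
  expect_warning(detect_breaths(coarse), "sampling rate")
})

test_that("trace CSVs round-trip through the plain-text interface", {
  tr <- make_breath_trace(breath_spec(duration_s = 12, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_breath_trace(tr, path)
  back <- read_breath_trace(path)
  expect_equal(back$flow_ml_s, tr$flow_ml_s, tolerance = 1e-9)
  expect_identical(back$movement, tr$movement)
  s1 <- analyze_respiration(tr)
  s2 <- analyze_respiration(back)
  expect_equal(s1$tidal_volume_ml, s2$tidal_volume_ml, tolerance = 1e-6)
})
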