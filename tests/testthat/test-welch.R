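test_that("the summary-statistic Welch test matches published worked example", {
  # expiratory time comparison from a two-group respiratory table
  w <- welch_from_summary(254.05, 28.25, 8, 218.26, 33.70, 8)
  expect_equal(round(w$p_two_sided, 3), 0.038)
  expect_true(w$significant)
  expect_lt(w$df, 14)
  expect_gt(w$df, 13)
})

test_that("equal means give t = 0 and p = 1; degenerate variances warn", {
  w <- welch_from_summary(5, 1, 8, 5, 2, 9)
  expect_equal(w$t_statistic, 0)
  expect_equal(w$p_two_sided, 1)
  w0 <- welch_from_summary(5, 0, 8, 5, 0, 8)
  expect_equal(w0$p_two_sided, 1)
  expect_warning(wd <- welch_from_summary(5, 0, 8, 6, 0, 8), "zero variance")
  expect_equal(wd$p_two_sided, 0)
})

test_that("p matches an independent numerical-integration oracle of the t density", {
  cases <- list(c(10, 2, 8, 8.5, 3, 7), c(-689, 134, 8, -1085, 346, 8),
                c(1, 1, 5, 1.2, 0.5, 12))
  for (cs in cases) {
    w <- welch_from_summary(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    dens <- function(x) {
      gamma((w$df + 1) / 2) / (sqrt(w$df * pi) * gamma(w$df / 2)) *
        (1 + x^2 / w$df)^(-(w$df + 1) / 2)
    }
    p_num <- 2 * integrate(dens, abs(w$t_statistic), Inf,
                           rel.tol = 1e-10)$value
    expect_equal(w$p_two_sided, p_num, tolerance = 1e-6)
  }
})

test_that("antisymmetry, scale invariance and monotonicity hold", {
  w1 <- welch_from_summary(10, 2, 8, 12, 3, 7)
  w2 <- welch_from_summary(12, 3, 7, 10, 2, 8)
  expect_equal(w1$t_statistic, -w2$t_statistic)
  expect_identical(w1$p_two_sided, w2$p_two_sided)
  for (k in c(0.01, 3, 1000)) {
    wk <- welch_from_summary(10 * k, 2 * k, 8, 12 * k, 3 * k, 7)
    expect_equal(wk$t_statistic, w1$t_statistic, tolerance = 1e-12)
    expect_equal(wk$p_two_sided, w1$p_two_sided, tolerance = 1e-12)
  }
  deltas <- seq(0.5, 5, by = 0.5)
  ps <- vapply(deltas, function(dl) {
    welch_from_summary(10, 2, 8, 10 + dl, 3, 7)$p_two_sided
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("sample-based Welch equals both its own summaries and stats::t.test", {
  set.seed(99)
  x <- rnorm(9, 5, 2)
  y <- rnorm(12, 6, 1)
  ws <- welch_from_samples(x, y)
  wm <- welch_from_summary(mean(x), sd(x), 9, mean(y), sd(y), 12)
  expect_equal(ws$p_two_sided, wm$p_two_sided, tolerance = 1e-12)
  # independent cross-check against the reference implementation
  tt <- t.test(x, y)
  expect_equal(ws$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ws$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(ws$p_two_sided, tt$p.value, tolerance = 1e-12)
  expect_equal(welch_from_samples(x, x)$p_two_sided, 1)
  expect_error(welch_from_samples(1, c(1, 2)), "at least 2")
})

test_that("tidy and glance return one-row summaries", {
  w <- welch_from_summary(10, 2, 8, 12, 3, 7)
  td <- tidy(w)
  expect_equal(nrow(td), 1)
  expect_equal(td$p.value, w$p_two_sided)
  gl <- glance(w)
  expect_named(gl, c("statistic", "df", "p.value", "n1", "n2", "significant"))
})

test_that("comparison reports flag significance at the 0.05 level", {
  mt <- tibble::tibble(
    metric = c("just_in", "just_out"),
    mean1 = c(0, 0), sd1 = c(1, 1), n1 = c(20, 20),
    mean2 = c(0.648, 0.6345), sd2 = c(1, 1), n2 = c(20, 20)
  )
  rep1 <- comparison_report(mt)
  expect_equal(nrow(rep1), 2)
  # p straddles 0.05 by construction of the mean separation
  expect_true(rep1$p_value[1] < 0.05 && rep1$significant[1])
  expect_true(rep1$p_value[2] > 0.05 && !rep1$significant[2])
  # holm adjustment is available but off by default
  rep2 <- comparison_report(mt, adjust = "holm")
  expect_true("p_adjusted" %in% names(rep2))
})

test_that("a structural weight-style row reproduces from raw synthetic samples", {
  set.seed(7)
  wt <- rnorm(8, 22.23, 2.83)
  dp <- rnorm(8, 20.40, 3.27)
  rep1 <- comparison_report(tibble::tibble(
    metric = "weight_g", mean1 = mean(wt), sd1 = sd(wt), n1 = 8,
    mean2 = mean(dp), sd2 = sd(dp), n2 = 8
  ))
  expect_equal(rep1$p_value, welch_from_samples(wt, dp)$p_two_sided,
               tolerance = 1e-12)
})
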