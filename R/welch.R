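#' Welch's unequal-variance t-test from summary statistics
#'
#' Computes the two-sided Welch test directly from per-group mean, SD and n:
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch–Satterthwaite degrees of freedom
#' \deqn{\nu = (s_1^2/n_1 + s_2^2/n_2)^2 /
#'   [(s_1^2/n_1)^2/(n_1-1) + (s_2^2/n_2)^2/(n_2-1)].}
#' This is the form needed to recompute P values from published group
#' summary tables without raw data.
#'
#' Degenerate variances: with both SDs zero and equal means, `t = 0`,
#' `p = 1`; with both SDs zero and unequal means, `p = 0` with a warning.
#'
#' @param mean1,sd1,n1 first group's mean, SD and size (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 second group.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return a `welch_test` object: `t_statistic`, `df`, `p_two_sided`,
#'   `significant`, plus the inputs.
#' @examples
#' # expiratory time (ms): group summaries straight from a printed table
#' welch_from_summary(254.05, 28.25, 8, 218.26, 33.70, 8)
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  if (se1 + se2 == 0) {
    if (mean1 == mean2) {
      t_stat <- 0
      df <- n1 + n2 - 2
      p <- 1
    } else {
      warning("both groups have zero variance and different means; p = 0",
              call. = FALSE)
      t_stat <- sign(mean1 - mean2) * Inf
      df <- n1 + n2 - 2
      p <- 0
    }
  } else {
    t_stat <- (mean1 - mean2) / sqrt(se1 + se2)
    df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(
    list(t_statistic = t_stat, df = df, p_two_sided = p,
         significant = is.finite(p) && p < alpha, alpha = alpha,
         mean1 = mean1, sd1 = sd1, n1 = n1,
         mean2 = mean2, sd2 = sd2, n2 = n2),
    class = "welch_test"
  )
}

#' Welch's t-test from raw samples
#'
#' Identical, by definition, to [welch_from_summary()] applied to the
#' samples' own means, SDs and sizes.
#'
#' @param x,y numeric samples, each of length >= 2 (NAs dropped).
#' @param alpha significance level for the `significant` flag.
#' @return a `welch_test` object.
#' @export
welch_from_samples <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  }
  welch_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
                     alpha = alpha)
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf(
    "Welch two-sample t-test\n  t = %.4f, df = %.3f, p = %.6g%s\n  group 1: %.6g +/- %.6g (n = %d)\n  group 2: %.6g +/- %.6g (n = %d)\n",
    x$t_statistic, x$df, x$p_two_sided,
    if (x$significant) sprintf(" (significant at %.3g)", x$alpha) else "",
    x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  invisible(x)
}

#' @rdname welch_from_summary
#' @param x a `welch_test`.
#' @param ... unused.
#' @export
tidy.welch_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean1 - x$mean2,
    statistic = x$t_statistic,
    df = x$df,
    p.value = x$p_two_sided,
    method = "Welch two-sample t-test"
  )
}

#' @rdname welch_from_summary
#' @export
glance.welch_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$t_statistic, df = x$df, p.value = x$p_two_sided,
    n1 = x$n1, n2 = x$n2, significant = x$significant
  )
}

#' Per-metric Welch comparison report
#'
#' One Welch test per row of a summary table — the engine behind group
#' comparison tables that print `Mean  SD  Mean  SD  P` per metric. No
#' multiple-testing adjustment is applied by default (each metric is reported
#' at the nominal level, as such tables conventionally are); Holm adjustment
#' is available via `adjust`.
#'
#' @param metric_table data frame with columns `metric`, `mean1`, `sd1`,
#'   `n1`, `mean2`, `sd2`, `n2`.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return tibble: inputs plus `t_statistic`, `df`, `p_value`, `significant`.
#' @export
comparison_report <- function(metric_table, alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  mt <- tibble::as_tibble(metric_table)
  req <- c("metric", "mean1", "sd1", "n1", "mean2", "sd2", "n2")
  stopifnot(all(req %in% names(mt)), nrow(mt) >= 1)
  res <- purrr::pmap(mt[req[-1]], function(mean1, sd1, n1, mean2, sd2, n2) {
    w <- welch_from_summary(mean1, sd1, n1, mean2, sd2, n2, alpha = alpha)
    tibble::tibble(t_statistic = w$t_statistic, df = w$df, p_value = w$p_two_sided)
  })
  out <- dplyr::bind_cols(mt[req], dplyr::bind_rows(res))
  if (adjust == "holm") {
    out$p_adjusted <- p.adjust(out$p_value, method = "holm")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

#' @importFrom stats p.adjust
NULL
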