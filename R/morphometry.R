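#' Default craniofacial landmark-pair battery
#'
#' The 26-measure linear-distance battery: 23 skull and mandible distances
#' (measures `a`–`w`) between numbered landmarks 1–26, plus the three
#' hyoid-position distances (`x`, `y`, `z`) among landmark 17 (caudal edge of
#' the hard palate region), 27 (ventral point on the basisphenoid–occipital
#' suture) and 28 (hyoid). Landmarks are abstract ids placed by the user (or
#' a phantom); the battery itself is purely geometric.
#'
#' @return tibble with columns `measure`, `id_a`, `id_b`.
#' @export
default_landmark_pairs <- function() {
  tibble::tribble(
    ~measure, ~id_a, ~id_b,
    "a", 1L, 3L, "b", 3L, 6L, "c", 6L, 9L, "d", 2L, 4L,
    "e", 5L, 7L, "f", 8L, 10L,
    "g", 11L, 15L, "h", 12L, 16L, "i", 15L, 16L, "j", 13L, 18L,
    "k", 13L, 14L, "l", 14L, 17L,
    "m", 1L, 18L, "n", 3L, 13L,
    "o", 19L, 21L, "p", 20L, 22L, "q", 21L, 23L, "r", 22L, 24L,
    "s", 19L, 23L, "t", 20L, 24L, "u", 23L, 25L, "v", 24L, 26L,
    "w", 23L, 24L,
    "x", 17L, 28L, "y", 17L, 27L, "z", 27L, 28L
  )
}

#' Euclidean landmark distances
#'
#' Computes the mm distance for every measure in `pair_map` from a single
#' subject's landmark set. Any measure referencing a missing landmark yields
#' `NA` (recorded, not an error) so that per-measure exclusion downstream
#' works the way published cohorts handle unusable subjects.
#'
#' @param landmarks data frame with columns `id` (integer or name) and
#'   `x_mm`, `y_mm`, `z_mm`; optional `subject_id` / `group` columns are
#'   carried through.
#' @param pair_map data frame with `measure`, `id_a`, `id_b`
#'   (default: [default_landmark_pairs()]).
#' @return a distance table tibble: `measure`, `distance_mm`, plus any
#'   `subject_id` / `group` metadata.
#' @examples
#' lm <- tibble::tibble(id = 1:2, x_mm = c(0, 1), y_mm = c(0, 1), z_mm = c(0, 1))
#' measure_distances(lm, tibble::tibble(measure = "diag", id_a = 1, id_b = 2))
#' @export
measure_distances <- function(landmarks, pair_map = default_landmark_pairs()) {
  lm <- tibble::as_tibble(landmarks)
  stopifnot(all(c("id", "x_mm", "y_mm", "z_mm") %in% names(lm)))
  coords <- setNames(
    lapply(seq_len(nrow(lm)), function(i) as.numeric(lm[i, c("x_mm", "y_mm", "z_mm")])),
    as.character(lm$id)
  )
  dist_one <- function(a, b) {
    pa <- coords[[as.character(a)]]
    pb <- coords[[as.character(b)]]
    if (is.null(pa) || is.null(pb) || anyNA(pa) || anyNA(pb)) {
      message("measure skipped: landmark ", if (is.null(pa) || anyNA(pa)) a else b,
              " missing")
      return(NA_real_)
    }
    sqrt(sum((pa - pb)^2))
  }
  out <- tibble::tibble(
    measure = pair_map$measure,
    distance_mm = purrr::map2_dbl(pair_map$id_a, pair_map$id_b, dist_one)
  )
  for (meta in c("subject_id", "group")) {
    if (meta %in% names(lm)) out[[meta]] <- lm[[meta]][1]
  }
  out
}

#' Hyoid position metrics
#'
#' Three distances characterising rostrocaudal and ventrocaudal hyoid
#' displacement: `x = |17-28|`, `y = |17-27|`, `z = |27-28|` (mm), where 17
#' is the caudal hard-palate landmark, 27 the ventral basisphenoid–occipital
#' suture point and 28 the hyoid. Any missing landmark makes the affected
#' metrics `NA`.
#'
#' @param landmarks as in [measure_distances()]; must contain ids 17, 27, 28
#'   for a complete result.
#' @return tibble with one row: `x_mm`, `y_mm`, `z_mm`.
#' @export
hyoid_metrics <- function(landmarks) {
  d <- measure_distances(
    landmarks,
    tibble::tibble(measure = c("x", "y", "z"),
                   id_a = c(17L, 17L, 27L), id_b = c(28L, 27L, 28L))
  )
  tibble::tibble(
    x_mm = d$distance_mm[d$measure == "x"],
    y_mm = d$distance_mm[d$measure == "y"],
    z_mm = d$distance_mm[d$measure == "z"]
  )
}

#' Two-group comparison of per-subject distance tables
#'
#' Takes one wide distance table per group (one row per subject, one column
#' per measure, as produced by [make_morphometry_cohort()] or by stacking
#' [measure_distances()] outputs) and runs a Welch test per measure. Subjects
#' with a missing value are excluded per measure, not per subject, so a
#' single unusable measurement (the way a cohort might lose one animal's
#' bone battery) reduces that measure's n only. Measures with fewer than two
#' valid subjects in either group are flagged untestable (`NA` statistics).
#'
#' @param tables_g1,tables_g2 wide tibbles: `subject_id` plus numeric measure
#'   columns (mm).
#' @param alpha significance level.
#' @return tibble: `measure`, `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`,
#'   `t_statistic`, `df`, `p_value`, `significant`, `untestable`.
#' @export
cohort_compare <- function(tables_g1, tables_g2, alpha = 0.05) {
  g1 <- tibble::as_tibble(tables_g1)
  g2 <- tibble::as_tibble(tables_g2)
  measures <- intersect(setdiff(names(g1), "subject_id"),
                        setdiff(names(g2), "subject_id"))
  if (length(measures) == 0) stop("no shared measures between groups", call. = FALSE)
  rows <- purrr::map(measures, function(mname) {
    x <- g1[[mname]][!is.na(g1[[mname]])]
    y <- g2[[mname]][!is.na(g2[[mname]])]
    base <- tibble::tibble(
      measure = mname,
      mean1 = if (length(x)) mean(x) else NA_real_, sd1 = if (length(x) > 1) sd(x) else NA_real_,
      n1 = length(x),
      mean2 = if (length(y)) mean(y) else NA_real_, sd2 = if (length(y) > 1) sd(y) else NA_real_,
      n2 = length(y)
    )
    if (length(x) < 2 || length(y) < 2) {
      return(dplyr::mutate(base, t_statistic = NA_real_, df = NA_real_,
                           p_value = NA_real_, significant = NA,
                           untestable = TRUE))
    }
    w <- welch_from_samples(x, y, alpha = alpha)
    dplyr::mutate(base, t_statistic = w$t_statistic, df = w$df,
                  p_value = w$p_two_sided, significant = w$significant,
                  untestable = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Read / write landmark coordinate CSVs
#'
#' Layout: `id, x_mm, y_mm, z_mm` with optional leading `subject_id, group`
#' columns (multiple subjects may share one file).
#'
#' @param landmarks landmark data frame.
#' @param path CSV path.
#' @return `read_landmarks()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(as.data.frame(landmarks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  if (!all(c("x_mm", "y_mm", "z_mm") %in% names(df))) {
    stop("landmark CSV needs x_mm, y_mm, z_mm columns", call. = FALSE)
  }
  df
}
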