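#' Specification of a two-group morphometry cohort
#'
#' Mirrors the structure of a published craniofacial summary table: one row
#' per linear measure with per-group mean and SD (mm) and per-group sample
#' sizes. [make_morphometry_cohort()] draws independent normal deviates with
#' exactly these moments.
#'
#' @param measures data frame with columns `measure`, `mean_g1`, `sd_g1`,
#'   `mean_g2`, `sd_g2` (mm; SDs >= 0).
#' @param n_g1,n_g2 integer group sizes (>= 2).
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(measures, n_g1 = 8, n_g2 = 8, seed = 1L) {
  measures <- tibble::as_tibble(measures)
  req <- c("measure", "mean_g1", "sd_g1", "mean_g2", "sd_g2")
  stopifnot(all(req %in% names(measures)),
            all(measures$sd_g1 >= 0), all(measures$sd_g2 >= 0),
            n_g1 >= 2, n_g2 >= 2)
  structure(
    list(measures = measures, n_g1 = as.integer(n_g1), n_g2 = as.integer(n_g2),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate per-subject distance tables for two groups
#'
#' Every (measure, subject) value is an independent draw from the normal
#' distribution with the group's specified mean and SD. Reproducible under
#' the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `g1` and `g2`, each a wide tibble: one row per
#'   subject (`subject_id`) and one column per measure (values in mm).
#' @examples
#' sp <- cohort_spec(
#'   tibble::tibble(measure = "b", mean_g1 = 7.93, sd_g1 = 0.17,
#'                  mean_g2 = 7.33, sd_g2 = 0.20),
#'   n_g1 = 8, n_g2 = 7, seed = 42
#' )
#' make_morphometry_cohort(sp)$g1
#' @export
make_morphometry_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$measures
  with_seed(spec$seed, {
    draw <- function(n, means, sds, prefix) {
      vals <- lapply(seq_len(nrow(m)), function(i) rnorm(n, means[i], sds[i]))
      names(vals) <- m$measure
      tibble::as_tibble(c(
        list(subject_id = sprintf("%s%02d", prefix, seq_len(n))), vals
      ))
    }
    g1 <- draw(spec$n_g1, m$mean_g1, m$sd_g1, "g1_")
    g2 <- draw(spec$n_g2, m$mean_g2, m$sd_g2, "g2_")
    list(g1 = g1, g2 = g2)
  })
}
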