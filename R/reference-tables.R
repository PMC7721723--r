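# Published group summary statistics for the Dp(16)1Yey (Dp16) upper-airway
# study, transcribed as code so that analyses can start from printed tables
# when raw data are unavailable. Values are mean/SD per genotype; units mm
# unless noted. WT n = 8 throughout; Dp16 n = 8 for respiratory and CFD
# measures and n = 7 for the bone battery (one animal excluded for
# hydrocephalus).

#' Reference craniofacial measurement table (WT vs Dp16)
#'
#' The 26-measure linear-distance battery (skull measures `a`-`n`, mandible
#' `o`-`w`, hyoid position `x`-`z`) with per-genotype mean and SD in mm, the
#' landmark pair behind each measure, group sizes, and the published P value
#' (`p_printed`; `< 0.001` entries are stored as 0.001 in `p_printed_lt`
#' form via the `p_lt` flag).
#'
#' @return a tibble, one row per measure.
#' @export
reference_craniofacial <- function() {
  tbl <- tibble::tribble(
    ~measure, ~id_a, ~id_b, ~mean_wt, ~sd_wt, ~mean_dp16, ~sd_dp16, ~p_printed, ~p_lt,
    "a", 1L, 3L, 7.09, 0.20, 7.03, 0.19, 0.584, FALSE,
    "b", 3L, 6L, 7.93, 0.17, 7.33, 0.20, 0.001, TRUE,
    "c", 6L, 9L, 3.82, 0.15, 3.69, 0.28, 0.344, FALSE,
    "d", 2L, 4L, 4.20, 0.06, 3.78, 0.05, 0.001, TRUE,
    "e", 5L, 7L, 5.98, 0.19, 6.00, 0.16, 0.831, FALSE,
    "f", 8L, 10L, 7.88, 0.19, 7.53, 0.27, 0.018, FALSE,
    "g", 11L, 15L, 7.41, 0.17, 6.84, 0.07, 0.001, TRUE,
    "h", 12L, 16L, 7.42, 0.19, 6.79, 0.09, 0.001, TRUE,
    "i", 15L, 16L, 3.40, 0.04, 3.19, 0.09, 0.001, TRUE,
    "j", 13L, 18L, 5.27, 0.14, 4.74, 0.26, 0.001, TRUE,
    "k", 13L, 14L, 3.75, 0.12, 3.37, 0.21, 0.001, FALSE,
    "l", 14L, 17L, 2.11, 0.05, 1.92, 0.08, 0.001, FALSE,
    "m", 1L, 18L, 2.66, 0.09, 2.51, 0.05, 0.002, FALSE,
    "n", 3L, 13L, 4.78, 0.11, 4.66, 0.16, 0.125, FALSE,
    "o", 19L, 21L, 5.10, 0.11, 4.75, 0.15, 0.001, TRUE,
    "p", 20L, 22L, 5.10, 0.14, 4.66, 0.15, 0.001, TRUE,
    "q", 21L, 23L, 6.86, 0.13, 6.47, 0.18, 0.001, TRUE,
    "r", 22L, 24L, 6.92, 0.12, 6.53, 0.18, 0.001, TRUE,
    "s", 19L, 23L, 8.57, 0.11, 7.92, 0.19, 0.001, TRUE,
    "t", 20L, 24L, 8.57, 0.19, 7.96, 0.21, 0.001, TRUE,
    "u", 23L, 25L, 3.93, 0.14, 3.86, 0.17, 0.360, FALSE,
    "v", 24L, 26L, 3.87, 0.12, 3.85, 0.18, 0.766, FALSE,
    "w", 23L, 24L, 9.46, 0.14, 9.06, 0.25, 0.005, FALSE,
    "x", 17L, 28L, 4.99, 0.12, 4.70, 0.07, 0.001, TRUE,
    "y", 17L, 27L, 4.18, 0.14, 3.33, 0.19, 0.001, TRUE,
    "z", 27L, 28L, 2.79, 0.12, 2.79, 0.13, 1.000, FALSE
  )
  tbl$n_wt <- 8L
  tbl$n_dp16 <- 7L
  tbl
}

#' Reference respiratory and CFD summaries (WT vs Dp16)
#'
#' Group summary statistics for the measures whose P values are quoted in
#' the study text: expiratory and inspiratory time (ms), nasal and pharyngeal
#' maximum airflow speed (m/s), maximum negative pressure at the epiglottis
#' (Pa), nasal and pharyngeal airway volumes (mm^3), pharyngeal length (mm)
#' and body weight (g). `n` is 8 per genotype.
#'
#' @return a tibble, one row per metric.
#' @export
reference_flow_respiratory <- function() {
  tibble::tribble(
    ~metric, ~unit, ~mean_wt, ~sd_wt, ~mean_dp16, ~sd_dp16, ~p_printed, ~p_lt,
    "expiratory_time", "ms", 254.05, 28.25, 218.26, 33.70, 0.038, FALSE,
    "inspiratory_time", "ms", 80.61, 17.83, 78.12, 8.03, 0.727, FALSE,
    "vmax_nasal", "m/s", 12.26, 4.28, 14.76, 6.25, 0.369, FALSE,
    "vmax_pharyngeal", "m/s", 12.29, 1.16, 17.63, 2.63, 0.001, TRUE,
    "pmax", "Pa", -689, 134, -1085, 346, 0.015, FALSE,
    "v_nasal", "mm3", 18.56, 3.22, 14.49, 2.5, 0.020, FALSE,
    "v_pharyngeal", "mm3", 5.13, 0.78, 3.39, 0.80, 0.001, TRUE,
    "pharyngeal_length", "mm", 5.80, 0.23, 5.53, 0.15, 0.014, FALSE,
    "weight", "g", 22.23, 2.83, 20.40, 3.27, 0.251, FALSE
  ) |>
    dplyr::mutate(n_wt = 8L, n_dp16 = 8L)
}

#' Mean peak inspiratory flow used as the constant simulation flow rate
#'
#' The cohort mean of peak inspiratory flow from plethysmography, 5.28 ml/s,
#' applied identically to every airway so that simulated pressures reflect
#' geometry alone.
#'
#' @return scalar, ml/s.
#' @export
reference_flow_rate_ml_s <- function() 5.28
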