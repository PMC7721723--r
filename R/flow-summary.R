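#' Summarise an airflow solution over the airway segments
#'
#' Extracts the standard inspiratory report: maximum speed in the nasal
#' cavity (nostrils to meatus merge) and in the pharyngeal airway
#' (hard-palate edge to epiglottis), the station pressure at the epiglottis
#' (`pmax`, negative under inspiration with the nostrils at 0 Pa), and the
#' per-segment pressure drops `p_nasal` (nostrils to meatus merge), `p_hard`
#' (meatus merge to hard-palate edge) and `p_soft` (hard-palate edge to
#' epiglottis). The three drops telescope exactly:
#' `p_nasal + p_hard + p_soft = pmax - inlet pressure`.
#'
#' Station pressures are cross-section averages (for the 3D solver: the mean
#' over lumen voxels within half a voxel of the station arclength), which is
#' robust to single-voxel extremes; the pointwise minimum pressure is also
#' reported for the 3D solver. Speeds within two hydraulic diameters of the
#' outlet are excluded from the pharyngeal maximum to avoid the Dirichlet
#' outlet-face artefact.
#'
#' @param solution a `flow_1d` or `flow_3d` solution.
#' @param segments an `airway_segments` from [partition_segments()] (for
#'   simple tubes, construct one with arclengths directly).
#' @param epiglottis_station arclength of the epiglottis station, mm
#'   (default `segments$s_epiglottis`).
#' @param centerline required for `flow_3d`: the centerline used to bin
#'   voxels by arclength.
#' @param volumes optional tibble from [segment_volumes()] merged into the
#'   report.
#' @param pharyngeal_length_mm optional scalar merged into the report.
#' @param ... passed to methods.
#' @return a `flow_summary` tibble (one row).
#' @export
summarize_flow <- function(solution, segments, ...) {
  UseMethod("summarize_flow")
}

flow_summary_row <- function(vmax_nasal, vmax_phar, pmax, p_inlet,
                             p_meatus, p_palate,
                             volumes = NULL, pharyngeal_length_mm = NULL,
                             pmax_pointwise = NA_real_) {
  out <- tibble::tibble(
    vmax_nasal_m_s = vmax_nasal,
    vmax_pharyngeal_m_s = vmax_phar,
    pmax_pa = pmax,
    pmax_pointwise_pa = pmax_pointwise,
    p_nasal_pa = p_meatus - p_inlet,
    p_hard_pa = p_palate - p_meatus,
    p_soft_pa = pmax - p_palate
  )
  if (!is.null(volumes)) out <- dplyr::bind_cols(out, volumes)
  if (!is.null(pharyngeal_length_mm)) out$pharyngeal_length_mm <- pharyngeal_length_mm
  class(out) <- c("flow_summary", class(out))
  out
}

#' @rdname summarize_flow
#' @export
summarize_flow.flow_1d <- function(solution, segments,
                                   epiglottis_station = segments$s_epiglottis,
                                   volumes = NULL, pharyngeal_length_mm = NULL,
                                   ...) {
  stopifnot(inherits(segments, "airway_segments"))
  s <- solution$s_mm
  rng <- range(s)
  stations <- c(segments$s_meatus_merge, segments$s_hard_palate, epiglottis_station)
  if (any(stations < rng[1] - 1e-9 | stations > rng[2] + 1e-9)) {
    stop("range error: stations outside the solved arclength range", call. = FALSE)
  }
  p_at <- function(st) approx(s, solution$pressure_pa, xout = st, rule = 2)$y
  v_in <- function(lo, hi) max(solution$velocity_m_s[s >= lo - 1e-9 & s <= hi + 1e-9])
  bc <- attr(solution, "bc")
  flow_summary_row(
    vmax_nasal = v_in(rng[1], segments$s_meatus_merge),
    vmax_phar = v_in(segments$s_hard_palate, epiglottis_station),
    pmax = p_at(epiglottis_station),
    p_inlet = bc$inlet_pressure_pa,
    p_meatus = p_at(segments$s_meatus_merge),
    p_palate = p_at(segments$s_hard_palate),
    volumes = volumes, pharyngeal_length_mm = pharyngeal_length_mm
  )
}

#' @rdname summarize_flow
#' @export
summarize_flow.flow_3d <- function(solution, segments, centerline,
                                   epiglottis_station = segments$s_epiglottis,
                                   volumes = NULL, pharyngeal_length_mm = NULL,
                                   ...) {
  stopifnot(inherits(segments, "airway_segments"))
  mask <- solution$mask
  s_vox <- voxel_arclengths(mask, centerline)
  vox <- which(mask$voxels)
  speed <- solution$speed_m_s[vox]
  pres <- solution$pressure_pa[vox]
  h_mm <- solution$h_m * 1e3

  if (epiglottis_station > max(s_vox, na.rm = TRUE) + h_mm ||
      epiglottis_station < min(s_vox, na.rm = TRUE) - h_mm) {
    stop("range error: epiglottis station outside the solution domain", call. = FALSE)
  }

  # exclude the outlet-adjacent region from Vmax extraction
  d_h_mm <- 2 * sqrt(solution$n_outlet_faces * h_mm^2 / pi)
  s_cap <- max(s_vox, na.rm = TRUE) - 2 * d_h_mm
  vmax_in <- function(lo, hi) {
    sel <- !is.na(s_vox) & s_vox >= lo & s_vox <= min(hi, s_cap)
    if (!any(sel)) return(NA_real_)
    max(speed[sel])
  }
  station_p <- function(st) {
    sel <- !is.na(s_vox) & abs(s_vox - st) <= h_mm / 2
    if (!any(sel)) sel <- !is.na(s_vox) & abs(s_vox - st) <= h_mm
    mean(pres[sel])
  }
  flow_summary_row(
    vmax_nasal = vmax_in(0, segments$s_meatus_merge),
    vmax_phar = vmax_in(segments$s_hard_palate, epiglottis_station),
    pmax = station_p(epiglottis_station),
    p_inlet = solution$bc$inlet_pressure_pa,
    p_meatus = station_p(segments$s_meatus_merge),
    p_palate = station_p(segments$s_hard_palate),
    volumes = volumes, pharyngeal_length_mm = pharyngeal_length_mm,
    pmax_pointwise = min(pres)
  )
}
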