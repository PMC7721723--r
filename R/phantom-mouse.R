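# Parametric mouse upper-airway phantom: not an anatomical atlas, but a tube
# with a mouse-like area profile, an optional paired-nostril split rostrally,
# and the six functional landmarks that anchor segment partition and flow
# summaries (nostrils, meatus merge, hard palate caudal edge, epiglottis,
# arytenoid).

#' Default configuration for the mouse upper-airway phantom
#'
#' Arclength positions (mm, measured caudally from the nostrils) and the
#' cross-sectional area profile are chosen to echo the scale of an adult
#' wild-type mouse: nasal cavity volume near 18.6 mm^3, pharyngeal volume
#' (hard palate to 5 mm caudal) near 5 mm^3, pharyngeal length (hard palate
#' to arytenoid) 5.8 mm, and the narrowest cross-section 1 mm caudal to the
#' hard palate edge.
#'
#' @param scale linear scale factor applied to cross-sections only; areas
#'   scale as `scale^2` while lengths are unchanged (a simple "genotype"
#'   knob: 1 for the baseline, < 1 for a uniformly narrowed airway).
#' @param split logical; model the rostral airway as paired left/right nasal
#'   passages that merge at the nasopharyngeal meatus confluence.
#' @param bend_amplitude_mm amplitude of a gentle dorsoventral bow of the
#'   central axis (0 = straight). Small relative to segment lengths so that
#'   axial planes remain near-perpendicular.
#' @return named list of configuration values.
#' @export
mouse_airway_config <- function(scale = 1, split = TRUE, bend_amplitude_mm = 0) {
  stopifnot(scale > 0, bend_amplitude_mm >= 0)
  list(
    s_meatus_merge = 7,
    s_hard_palate = 11,
    s_epiglottis = 16,
    s_arytenoid = 16.8,
    s_total = 17,
    area_knots_s = c(0, 3, 7, 9, 11, 12, 14, 16, 17),
    area_knots_mm2 = c(0.7, 1.9, 2.2, 1.6, 1.2, 0.85, 1.0, 1.1, 1.1),
    split = split,
    split_offset_mm = 0.8,
    scale = scale,
    bend_amplitude_mm = bend_amplitude_mm
  )
}

# union area of two circles of radius r with centres 2*d apart
two_circle_union <- function(r, d) {
  D <- 2 * d
  out <- rep(2 * pi * r^2, length(r))
  ov <- D < 2 * r
  if (any(ov)) {
    ri <- r[ov]
    Di <- pmin(D[ov], 2 * ri)
    lens <- 2 * ri^2 * acos(Di / (2 * ri)) - (Di / 2) * sqrt(pmax(4 * ri^2 - Di^2, 0))
    out[ov] <- 2 * pi * ri^2 - lens
  }
  out
}

# lobe radius such that the union of the two offset circles has area `target`
lobe_radius_for_area <- function(target, d) {
  vapply(seq_along(target), function(i) {
    lo <- sqrt(target[i] / (2 * pi))      # disjoint circles
    hi <- sqrt(target[i] / pi) + d[i]     # single circle upper bound
    if (d[i] <= 1e-12) return(sqrt(target[i] / pi))
    uniroot(function(r) two_circle_union(r, d[i]) - target[i],
            lower = lo * 0.999, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

#' Parametric mouse upper-airway phantom
#'
#' Builds a CT-like volume, the ground-truth lumen mask, a landmark table and
#' a [phantom_truth] whose area profile is exact by construction: at every
#' arclength the lumen cross-section (single circle, or union of two offset
#' circles in the split rostral region) is sized to realise the configured
#' area profile exactly. Per-segment volumes and the pharyngeal length are
#' recorded as ground truth.
#'
#' @param config configuration list from [mouse_airway_config()].
#' @param spacing_mm voxel spacing, mm (isotropic by default; the native
#'   micro-CT scale of 0.02 mm gives ~20M voxels — coarser grids are adequate
#'   for most validation work).
#' @param seed optional integer; reserved for reproducibility of any
#'   stochastic options (the default phantom is deterministic).
#' @return list with `volume` ([volume3d]), `mask` ([binary_mask]),
#'   `landmarks` (tibble: name, x_mm, y_mm, z_mm) and `truth`
#'   ([phantom_truth]; `truth$extra` holds `v_nasal_true_mm3`,
#'   `v_pharyngeal_true_mm3` and `pharyngeal_length_true_mm`).
#' @export
make_mouse_airway_phantom <- function(config = mouse_airway_config(),
                                      spacing_mm = 0.02, seed = NULL) {
  cf <- config
  area_at <- function(s) {
    approx(cf$area_knots_s, cf$area_knots_mm2, xout = s, rule = 2)$y * cf$scale^2
  }
  offset_at <- function(s) {
    if (!cf$split) return(rep(0, length(s)))
    cf$split_offset_mm * cf$scale * pmax(0, 1 - s / cf$s_meatus_merge)
  }
  yc_at <- function(s) {
    if (cf$bend_amplitude_mm == 0) return(rep(0, length(s)))
    cf$bend_amplitude_mm * sin(pi * s / cf$s_total)
  }

  max_r <- sqrt(max(cf$area_knots_mm2) * cf$scale^2 / pi) + offset_at(0) + 0.2
  lower <- c(-max_r, -max_r - cf$bend_amplitude_mm, 0)
  upper <- c(max_r, max_r + cf$bend_amplitude_mm, cf$s_total)

  predicate <- function(pts) {
    z <- pts[, 3]
    inside_span <- z >= 0 & z <= cf$s_total
    out <- rep(FALSE, nrow(pts))
    if (!any(inside_span)) return(out)
    zz <- z[inside_span]
    d <- offset_at(zz)
    rl <- lobe_radius_for_area_cached(area_at(zz), d)
    yc <- yc_at(zz)
    x <- pts[inside_span, 1]
    y <- pts[inside_span, 2] - yc
    left <- (x + d)^2 + y^2 <= rl^2
    right <- (x - d)^2 + y^2 <= rl^2
    out[inside_span] <- left | right
    out
  }
  bone_predicate <- function(pts) {
    z <- pts[, 3]
    inside_span <- z >= 0 & z <= cf$s_hard_palate
    out <- rep(FALSE, nrow(pts))
    if (!any(inside_span)) return(out)
    zz <- z[inside_span]
    d <- offset_at(zz)
    rl <- lobe_radius_for_area_cached(area_at(zz), d)
    yc <- yc_at(zz)
    x <- pts[inside_span, 1]
    y <- pts[inside_span, 2] - yc
    dist_l <- sqrt((x + d)^2 + y^2) - rl
    dist_r <- sqrt((x - d)^2 + y^2) - rl
    near_wall <- pmin(dist_l, dist_r)
    out[inside_span] <- near_wall > 0 & near_wall <= 0.3
    out
  }

  # memoise lobe radii on the slice grid: z values repeat within a slice
  radius_cache <- new.env(parent = emptyenv())
  lobe_radius_for_area_cached <- function(target, d) {
    if (all(target == target[1]) && all(d == d[1])) {
      key <- sprintf("%.12g_%.12g", target[1], d[1])
      hit <- radius_cache[[key]]
      if (is.null(hit)) {
        hit <- lobe_radius_for_area(target[1], d[1])
        radius_cache[[key]] <- hit
      }
      return(rep(hit, length(target)))
    }
    lobe_radius_for_area(target, d)
  }

  ras <- rasterize_phantom(lower, upper, spacing_mm, predicate, bone_predicate)

  lm_points <- function(s, x = 0) c(x, yc_at(s), s)
  d0 <- offset_at(0)
  landmarks <- tibble::tibble(
    name = c("nostril_left", "nostril_right", "meatus_merge",
             "hard_palate_edge", "epiglottis", "arytenoid"),
    x_mm = c(-d0, d0, 0, 0, 0, 0),
    y_mm = yc_at(c(0, 0, cf$s_meatus_merge, cf$s_hard_palate,
                   cf$s_epiglottis, cf$s_arytenoid)),
    z_mm = c(0, 0, cf$s_meatus_merge, cf$s_hard_palate,
             cf$s_epiglottis, cf$s_arytenoid)
  )
  inside <- sample_nearest(ras$mask, as.matrix(landmarks[, c("x_mm", "y_mm", "z_mm")]),
                           fill = FALSE)
  if (!all(inside)) {
    stop("phantom generation failed: landmarks outside the lumen mask: ",
         paste(landmarks$name[!inside], collapse = ", "), call. = FALSE)
  }

  # ground truth: the configured area profile is realised exactly, so volumes
  # are trapezoid integrals of the piecewise-linear profile (exact)
  s_knots <- sort(unique(c(cf$area_knots_s, cf$s_meatus_merge, cf$s_hard_palate,
                           cf$s_hard_palate + 5, cf$s_epiglottis, cf$s_arytenoid)))
  s_knots <- s_knots[s_knots <= cf$s_total]
  a_knots <- area_at(s_knots)
  trap <- function(s0, s1) {
    ss <- sort(unique(c(s_knots[s_knots >= s0 & s_knots <= s1], s0, s1)))
    aa <- area_at(ss)
    sum(diff(ss) * (head(aa, -1) + tail(aa, -1)) / 2)
  }
  v_total <- trap(0, cf$s_total)
  v_nasal <- trap(0, cf$s_hard_palate)
  v_phar <- trap(cf$s_hard_palate, min(cf$s_hard_palate + 5, cf$s_total))

  truth <- phantom_truth(
    "mouse_airway",
    tibble::tibble(s_mm = s_knots, area_mm2 = a_knots),
    volume_true_mm3 = v_total,
    length_true_mm = cf$s_total,
    landmark_truth = setNames(
      lapply(seq_len(nrow(landmarks)),
             function(i) as.numeric(landmarks[i, c("x_mm", "y_mm", "z_mm")])),
      landmarks$name
    ),
    extra = list(
      v_nasal_true_mm3 = v_nasal,
      v_pharyngeal_true_mm3 = v_phar,
      pharyngeal_length_true_mm = cf$s_arytenoid - cf$s_hard_palate,
      config = cf
    )
  )
  c(ras, list(landmarks = landmarks, truth = truth))
}
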