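# Curved-reformation measurements: cross-sections perpendicular to the
# centerline, station profiles anchored at a landmark, segment partition and
# per-segment volumes.

plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    n[2] * e1[3] - n[3] * e1[2],
    n[3] * e1[1] - n[1] * e1[3],
    n[1] * e1[2] - n[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

#' Perpendicular cross-section of a mask at a centerline station
#'
#' The mask is resampled (nearest neighbour) on a plane through the
#' centerline point at arclength `s_mm`, with plane normal equal to the local
#' centerline tangent and an in-plane grid pitch of half the voxel spacing.
#' The cross-sectional area is that of the in-plane connected region
#' containing the centerline point: pixel count times pixel area. This yields
#' the true perpendicular area, not the inflated area of an oblique axial
#' slice.
#'
#' @param mask a [binary_mask].
#' @param centerline a `centerline` covering `s_mm`.
#' @param s_mm arclength of the station, mm (within the centerline range).
#' @param pitch_mm in-plane sampling pitch; default half the smallest voxel
#'   spacing.
#' @param region `"centerline"` (default) measures the in-plane connected
#'   region containing the centerline point — the station area of
#'   curved-reformation morphometry. `"all"` counts every lumen pixel in the
#'   plane, which is the total duct area carried by parallel passages (e.g.
#'   paired nasal airways) and is the right quantity for reduced-order flow.
#' @return a `cross_section` list: `s_mm`, `plane_point_mm`, `plane_normal`,
#'   `area_mm2`, `n_pixels`, `pitch_mm`, `truncated` (TRUE when the in-plane
#'   region touched the sampling window or volume boundary), and `pixels_uv`
#'   (in-plane coordinates of the region, for contouring/plotting).
#' @export
cross_section_at <- function(mask, centerline, s_mm, pitch_mm = NULL,
                             region = c("centerline", "all")) {
  region_mode <- match.arg(region)
  stopifnot(inherits(mask, "binary_mask"))
  if (s_mm < min(centerline$s_mm) - 1e-9 || s_mm > max(centerline$s_mm) + 1e-9) {
    stop("range error: station s = ", s_mm, " mm is outside the centerline range [",
         round(min(centerline$s_mm), 3), ", ", round(max(centerline$s_mm), 3), "]",
         call. = FALSE)
  }
  if (is.null(pitch_mm)) pitch_mm <- min(mask$spacing_mm) / 2
  centre <- centerline_point(centerline, s_mm)
  normal <- centerline_tangent(centerline, s_mm)
  basis <- plane_basis(normal)

  half_w <- 16 * pitch_mm
  d <- dim(mask$voxels)
  diag_mm <- sqrt(sum((d * mask$spacing_mm)^2))
  repeat {
    uv <- seq(-half_w, half_w, by = pitch_mm)
    grid <- expand.grid(u = uv, v = uv)
    pts <- cbind(
      centre[1] + grid$u * basis$e1[1] + grid$v * basis$e2[1],
      centre[2] + grid$u * basis$e1[2] + grid$v * basis$e2[2],
      centre[3] + grid$u * basis$e1[3] + grid$v * basis$e2[3]
    )
    inside <- sample_nearest(mask, pts, fill = NA)
    out_of_volume <- is.na(inside)
    img <- matrix(!is.na(inside) & inside, nrow = length(uv))

    # connected in-plane region containing the plane centre
    lab <- EBImage::bwlabel(EBImage::Image(img * 1))
    lab <- as.array(lab)
    c0 <- ceiling(length(uv) / 2)
    centre_lab <- lab[c0, c0]
    if (centre_lab == 0) {
      # centre pixel off-lumen (e.g. just past a thin wall): take nearest label
      on <- which(lab > 0, arr.ind = TRUE)
      if (nrow(on) == 0) {
        return(structure(list(s_mm = s_mm, plane_point_mm = centre,
                              plane_normal = normal, area_mm2 = 0,
                              n_pixels = 0L, pitch_mm = pitch_mm,
                              truncated = FALSE, pixels_uv = NULL),
                         class = "cross_section"))
      }
      dd <- (on[, 1] - c0)^2 + (on[, 2] - c0)^2
      centre_lab <- lab[on[which.min(dd), 1], on[which.min(dd), 2]]
    }
    region <- if (region_mode == "all") img else lab == centre_lab
    touches_edge <- any(region[1, ]) || any(region[nrow(region), ]) ||
      any(region[, 1]) || any(region[, ncol(region)])
    if (!touches_edge || 2 * half_w > diag_mm) break
    half_w <- half_w * 2
  }

  # truncation: region pixels adjacent to out-of-volume samples
  truncated <- FALSE
  oov <- matrix(out_of_volume, nrow = length(uv))
  if (any(oov)) {
    grown <- region
    grown[-1, ] <- grown[-1, ] | region[-nrow(region), ]
    grown[-nrow(region), ] <- grown[-nrow(region), ] | region[-1, ]
    grown[, -1] <- grown[, -1] | region[, -ncol(region)]
    grown[, -ncol(region)] <- grown[, -ncol(region)] | region[, -1]
    truncated <- any(grown & oov)
  }
  if (touches_edge) truncated <- TRUE
  if (truncated) {
    warning("cross-section at s = ", signif(s_mm, 5),
            " mm is clipped at the volume boundary; area covers the in-volume part",
            call. = FALSE)
  }

  px <- which(region, arr.ind = TRUE)
  structure(
    list(
      s_mm = s_mm, plane_point_mm = centre, plane_normal = normal,
      area_mm2 = nrow(px) * pitch_mm^2,
      n_pixels = nrow(px), pitch_mm = pitch_mm, truncated = truncated,
      pixels_uv = cbind(u = uv[px[, 1]], v = uv[px[, 2]])
    ),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> s = %.3f mm, area = %.4f mm^2 (%d px @ %.3g mm)%s\n",
              x$s_mm, x$area_mm2, x$n_pixels, x$pitch_mm,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Cross-sectional area profile at landmark-anchored stations
#'
#' Measures one perpendicular cross-section per station offset, anchored at
#' `s_anchor_mm` (typically the caudal edge of the hard palate). Station
#' labels are signed offsets in mm with positive = rostral of the anchor, so
#' the default offsets `+3 ... -5` give nine consecutive stations at 1 mm
#' intervals from 3 mm rostral to 5 mm caudal. A station whose arclength
#' falls outside the centerline is flagged missing (`NA` area) and the others
#' are still returned.
#'
#' @param mask a [binary_mask].
#' @param centerline a `centerline`.
#' @param s_anchor_mm arclength (mm) of the anchor landmark on the centerline.
#' @param offsets_mm signed station offsets, mm (positive = rostral).
#' @param pitch_mm,region passed to [cross_section_at()].
#' @return an `area_profile` tibble: `station_label_mm`, `s_mm`, `area_mm2`,
#'   `truncated`, `missing`, ordered rostral to caudal.
#' @export
area_profile <- function(mask, centerline, s_anchor_mm,
                         offsets_mm = c(3, 2, 1, 0, -1, -2, -3, -4, -5),
                         pitch_mm = NULL, region = "centerline") {
  offsets_mm <- sort(offsets_mm, decreasing = TRUE) # rostral -> caudal
  s_lo <- min(centerline$s_mm)
  s_hi <- max(centerline$s_mm)
  rows <- purrr::map(offsets_mm, function(off) {
    s <- s_anchor_mm - off
    if (s < s_lo || s > s_hi) {
      return(tibble::tibble(station_label_mm = off, s_mm = s,
                            area_mm2 = NA_real_, truncated = NA, missing = TRUE))
    }
    cs <- cross_section_at(mask, centerline, s, pitch_mm = pitch_mm,
                           region = region)
    tibble::tibble(station_label_mm = off, s_mm = s, area_mm2 = cs$area_mm2,
                   truncated = cs$truncated, missing = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("area_profile", class(out))
  out
}

#' Partition the airway into nasal / hard-palate / soft-palate segments
#'
#' Projects the three boundary landmarks (nasopharyngeal meatus merge, caudal
#' edge of the hard palate, epiglottis) onto the centerline and returns their
#' arclengths, plus `s_end` = `min(centerline end, s_hard_palate + 5 mm)`
#' used as the caudal bound of volume accounting.
#'
#' @param centerline a `centerline`.
#' @param landmarks a landmark table (tibble with `name`, `x_mm`, `y_mm`,
#'   `z_mm`) or named list of 3-vectors, containing `meatus_merge`,
#'   `hard_palate_edge` and `epiglottis`.
#' @return an `airway_segments` list: `s_meatus_merge`, `s_hard_palate`,
#'   `s_epiglottis`, `s_end` (mm).
#' @export
partition_segments <- function(centerline, landmarks) {
  lm <- landmarks_as_list(landmarks)
  need <- c("meatus_merge", "hard_palate_edge", "epiglottis")
  if (!all(need %in% names(lm))) {
    stop("landmarks must include: ", paste(need, collapse = ", "), call. = FALSE)
  }
  cl <- centerline_matrix(centerline)
  proj <- function(p) {
    d2 <- colSums((t(cl) - p)^2)
    centerline$s_mm[which.min(d2)]
  }
  s_mm <- proj(lm$meatus_merge)
  s_hp <- proj(lm$hard_palate_edge)
  s_ep <- proj(lm$epiglottis)
  if (!(s_mm < s_hp && s_hp < s_ep)) {
    stop("ordering error: landmarks must project rostral to caudal as ",
         "meatus_merge < hard_palate_edge < epiglottis (got ",
         paste(signif(c(s_mm, s_hp, s_ep), 4), collapse = ", "), ")", call. = FALSE)
  }
  structure(
    list(s_meatus_merge = s_mm, s_hard_palate = s_hp, s_epiglottis = s_ep,
         s_end = min(max(centerline$s_mm), s_hp + 5)),
    class = "airway_segments"
  )
}

#' @export
print.airway_segments <- function(x, ...) {
  cat(sprintf(
    "<airway_segments> meatus merge %.3f | hard palate %.3f | epiglottis %.3f | end %.3f mm\n",
    x$s_meatus_merge, x$s_hard_palate, x$s_epiglottis, x$s_end))
  invisible(x)
}

landmarks_as_list <- function(landmarks) {
  if (is.data.frame(landmarks)) {
    setNames(
      lapply(seq_len(nrow(landmarks)),
             function(i) as.numeric(landmarks[i, c("x_mm", "y_mm", "z_mm")])),
      as.character(landmarks$name)
    )
  } else {
    landmarks
  }
}

#' Segment volumes along the centerline
#'
#' Each mask voxel is assigned to the arclength of its nearest centerline
#' point; the nasal volume covers the nostrils to the hard-palate edge, the
#' pharyngeal volume the hard-palate edge to 5 mm caudal of it (`s_end`), and
#' the total is their sum (exact, the bins partition the voxels).
#'
#' @param mask a [binary_mask].
#' @param centerline a `centerline`.
#' @param segments an `airway_segments` from [partition_segments()].
#' @return tibble with `v_nasal_mm3`, `v_pharyngeal_mm3`, `v_total_mm3`.
#' @export
segment_volumes <- function(mask, centerline, segments) {
  stopifnot(inherits(segments, "airway_segments"))
  s_vox <- voxel_arclengths(mask, centerline)
  vv <- voxel_volume_mm3(mask)
  v_nasal <- sum(s_vox < segments$s_hard_palate, na.rm = TRUE) * vv
  v_phar <- sum(s_vox >= segments$s_hard_palate & s_vox <= segments$s_end,
                na.rm = TRUE) * vv
  tibble::tibble(
    v_nasal_mm3 = v_nasal,
    v_pharyngeal_mm3 = v_phar,
    v_total_mm3 = v_nasal + v_phar
  )
}

#' Pharyngeal airway length
#'
#' Arclength from the caudal edge of the hard palate to the arytenoid
#' cartilage along the centerline.
#'
#' @param centerline a `centerline`.
#' @param s_hard_palate,s_arytenoid station arclengths, mm, both within the
#'   centerline range and in rostral-to-caudal order.
#' @return scalar, mm.
#' @export
pharyngeal_length <- function(centerline, s_hard_palate, s_arytenoid) {
  rng <- range(centerline$s_mm)
  if (s_hard_palate < rng[1] - 1e-9 || s_arytenoid > rng[2] + 1e-9) {
    stop("range error: stations outside the centerline range", call. = FALSE)
  }
  if (s_arytenoid < s_hard_palate) {
    stop("ordering error: the arytenoid station must be caudal to the hard palate",
         call. = FALSE)
  }
  s_arytenoid - s_hard_palate
}

#' Area profile from binned voxel volumes
#'
#' A robust alternative to plane resampling for reduced-order flow: every
#' lumen voxel is assigned to the arclength of its nearest centerline point,
#' and the area at a station is the voxel volume per arclength bin divided by
#' the bin width (the derivative of cumulative volume with respect to
#' arclength). Paired passages are automatically counted in parallel and
#' end caps cause no plane-clipping artefacts; the price is smoothing over
#' the bin width.
#'
#' @param mask a [binary_mask].
#' @param centerline a `centerline`.
#' @param step_mm spacing of evaluation stations, mm.
#' @param window_mm averaging window width, mm; the default
#'   `max(2 * step_mm, 4 * voxel spacing)` overlaps adjacent stations and
#'   spans several voxel layers, which suppresses layer-aliasing noise.
#' @param s_range optional numeric(2) arclength range (default: the
#'   centerline's).
#' @return tibble with `s_mm` (station positions) and `area_mm2`.
#' @export
arclength_area_profile <- function(mask, centerline, step_mm = 0.25,
                                   window_mm = NULL, s_range = NULL) {
  if (is.null(window_mm)) {
    window_mm <- max(2 * step_mm, 4 * min(mask$spacing_mm))
  }
  s_vox <- sort(voxel_arclengths(mask, centerline))
  if (is.null(s_range)) s_range <- range(centerline$s_mm)
  lo <- s_range[1] + window_mm / 2
  hi <- s_range[2] - window_mm / 2
  if (hi <= lo) stop("arclength range narrower than the averaging window",
                     call. = FALSE)
  centers <- seq(lo, hi, by = step_mm)
  if (tail(centers, 1) < hi - 1e-9) centers <- c(centers, hi)
  counts <- findInterval(centers + window_mm / 2, s_vox) -
    findInterval(centers - window_mm / 2, s_vox)
  tibble::tibble(
    s_mm = centers,
    area_mm2 = counts * voxel_volume_mm3(mask) / window_mm
  )
}
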