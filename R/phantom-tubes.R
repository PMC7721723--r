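# Voxel phantoms with analytic ground truth: the validation substrate for
# segmentation, cross-sectional morphometry and flow simulation. The intensity
# model mimics CT: lumen air -1000, soft tissue 0, bone +1000 (HU-like).

HU_AIR <- -1000
HU_SOFT <- 0
HU_BONE <- 1000

#' Ground truth bundle attached to every phantom
#'
#' @param shape_kind one of `"tube"`, `"venturi"`, `"curved_tube"`,
#'   `"mouse_airway"`.
#' @param area_profile_true tibble with `s_mm` (strictly increasing arclength)
#'   and `area_mm2` (> 0).
#' @param volume_true_mm3,length_true_mm analytic lumen volume and centerline
#'   length.
#' @param landmark_truth named list of 3D points (mm), may be empty.
#' @param extra named list of additional truths (segment volumes etc.).
#' @return a `phantom_truth` object.
#' @export
phantom_truth <- function(shape_kind, area_profile_true, volume_true_mm3,
                          length_true_mm, landmark_truth = list(), extra = list()) {
  shape_kind <- match.arg(shape_kind, c("tube", "venturi", "curved_tube", "mouse_airway"))
  stopifnot(
    all(diff(area_profile_true$s_mm) > 0),
    all(area_profile_true$area_mm2 > 0),
    volume_true_mm3 > 0, length_true_mm > 0
  )
  structure(
    list(shape_kind = shape_kind,
         area_profile_true = tibble::as_tibble(area_profile_true),
         volume_true_mm3 = volume_true_mm3,
         length_true_mm = length_true_mm,
         landmark_truth = landmark_truth,
         extra = extra),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s: volume %.4f mm^3, length %.3f mm, %d landmarks\n",
              x$shape_kind, x$volume_true_mm3, x$length_true_mm,
              length(x$landmark_truth)))
  invisible(x)
}

# Evaluate a lumen predicate over a voxel grid and assemble volume + mask.
# predicate(points_mm) -> logical; bone_predicate optional.
rasterize_phantom <- function(lower_mm, upper_mm, spacing_mm,
                              predicate, bone_predicate = NULL, margin_vox = 3) {
  spacing_mm <- check_spacing(spacing_mm)
  origin <- lower_mm - margin_vox * spacing_mm
  dims <- pmax(ceiling((upper_mm - origin) / spacing_mm) + margin_vox + 1, 2)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing_mm[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing_mm[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing_mm[3]
  # evaluate slab-wise in z to bound memory
  mask <- array(FALSE, dims)
  bone <- if (!is.null(bone_predicate)) array(FALSE, dims) else NULL
  grid_xy <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]))
  for (k in seq_len(dims[3])) {
    pts <- cbind(grid_xy, zs[k])
    mask[, , k] <- predicate(pts)
    if (!is.null(bone)) bone[, , k] <- bone_predicate(pts)
  }
  vox <- array(HU_SOFT, dims)
  if (!is.null(bone)) vox[bone] <- HU_BONE
  vox[mask] <- HU_AIR
  list(
    volume = volume3d(vox, spacing_mm, origin),
    mask = binary_mask(mask, spacing_mm, origin)
  )
}

warn_if_coarse <- function(diameter_mm, spacing_mm) {
  nvox <- diameter_mm / max(spacing_mm)
  if (nvox < 8) {
    warning(sprintf(
      "only %.1f voxels span the lumen diameter; area and flow estimates will be coarse (>= 8 recommended)",
      nvox), call. = FALSE)
  }
}

#' Straight-tube phantom
#'
#' A solid circular cylinder of lumen air inside soft tissue, with exact
#' analytic ground truth (`area = pi r^2` everywhere, `volume = pi r^2 L`).
#' The axis may be tilted relative to the voxel grid, which is how
#' perpendicular-plane area measurement is distinguished from axial-slice
#' area.
#'
#' @param radius_mm,length_mm tube radius and length, mm (> 0).
#' @param spacing_mm voxel spacing, mm; a warning is issued when fewer than 8
#'   voxels span the diameter.
#' @param axis_direction 3-vector, tube axis (normalised internally).
#' @return list with `volume` ([volume3d]), `mask` ([binary_mask]) and
#'   `truth` ([phantom_truth]).
#' @examples
#' ph <- make_tube_phantom(0.5, 5, spacing_mm = 0.05)
#' ph$truth
#' @export
make_tube_phantom <- function(radius_mm, length_mm, spacing_mm = 0.02,
                              axis_direction = c(0, 0, 1)) {
  if (radius_mm <= 0 || length_mm <= 0 || any(spacing_mm <= 0)) {
    stop("tube radius, length and spacing must all be > 0", call. = FALSE)
  }
  warn_if_coarse(2 * radius_mm, spacing_mm)
  d <- axis_direction / sqrt(sum(axis_direction^2))
  p0 <- c(0, 0, 0)
  ends <- rbind(p0, p0 + length_mm * d)
  lower <- apply(ends, 2, min) - radius_mm
  upper <- apply(ends, 2, max) + radius_mm
  predicate <- function(pts) {
    rel <- sweep(pts, 2, p0)
    t <- as.vector(rel %*% d)
    # form the perpendicular component explicitly: subtracting t^2 from
    # |rel|^2 cancels catastrophically for points exactly on the surface
    perp <- rel - outer(t, d)
    t >= 0 & t <= length_mm & rowSums(perp^2) <= radius_mm^2
  }
  ras <- rasterize_phantom(lower, upper, spacing_mm, predicate)
  s <- seq(0, length_mm, length.out = 41)
  truth <- phantom_truth(
    "tube",
    tibble::tibble(s_mm = s, area_mm2 = rep(pi * radius_mm^2, length(s))),
    volume_true_mm3 = pi * radius_mm^2 * length_mm,
    length_true_mm = length_mm,
    landmark_truth = list(start = p0, end = p0 + length_mm * d),
    extra = list(radius_mm = radius_mm, axis = d)
  )
  c(ras, list(truth = truth))
}

#' Curved-tube (torus-arc) phantom
#'
#' A circular tube bent along a circular arc of given centerline radius in the
#' x-z plane. By Pappus' theorem the lumen volume is `pi r^2 * R * theta`
#' and the centerline length is `R * theta` — the oracle for curved
#' centerline arclength measurement.
#'
#' @param centerline_radius_mm arc radius R of the centerline, mm.
#' @param tube_radius_mm lumen radius r, mm (must be < R).
#' @param angle_deg arc angle, degrees (default 90: quarter torus).
#' @param spacing_mm voxel spacing, mm.
#' @return list with `volume`, `mask`, `truth` as [make_tube_phantom()].
#' @export
make_curved_tube_phantom <- function(centerline_radius_mm = 5, tube_radius_mm = 0.5,
                                     angle_deg = 90, spacing_mm = 0.05) {
  stopifnot(centerline_radius_mm > tube_radius_mm, tube_radius_mm > 0,
            angle_deg > 0, angle_deg <= 180)
  warn_if_coarse(2 * tube_radius_mm, spacing_mm)
  R <- centerline_radius_mm
  r <- tube_radius_mm
  th <- angle_deg * pi / 180
  # centerline: (R sin a, 0, R - R cos a), a in [0, th]; starts at origin along +z? no:
  # starts at (0,0,0) tangent +z when a=0.
  predicate <- function(pts) {
    x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
    # torus centre at (R, 0, 0) rotated: centerline (R - R cos a, 0, R sin a)
    dx <- x - R
    rho <- sqrt(dx^2 + z^2)
    a <- atan2(z, -dx) # a = 0 at start (x=0,z=0), increases with z
    inside <- (rho - R)^2 + y^2 <= r^2
    inside & a >= 0 & a <= th
  }
  lower <- c(-r, -r, -r)
  upper <- c(R - R * cos(th) + r, r, R * sin(th) + r)
  if (th > pi / 2) upper[1] <- R + r
  ras <- rasterize_phantom(lower, upper, spacing_mm, predicate)
  L <- R * th
  s <- seq(0, L, length.out = 41)
  a_end <- th
  truth <- phantom_truth(
    "curved_tube",
    tibble::tibble(s_mm = s, area_mm2 = rep(pi * r^2, length(s))),
    volume_true_mm3 = pi * r^2 * L,
    length_true_mm = L,
    landmark_truth = list(
      start = c(0, 0, 0),
      end = c(R - R * cos(a_end), 0, R * sin(a_end))
    ),
    extra = list(radius_mm = r, arc_radius_mm = R, angle_rad = th)
  )
  c(ras, list(truth = truth))
}

#' Venturi (constricted-tube) phantom
#'
#' Axisymmetric inlet tube, linear taper to a narrow throat, and symmetric
#' expansion back to the outlet diameter — the analogue of a localised upper
#' airway narrowing. The analytic area profile has its minimum inside the
#' throat; frustum volumes are exact.
#'
#' @param r_inlet_mm,r_throat_mm inlet and throat radii, mm
#'   (`r_throat_mm < r_inlet_mm`).
#' @param l_inlet_mm,l_throat_mm,l_outlet_mm straight segment lengths, mm.
#' @param taper_len_mm length of each linear taper, mm.
#' @param spacing_mm voxel spacing, mm.
#' @return list with `volume`, `mask`, `truth`.
#' @export
make_venturi_phantom <- function(r_inlet_mm = 0.8, r_throat_mm = 0.4,
                                 l_inlet_mm = 3, l_throat_mm = 2, l_outlet_mm = 3,
                                 taper_len_mm = 1.5, spacing_mm = 0.02) {
  if (r_throat_mm >= r_inlet_mm) {
    stop("`r_throat_mm` must be smaller than `r_inlet_mm`", call. = FALSE)
  }
  stopifnot(l_inlet_mm > 0, l_throat_mm > 0, l_outlet_mm > 0, taper_len_mm > 0)
  warn_if_coarse(2 * r_throat_mm, spacing_mm)
  L <- l_inlet_mm + taper_len_mm + l_throat_mm + taper_len_mm + l_outlet_mm
  knots_s <- c(0, l_inlet_mm, l_inlet_mm + taper_len_mm,
               l_inlet_mm + taper_len_mm + l_throat_mm,
               l_inlet_mm + 2 * taper_len_mm + l_throat_mm, L)
  knots_r <- c(r_inlet_mm, r_inlet_mm, r_throat_mm, r_throat_mm,
               r_inlet_mm, r_inlet_mm)
  radius_at <- function(s) approx(knots_s, knots_r, xout = s, rule = 2)$y
  predicate <- function(pts) {
    z <- pts[, 3]
    rr <- radius_at(z)
    inside <- pts[, 1]^2 + pts[, 2]^2 <= rr^2
    inside & z >= 0 & z <= L
  }
  ras <- rasterize_phantom(c(-r_inlet_mm, -r_inlet_mm, 0),
                           c(r_inlet_mm, r_inlet_mm, L), spacing_mm, predicate)
  s <- sort(unique(c(seq(0, L, length.out = 81), knots_s)))
  frustum <- function(h, R1, R2) pi * h / 3 * (R1^2 + R1 * R2 + R2^2)
  vol <- sum(vapply(seq_len(length(knots_s) - 1), function(i) {
    frustum(knots_s[i + 1] - knots_s[i], knots_r[i], knots_r[i + 1])
  }, numeric(1)))
  truth <- phantom_truth(
    "venturi",
    tibble::tibble(s_mm = s, area_mm2 = pi * radius_at(s)^2),
    volume_true_mm3 = vol,
    length_true_mm = L,
    landmark_truth = list(
      inlet = c(0, 0, 0),
      throat_centre = c(0, 0, l_inlet_mm + taper_len_mm + l_throat_mm / 2),
      outlet = c(0, 0, L)
    ),
    extra = list(radius_at = radius_at, knots_s = knots_s, knots_r = knots_r)
  )
  c(ras, list(truth = truth))
}
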