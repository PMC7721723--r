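# Airway lumen isolation: intensity inversion, (Otsu or fixed) thresholding,
# seeded 26-connected component extraction, slice-wise hole filling.

#' Invert voxel intensities
#'
#' Negates every voxel value, so that the air lumen (dark in CT) becomes the
#' brightest structure and can be thresholded directly. Geometry is
#' unchanged; applying the inversion twice restores the original volume.
#'
#' @param volume a [volume3d].
#' @return a [volume3d] with negated voxels.
#' @export
invert_intensity <- function(volume) {
  stopifnot(inherits(volume, "volume3d"), !inherits(volume, "binary_mask"))
  volume3d(-volume$voxels, volume$spacing_mm, volume$origin_mm)
}

#' Otsu threshold of a voxel histogram
#'
#' Maximises between-class variance over a 256-bin histogram; returns the
#' threshold intensity (bin upper edge). Suited to the strongly bimodal
#' air/tissue histograms of inverted CT volumes.
#'
#' @param values numeric vector or a [volume3d].
#' @param n_bins number of histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  if (inherits(values, "volume3d")) values <- values$voxels
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  w <- counts / sum(counts)
  cum_w <- cumsum(w)
  cum_mu <- cumsum(w * mids)
  mu_t <- cum_mu[n_bins]
  denom <- cum_w * (1 - cum_w)
  between <- ifelse(denom > 0, (mu_t * cum_w - cum_mu)^2 / denom, 0)
  breaks[which.max(between) + 1]
}

# linear indices of 26-neighbour pairs among TRUE voxels; returns 2-col matrix
# of compact ids (1..n_true)
mask_adjacency <- function(mask_arr) {
  d <- dim(mask_arr)
  idmap <- array(0L, d)
  idmap[mask_arr] <- seq_len(sum(mask_arr))
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[order(offsets$dz, offsets$dy, offsets$dx), ]
  offsets <- offsets[with(offsets, dz > 0 | (dz == 0 & dy > 0) |
                            (dz == 0 & dy == 0 & dx > 0)), ]
  edges <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    o <- as.integer(offsets[i, ])
    xr <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    yr <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zr <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    a <- mask_arr[xr, yr, zr, drop = FALSE]
    b <- mask_arr[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
    both <- a & b
    if (!any(both)) next
    ia <- idmap[xr, yr, zr, drop = FALSE][both]
    ib <- idmap[xr + o[1], yr + o[2], zr + o[3], drop = FALSE][both]
    edges[[i]] <- cbind(ia, ib)
  }
  do.call(rbind, edges)
}

# label of the 26-connected component containing compact id `seed_id`
component_of <- function(mask_arr, seed_id) {
  n <- sum(mask_arr)
  edges <- mask_adjacency(mask_arr)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  comp$membership == comp$membership[seed_id]
}

fill_holes_slicewise <- function(mask_arr) {
  d <- dim(mask_arr)
  out <- mask_arr
  for (k in seq_len(d[3])) {
    sl <- mask_arr[, , k]
    if (!any(sl)) next
    filled <- EBImage::fillHull(EBImage::Image(sl * 1))
    out[, , k] <- as.array(filled) > 0
  }
  out
}

#' Segment the airway lumen from an inverted volume
#'
#' Thresholds the (already inverted, lumen-bright) volume, keeps only the
#' 26-connected component containing the seed point, and fills holes slice by
#' slice along the axial (z) axis. The threshold is either automatic
#' (bimodal/Otsu on the histogram) or a fixed intensity.
#'
#' @param volume an inverted [volume3d] (lumen holds the highest intensities).
#' @param threshold `"auto"` for Otsu selection, or a numeric intensity;
#'   voxels strictly above the threshold are candidate lumen.
#' @param seed_point_mm 3-vector, world coordinate (mm) of a point inside the
#'   intended lumen.
#' @param fill_holes logical; fill 2D holes per axial slice (default TRUE).
#' @return a [binary_mask] with the geometry of `volume`; the chosen
#'   threshold is attached as attribute `"threshold"`.
#' @export
segment_airway <- function(volume, threshold = "auto", seed_point_mm,
                           fill_holes = TRUE) {
  stopifnot(inherits(volume, "volume3d"))
  thr <- if (identical(threshold, "auto")) {
    # the lumen is the brightest structure in the inverted volume; applying
    # the bimodal criterion to the upper half of the distribution keeps dense
    # tissue (bone, darkest after inversion) from capturing the split
    v <- volume$voxels
    otsu_threshold(v[v >= stats::median(v)])
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    threshold
  }
  cand <- volume$voxels > thr
  idx <- round(world_to_index(volume, seed_point_mm))[1, ]
  d <- dim(volume$voxels)
  if (any(idx < 1) || any(idx > d)) {
    stop("seed point lies outside the volume", call. = FALSE)
  }
  if (!cand[idx[1], idx[2], idx[3]]) {
    stop("segmentation error: seed point is not in any above-threshold region",
         call. = FALSE)
  }
  idmap <- array(0L, d)
  idmap[cand] <- seq_len(sum(cand))
  keep <- component_of(cand, idmap[idx[1], idx[2], idx[3]])
  lumen <- array(FALSE, d)
  lumen[cand] <- keep
  if (fill_holes) lumen <- fill_holes_slicewise(lumen)
  out <- binary_mask(lumen, volume$spacing_mm, volume$origin_mm)
  attr(out, "threshold") <- thr
  out
}

#' Mask volume in mm^3, optionally restricted along a centerline
#'
#' Voxel count times voxel volume. When a centerline and an arclength
#' interval are supplied, only voxels whose nearest centerline point falls in
#' `[s_range[1], s_range[2]]` are counted (the mechanism behind "from the
#' nostrils to 5 mm caudal of the hard palate" style bounds).
#'
#' @param mask a [binary_mask].
#' @param centerline optional [centerline] for region restriction.
#' @param s_range optional numeric(2) arclength interval, mm.
#' @return scalar, mm^3 (0 with a warning for an empty region).
#' @export
mask_volume_mm3 <- function(mask, centerline = NULL, s_range = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(centerline) || is.null(s_range)) {
    return(sum(mask$voxels) * voxel_volume_mm3(mask))
  }
  if (s_range[2] <= s_range[1]) {
    warning("empty arclength interval: volume is 0", call. = FALSE)
    return(0)
  }
  s_vox <- voxel_arclengths(mask, centerline)
  n <- sum(s_vox >= s_range[1] & s_vox <= s_range[2], na.rm = TRUE)
  if (n == 0) warning("no mask voxels in the requested region", call. = FALSE)
  n * voxel_volume_mm3(mask)
}
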