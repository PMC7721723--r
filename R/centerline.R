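# Centerline extraction: medial-weighted shortest path through the lumen
# voxel graph, then moving-average smoothing and arclength parameterisation.

#' Build a centerline from an ordered polyline
#'
#' Used both by [extract_centerline()] and to supply a manually defined
#' central axis. Consecutive duplicate points are dropped; arclength is the
#' cumulative chord length starting at 0 at the first (rostral) point.
#'
#' @param points_mm n x 3 matrix or data frame of ordered 3D points (mm).
#' @return a `centerline` tibble with columns `s_mm`, `x_mm`, `y_mm`, `z_mm`.
#' @export
centerline_from_points <- function(points_mm) {
  p <- as.matrix(points_mm)
  stopifnot(ncol(p) == 3)
  if (nrow(p) > 1) {
    keep <- c(TRUE, rowSums((p[-1, , drop = FALSE] -
                               p[-nrow(p), , drop = FALSE])^2) > 0)
    p <- p[keep, , drop = FALSE]
  }
  if (nrow(p) < 2) {
    stop("path error: a centerline needs at least two distinct points", call. = FALSE)
  }
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  out <- tibble::tibble(
    s_mm = c(0, cumsum(seg)),
    x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3]
  )
  class(out) <- c("centerline", class(out))
  out
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.3f mm\n", nrow(x), max(x$s_mm)))
  NextMethod()
}

# interior depth (6-connected grassfire): number of erosions before a voxel
# is removed; proportional to distance from the wall
grassfire_depth <- function(mask_arr) {
  d <- dim(mask_arr)
  depth <- array(0L, d)
  cur <- mask_arr
  shift_and <- function(m, o) {
    out <- array(FALSE, d)
    xr <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    yr <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zr <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    out[xr, yr, zr] <- m[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
    out
  }
  while (any(cur)) {
    depth[cur] <- depth[cur] + 1L
    nxt <- cur
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nxt <- nxt & shift_and(cur, o)
    }
    if (identical(nxt, cur)) { # safety: cannot happen for finite masks
      depth[cur] <- depth[cur] + 1L
      break
    }
    cur <- nxt
  }
  depth
}

nearest_true_voxel <- function(mask, point_mm) {
  idx <- round(world_to_index(mask, point_mm))[1, ]
  d <- dim(mask$voxels)
  idx <- pmax(pmin(idx, d), 1)
  if (mask$voxels[idx[1], idx[2], idx[3]]) return(idx)
  # expand a small search cube until a lumen voxel is found
  for (r in 1:25) {
    xr <- max(1, idx[1] - r):min(d[1], idx[1] + r)
    yr <- max(1, idx[2] - r):min(d[2], idx[2] + r)
    zr <- max(1, idx[3] - r):min(d[3], idx[3] + r)
    sub <- mask$voxels[xr, yr, zr, drop = FALSE]
    if (any(sub)) {
      w <- which(sub, arr.ind = TRUE)[1, ]
      return(c(xr[w[1]], yr[w[2]], zr[w[3]]))
    }
  }
  stop("path error: no lumen voxel near the requested endpoint", call. = FALSE)
}

#' Extract an airway centerline from a binary mask
#'
#' Computes a medial path between two endpoints: the lumen voxel graph
#' (26-connectivity, physical chord-length edges) is weighted so that voxels
#' deep inside the lumen are strongly preferred over wall-adjacent ones
#' (inverse-square of the grassfire interior depth), and the minimum-cost
#' path is found by Dijkstra's algorithm. The raw voxel path is then smoothed
#' with a moving average over `smoothing_window_mm` of arclength and
#' re-parameterised by cumulative chord length.
#'
#' @param mask a [binary_mask].
#' @param start_point_mm,end_point_mm 3-vectors (mm) inside the lumen;
#'   `start_point_mm` defines arclength 0 (the rostral end).
#' @param smoothing_window_mm moving-average window, mm. The default 0.2 mm
#'   suppresses voxel-scale jaggedness while staying far below the 1 mm
#'   station spacing used for cross-sectional profiling.
#' @return a `centerline` tibble (see [centerline_from_points()]).
#' @export
extract_centerline <- function(mask, start_point_mm, end_point_mm,
                               smoothing_window_mm = 0.2) {
  stopifnot(inherits(mask, "binary_mask"))
  if (isTRUE(all.equal(as.numeric(start_point_mm), as.numeric(end_point_mm)))) {
    stop("path error: start and end points coincide", call. = FALSE)
  }
  m <- mask$voxels
  d <- dim(m)
  start_idx <- nearest_true_voxel(mask, start_point_mm)
  end_idx <- nearest_true_voxel(mask, end_point_mm)

  depth <- grassfire_depth(m)
  idmap <- array(0L, d)
  n <- sum(m)
  idmap[m] <- seq_len(n)
  edges <- mask_adjacency(m)
  if (is.null(edges) || nrow(edges) == 0) {
    stop("path error: mask has no connected lumen", call. = FALSE)
  }
  vox_idx <- which(m)
  ai <- arrayInd(vox_idx, d)
  wpts <- index_to_world(mask, ai)
  dep <- as.numeric(depth[vox_idx])
  seg_len <- sqrt(rowSums((wpts[edges[, 1], , drop = FALSE] -
                             wpts[edges[, 2], , drop = FALSE])^2))
  medial_pen <- (1 / dep[edges[, 1]]^2 + 1 / dep[edges[, 2]]^2) / 2
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  from <- idmap[start_idx[1], start_idx[2], start_idx[3]]
  to <- idmap[end_idx[1], end_idx[2], end_idx[3]]
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = from, to = to, weights = seg_len * medial_pen, output = "vpath"
  ))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0) {
    stop("path error: endpoints lie in disconnected lumen components", call. = FALSE)
  }
  path <- wpts[vp, , drop = FALSE]

  # moving-average smoothing over ~smoothing_window_mm of arclength,
  # endpoints pinned
  step <- mean(sqrt(rowSums(diff(path)^2)))
  k <- max(1, round(smoothing_window_mm / step / 2))
  if (k > 0 && nrow(path) > 2 * k + 1) {
    sm <- apply(path, 2, function(v) {
      padded <- c(rep(v[1], k), v, rep(v[length(v)], k))
      as.numeric(stats::filter(padded, rep(1 / (2 * k + 1), 2 * k + 1),
                               sides = 2))[(k + 1):(k + length(v))]
    })
    sm[1, ] <- path[1, ]
    sm[nrow(sm), ] <- path[nrow(path), ]
    path <- sm
  }
  centerline_from_points(path)
}

centerline_matrix <- function(centerline) {
  as.matrix(centerline[, c("x_mm", "y_mm", "z_mm")])
}

# resample a centerline at uniform arclength steps (linear interpolation)
resample_centerline <- function(centerline, step_mm) {
  s_new <- seq(min(centerline$s_mm), max(centerline$s_mm), by = step_mm)
  cl <- centerline_matrix(centerline)
  out <- tibble::tibble(
    s_mm = s_new,
    x_mm = approx(centerline$s_mm, cl[, 1], xout = s_new)$y,
    y_mm = approx(centerline$s_mm, cl[, 2], xout = s_new)$y,
    z_mm = approx(centerline$s_mm, cl[, 3], xout = s_new)$y
  )
  class(out) <- c("centerline", class(out))
  out
}

# arclength of the nearest centerline point, for every foreground voxel.
# The polyline is densified to half a voxel first so that nearest-point
# arclengths are quasi-continuous (no aliasing against downstream bins).
voxel_arclengths <- function(mask, centerline) {
  step <- min(mask$spacing_mm) / 2
  if (stats::median(diff(centerline$s_mm)) > step) {
    centerline <- resample_centerline(centerline, step)
  }
  cl <- centerline_matrix(centerline)
  s <- centerline$s_mm
  vox_idx <- which(mask$voxels)
  pts <- index_to_world(mask, arrayInd(vox_idx, dim(mask$voxels)))
  best_d2 <- rep(Inf, nrow(pts))
  best_s <- rep(NA_real_, nrow(pts))
  chunk <- 40
  for (start in seq(1, nrow(cl), by = chunk)) {
    js <- start:min(start + chunk - 1, nrow(cl))
    for (j in js) {
      d2 <- (pts[, 1] - cl[j, 1])^2 + (pts[, 2] - cl[j, 2])^2 +
        (pts[, 3] - cl[j, 3])^2
      upd <- d2 < best_d2
      if (any(upd)) {
        best_d2[upd] <- d2[upd]
        best_s[upd] <- s[j]
      }
    }
  }
  best_s
}

# unit tangent at arclength s (central difference on the polyline)
centerline_tangent <- function(centerline, s_mm) {
  cl <- centerline_matrix(centerline)
  s <- centerline$s_mm
  h <- max(2 * mean(diff(s)), 1e-6)
  p_lo <- centerline_point(centerline, max(min(s), s_mm - h))
  p_hi <- centerline_point(centerline, min(max(s), s_mm + h))
  tg <- p_hi - p_lo
  tg / sqrt(sum(tg^2))
}

# interpolated point at arclength s
centerline_point <- function(centerline, s_mm) {
  cl <- centerline_matrix(centerline)
  s <- centerline$s_mm
  vapply(1:3, function(j) approx(s, cl[, j], xout = s_mm, rule = 2)$y, numeric(1))
}
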