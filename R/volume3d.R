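#' Volumetric image and binary mask containers
#'
#' `volume3d()` wraps a 3D scalar voxel grid together with its physical
#' geometry: isotropic-or-anisotropic voxel spacing in mm and the world
#' coordinate of the first voxel centre. `binary_mask()` is the boolean
#' analogue used for segmented airway lumens; a mask always carries the same
#' geometry as the volume it was derived from.
#'
#' The coordinate convention is voxel-centre: the world position of the voxel
#' at (1-based) array index `i` is `origin + (i - 1) * spacing`, all in mm.
#' Axis order is (x, y, z).
#'
#' @param voxels 3D numeric (volume) or logical (mask) array.
#' @param spacing_mm numeric(3), voxel spacing in mm, all > 0. A scalar is
#'   recycled to the three axes.
#' @param origin_mm numeric(3), world coordinate (mm) of the first voxel
#'   centre. Defaults to `c(0, 0, 0)`.
#' @return An object of class `volume3d` (or `binary_mask`, which inherits
#'   the geometry contract).
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing_mm = 0.02)
#' voxel_volume_mm3(v)
#' @export
volume3d <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing_mm <- check_spacing(spacing_mm)
  origin_mm <- check_origin(origin_mm)
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "volume3d"
  )
}

#' @rdname volume3d
#' @export
binary_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  storage.mode(voxels) <- "logical"
  spacing_mm <- check_spacing(spacing_mm)
  origin_mm <- check_origin(origin_mm)
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = c("binary_mask", "volume3d")
  )
}

check_spacing <- function(spacing_mm) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 strictly positive finite values", call. = FALSE)
  }
  as.numeric(spacing_mm)
}

check_origin <- function(origin_mm) {
  if (length(origin_mm) != 3 || any(!is.finite(origin_mm))) {
    stop("`origin_mm` must be 3 finite values", call. = FALSE)
  }
  as.numeric(origin_mm)
}

#' @export
print.volume3d <- function(x, ...) {
  kind <- if (inherits(x, "binary_mask")) "binary_mask" else "volume3d"
  d <- dim(x$voxels)
  cat(sprintf(
    "<%s> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
    kind, d[1], d[2], d[3],
    paste(signif(x$spacing_mm, 4), collapse = " x "),
    paste(signif(x$origin_mm, 4), collapse = ", ")
  ))
  if (inherits(x, "binary_mask")) {
    cat(sprintf("  %d foreground voxels (%.3f mm^3)\n",
                sum(x$voxels), sum(x$voxels) * voxel_volume_mm3(x)))
  } else {
    rng <- range(x$voxels)
    cat(sprintf("  intensity range [%g, %g]\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param x a `volume3d` or `binary_mask`.
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

#' Convert between world (mm) and 1-based voxel index coordinates
#'
#' Voxel-centre convention: `world = origin + (index - 1) * spacing`.
#' `world_to_index()` returns fractional (unrounded) indices.
#'
#' @param x a `volume3d` or `binary_mask`.
#' @param points_mm numeric(3) or an n x 3 matrix of world coordinates (mm).
#' @param index numeric(3) or an n x 3 matrix of 1-based voxel indices.
#' @return an n x 3 matrix.
#' @export
world_to_index <- function(x, points_mm) {
  p <- rbind3(points_mm)
  sweep(sweep(p, 2, x$origin_mm, "-"), 2, x$spacing_mm, "/") + 1
}

#' @rdname world_to_index
#' @export
index_to_world <- function(x, index) {
  i <- rbind3(index)
  sweep(sweep(i - 1, 2, x$spacing_mm, "*"), 2, x$origin_mm, "+")
}

rbind3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  stopifnot(ncol(p) == 3)
  p
}

#' Sample a mask or volume at world coordinates (nearest neighbour)
#'
#' Points falling outside the grid return `fill`.
#'
#' @param x a `volume3d` or `binary_mask`.
#' @param points_mm n x 3 matrix of world coordinates, mm.
#' @param fill value returned for out-of-grid points.
#' @return vector of length n.
#' @export
sample_nearest <- function(x, points_mm, fill = NA) {
  idx <- round(world_to_index(x, points_mm))
  d <- dim(x$voxels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(fill, nrow(idx))
  if (any(ok)) {
    lin <- (idx[ok, 3] - 1) * d[1] * d[2] + (idx[ok, 2] - 1) * d[1] + idx[ok, 1]
    out[ok] <- x$voxels[lin]
  }
  out
}

#' Tidy a voxel grid into a long tibble
#'
#' One row per voxel (masks: per foreground voxel) with world coordinates.
#' Intended for small volumes and plotting; a full micro-CT volume tidied
#' this way is very large.
#'
#' @param x a `volume3d` or `binary_mask`.
#' @param ... unused.
#' @return tibble with columns `x_mm`, `y_mm`, `z_mm`, `value`.
#' @export
tidy.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  keep <- if (inherits(x, "binary_mask")) which(x$voxels) else seq_len(prod(d))
  ai <- arrayInd(keep, d)
  w <- index_to_world(x, ai)
  tibble::tibble(
    x_mm = w[, 1], y_mm = w[, 2], z_mm = w[, 3],
    value = as.vector(x$voxels[keep])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
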