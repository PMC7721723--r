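# Minimal DICOM slice series I/O (explicit VR, little endian, uncompressed).
#
# Scope: single-frame 16-bit CT-style slices as produced by micro-CT DICOM
# converters — enough to read a directory of axial slices into a volume3d and
# to write one back out. Sequences, compressed transfer syntaxes and implicit
# VR are not supported.

DICM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose length field is 4 bytes after a 2-byte reserved gap
.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

# Parse one DICOM file, returning the tags this package needs.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(raw) >= 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
  }
  tags <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- read_uint(raw[pos:(pos + 1L)])
    elem <- read_uint(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .vr_long) {
      len <- read_uint(raw[(pos + 8L):(pos + 11L)])
      vpos <- pos + 12L
    } else {
      len <- read_uint(raw[(pos + 6L):(pos + 7L)])
      vpos <- pos + 8L
    }
    if (vpos + len - 1L > n) stop("truncated DICOM file: ", path, call. = FALSE)
    key <- sprintf("%04x%04x", group, elem)
    val <- raw[vpos:(vpos + len - 1L)]
    if (len == 0L) val <- raw(0)
    tags[[key]] <- list(vr = vr, value = val)
    pos <- vpos + len
    if (key == "7fe00010") break
  }
  tags
}

dcm_string <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_character_)
  v <- t$value
  v <- v[v != as.raw(0)] # UI values are null-padded
  trimws(rawToChar(v))
}

dcm_numeric <- function(tags, key) {
  s <- dcm_string(tags, key)
  if (is.na(s)) return(NA_real_)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NA_integer_)
  as.integer(read_uint(t$value[1:2]))
}

#' Read a directory of DICOM slices as a volume
#'
#' Slices are ordered by their spatial position along the slice normal (the
#' cross product of the in-plane orientation vectors), never by filename, and
#' must all belong to one series. Slice spacing is taken from successive
#' positions and must be uniform to within 1%.
#'
#' @param dir directory containing one DICOM series (`.dcm` files or all
#'   regular files in the directory).
#' @return a [volume3d].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, read_dicom_file)

  uids <- vapply(slices, dcm_string, "", key = "0020000e")
  if (length(unique(uids)) != 1) {
    stop("directory mixes DICOM series (", length(unique(uids)),
         " SeriesInstanceUIDs found)", call. = FALSE)
  }

  orient <- dcm_numeric(slices[[1]], "00200037")
  if (anyNA(orient) || length(orient) != 6) orient <- c(1, 0, 0, 0, 1, 0)
  normal <- c(
    orient[2] * orient[6] - orient[3] * orient[5],
    orient[3] * orient[4] - orient[1] * orient[6],
    orient[1] * orient[5] - orient[2] * orient[4]
  )
  pos <- t(vapply(slices, dcm_numeric, numeric(3), key = "00200032"))
  z <- as.vector(pos %*% normal)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]

  if (length(z) > 2) {
    dz <- diff(z)
    if ((max(dz) - min(dz)) > 0.01 * mean(dz)) {
      stop("inconsistent DICOM slice spacing (> 1% variation)", call. = FALSE)
    }
  }
  dz <- if (length(z) > 1) mean(diff(z)) else 1

  rows <- dcm_uint16(slices[[1]], "00280010")
  cols <- dcm_uint16(slices[[1]], "00280011")
  ps <- dcm_numeric(slices[[1]], "00280030") # (row spacing, col spacing)
  slope <- dcm_numeric(slices[[1]], "00281053")
  icept <- dcm_numeric(slices[[1]], "00281052")
  if (is.na(slope)) slope <- 1
  if (is.na(icept)) icept <- 0

  vox <- array(0, dim = c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    pd <- slices[[k]][["7fe00010"]]
    if (is.null(pd)) stop("DICOM slice without PixelData", call. = FALSE)
    v <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                 signed = TRUE, endian = "little")
    # pixel data is row-major: x (column index) varies fastest
    vox[, , k] <- matrix(v, nrow = cols, ncol = rows)
  }
  vox <- vox * slope + icept
  volume3d(vox, spacing_mm = c(ps[2], ps[1], dz),
           origin_mm = c(pos[ord[1], 1], pos[ord[1], 2], z[1]))
}

encode_tag <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) {
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(
    writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
    charToRaw(vr)
  )
  if (vr %in% .vr_long) {
    c(hdr, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(hdr,
      writeBin(as.integer(length(value_raw)), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

tag_str <- function(group, elem, vr, s) encode_tag(group, elem, vr, charToRaw(s))
tag_us <- function(group, elem, v) {
  encode_tag(group, elem, "US", writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

#' Write a volume as a DICOM slice series
#'
#' One explicit-VR little-endian file per axial (z) slice; intensities are
#' rounded to signed 16-bit integers. The inverse of [read_dicom_series()].
#'
#' @param volume a [volume3d].
#' @param dir output directory (created if needed).
#' @param series_uid SeriesInstanceUID string shared by all slices.
#' @param file_names optional character vector of file names, one per slice
#'   (defaults to `slice_0001.dcm`, ...). Deliberately decoupled from spatial
#'   order so readers can be tested against shuffled names.
#' @return invisibly, the written file paths.
#' @export
write_dicom_series <- function(volume, dir, series_uid = "1.2.826.0.1.3680043.9999.1",
                               file_names = NULL) {
  stopifnot(inherits(volume, "volume3d"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  if (is.null(file_names)) {
    file_names <- sprintf("slice_%04d.dcm", seq_len(d[3]))
  }
  stopifnot(length(file_names) == d[3])
  sp <- volume$spacing_mm
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- volume$origin_mm + c(0, 0, (k - 1) * sp[3])
    pix <- as.integer(round(volume$voxels[, , k]))
    pix <- pmax(pmin(pix, 32767L), -32768L)
    body <- c(
      tag_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      tag_str(0x0008, 0x0018, "UI", paste0(series_uid, ".", k)),
      tag_str(0x0020, 0x000e, "UI", series_uid),
      tag_str(0x0020, 0x0032, "DS", paste(format(ipp, trim = TRUE), collapse = "\\")),
      tag_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      tag_us(0x0028, 0x0010, d[2]),          # Rows (y)
      tag_us(0x0028, 0x0011, d[1]),          # Columns (x)
      tag_str(0x0028, 0x0030, "DS", paste(format(c(sp[2], sp[1]), trim = TRUE), collapse = "\\")),
      tag_us(0x0028, 0x0100, 16),
      tag_us(0x0028, 0x0101, 16),
      tag_us(0x0028, 0x0102, 15),
      tag_us(0x0028, 0x0103, 1),
      tag_str(0x0028, 0x1052, "DS", "0"),
      tag_str(0x0028, 0x1053, "DS", "1"),
      encode_tag(0x7fe0, 0x0010, "OW",
                 writeBin(pix, raw(), size = 2, endian = "little"))
    )
    meta <- c(
      encode_tag(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      tag_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      tag_str(0x0002, 0x0003, "UI", paste0(series_uid, ".", k)),
      tag_str(0x0002, 0x0010, "UI", DICM_EXPLICIT_LE)
    )
    grp_len <- encode_tag(0x0002, 0x0000, "UL",
                          writeBin(length(meta), raw(), size = 4, endian = "little"))
    paths[k] <- file.path(dir, file_names[k])
    con <- file(paths[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), grp_len, meta, body), con)
    close(con)
  }
  invisible(paths)
}
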