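#' Read a volumetric image
#'
#' Dispatches on the path: NIfTI (`.nii` / `.nii.gz`, via RNifti), MetaImage
#' (`.mhd` / `.mha`), or a directory containing one DICOM slice series
#' (ordered by spatial position, see [read_dicom_series()]). Voxel spacing and
#' origin are populated from the header, in mm.
#'
#' @param path file or DICOM directory.
#' @return a [volume3d].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return(read_nifti_volume(path))
  if (grepl("\\.(mhd|mha)$", lower)) return(read_metaimage(path))
  stop("unrecognised volume format: ", path, call. = FALSE)
}

#' Write a volume or mask
#'
#' NIfTI (`.nii` / `.nii.gz`) or MetaImage (`.mhd` + `.raw`, or single-file
#' `.mha`). Masks are written with a uint8 payload.
#'
#' @param x a [volume3d] or [binary_mask].
#' @param path output path; the extension selects the format.
#' @return invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "volume3d"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    write_nifti_volume(x, path)
  } else if (grepl("\\.(mhd|mha)$", lower)) {
    write_metaimage(x, path)
  } else {
    stop("unrecognised volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  sp <- hdr$pixdim[2:4]
  xf <- RNifti::xform(img)
  org <- xf[1:3, 4]
  # our axes follow the stored array; take |column| scaling as spacing sanity
  vox <- array(as.numeric(img), dim = dim(img)[1:3])
  volume3d(vox, spacing_mm = abs(sp), origin_mm = org)
}

write_nifti_volume <- function(x, path) {
  vox <- x$voxels
  if (is.logical(vox)) {
    vox <- array(as.integer(vox), dim = dim(vox))
    datatype <- "uint8"
  } else {
    datatype <- "float"
  }
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- x$spacing_mm
  xfrm <- rbind(cbind(diag(x$spacing_mm), x$origin_mm), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(xfrm, code = 2L)
  RNifti::qform(img) <- structure(xfrm, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "binary_mask"))
  write_volume(x, path)
}

.met_types <- list(
  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
  MET_INT = list(what = "integer", size = 4, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("MetaImage header without ElementDataFile", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- if (!is.null(hdr$ElementSpacing)) {
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  } else rep(1, 3)
  org <- if (!is.null(hdr$Offset)) {
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  } else rep(0, 3)
  tp <- .met_types[[hdr$ElementType]]
  if (is.null(tp)) stop("unsupported MetaImage ElementType: ", hdr$ElementType, call. = FALSE)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    v <- readBin(con, tp$what, n = n, size = tp$size,
                 signed = tp$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    v <- readBin(rawpath, tp$what, n = n, size = tp$size,
                 signed = tp$signed, endian = "little")
  }
  volume3d(array(as.numeric(v), dim = dims), spacing_mm = sp, origin_mm = org)
}

write_metaimage <- function(x, path) {
  vox <- x$voxels
  is_mask <- is.logical(vox)
  local <- grepl("\\.mha$", tolower(path))
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(vox), collapse = " ")),
    paste("ElementSpacing =", paste(format(x$spacing_mm, trim = TRUE), collapse = " ")),
    paste("Offset =", paste(format(x$origin_mm, trim = TRUE), collapse = " ")),
    paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_DOUBLE"),
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  writeLines(hdr, con)
  payload <- if (is_mask) {
    writeBin(as.integer(vox), raw(), size = 1)
  } else {
    writeBin(as.numeric(vox), raw(), size = 8, endian = "little")
  }
  if (local) {
    writeBin(payload, con)
    close(con)
  } else {
    close(con)
    writeBin(payload, file.path(dirname(path), datafile))
  }
  invisible(path)
}
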