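#' Read a volumetric scan into an [image_volume()]
#'
#' Supported containers: a DICOM series directory (uncompressed CT slices,
#' little-endian transfer syntaxes), NIfTI (`.nii` / `.nii.gz`), and MetaImage
#' (`.mha`).  DICOM stored values are converted to Hounsfield units with the
#' per-file rescale slope and intercept; slices are ordered by Image Position
#' (Patient) projected on the slice normal, never by filename, and
#' non-uniform slice gaps beyond 1% are an error rather than being silently
#' resampled.
#'
#' @param path file (NIfTI/MetaImage) or directory (DICOM series).
#' @param format one of `"auto"`, `"metaimage"`, `"nifti"`, `"dicom_dir"`.
#'   `"auto"` dispatches on the file extension or directory-ness of `path`.
#' @return An [image_volume()] in HU with spacing/origin from the metadata.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("auto", "metaimage", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("no such file or directory: ", path, call. = FALSE)
  if (format == "auto") format <- guess_volume_format(path)
  switch(format,
    metaimage = read_mha(path),
    nifti     = read_nifti_volume(path),
    dicom_dir = read_dicom_dir(path))
}

#' Write an [image_volume()] to disk
#'
#' MetaImage is written as double precision raw data and is therefore a
#' bit-exact round trip; NIfTI goes through RNifti; DICOM writes one
#' explicit-VR little-endian CT slice per file (stored values
#' `HU + 1024`, rescale intercept -1024, slope 1).
#'
#' @inheritParams read_volume
#' @param vol the [image_volume()] (or [binary_mask()]) to write.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, format = c("auto", "metaimage", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (!inherits(vol, "image_volume")) stop("`vol` must be an image_volume", call. = FALSE)
  if (format == "auto") format <- guess_volume_format(path, writing = TRUE)
  switch(format,
    metaimage = write_mha(vol, path),
    nifti     = write_nifti_volume(vol, path),
    dicom_dir = write_dicom_dir(vol, path))
  invisible(path)
}

guess_volume_format <- function(path, writing = FALSE) {
  if ((!writing && dir.exists(path)) ||
      (writing && !grepl("\\.[A-Za-z]", basename(path))))
    return("dicom_dir")
  low <- tolower(path)
  if (grepl("\\.mha$|\\.mhd$", low)) return("metaimage")
  if (grepl("\\.nii$|\\.nii\\.gz$", low)) return("nifti")
  stop("cannot infer volume format from path: ", path, call. = FALSE)
}

# ---- MetaImage (.mha, local raw data) --------------------------------------
# Header keys follow the MetaIO convention: DimSize/ElementSpacing/Offset are
# in (x, y, z) fastest-first order, i.e. the reverse of the package's
# (slice, row, column) array order.

write_mha <- function(vol, path) {
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s", "1 0 0 0 1 0 0 0 1"),
    sprintf("Offset = %s", paste(format(rev(vol$origin), digits = 17), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(rev(vol$spacing), digits = 17), collapse = " ")),
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  # raw data with x (array axis 3) fastest
  writeBin(as.vector(aperm(vol$data, c(3, 2, 1))), con, size = 8, endian = "little")
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("MetaImage header ended before ElementDataFile: ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", line, call. = FALSE)
    key <- trimws(kv[1]); value <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- value
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file MetaImage (ElementDataFile = LOCAL) is supported", call. = FALSE)
  if (!is.null(hdr[["CompressedData"]]) && toupper(hdr[["CompressedData"]]) == "TRUE")
    stop("compressed MetaImage data is not supported", call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(dims) != 3) stop("not a 3D MetaImage volume: ", path, call. = FALSE)
  spacing <- as.double(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  offset <- as.double(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  vals <- switch(type,
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
    MET_SHORT  = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    MET_UCHAR  = readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
    stop("unsupported MetaImage ElementType: ", type, call. = FALSE))
  if (length(vals) != n) stop("MetaImage raw data truncated: ", path, call. = FALSE)
  arr <- aperm(array(as.double(vals), dim = dims), c(3, 2, 1))
  image_volume(arr, spacing = rev(spacing), origin = rev(offset))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- NIfTI -----------------------------------------------------------------
# NIfTI arrays are (x, y, z) fastest-first; permute to (slice, row, column).
# Geometry is carried in the sform with an axis-aligned affine.

write_nifti_volume <- function(vol, path) {
  arr <- aperm(vol$data, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  aff <- diag(c(rev(vol$spacing), 1))
  aff[1:3, 4] <- rev(vol$origin)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3)
    stop("not a 3D NIfTI volume: ", path, call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing_xyz <- sqrt(colSums(rot^2))
  off_diag <- abs(rot) - diag(spacing_xyz)
  if (max(abs(off_diag)) > 1e-4 * max(spacing_xyz))
    stop("oblique NIfTI orientations are not supported: ", path, call. = FALSE)
  origin_xyz <- xf[1:3, 4]
  image_volume(aperm(arr, c(3, 2, 1)),
               spacing = rev(spacing_xyz), origin = rev(origin_xyz))
}
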