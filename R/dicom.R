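# Minimal DICOM CT series support: uncompressed little-endian transfer
# syntaxes (explicit and implicit VR), axis-aligned acquisitions.  No R DICOM
# reader ships in the dependency set, so the subset of Part 10 this pipeline
# needs is implemented here directly.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

tag_id <- function(group, element) group * 65536 + element

# tags we interpret; everything else is skipped
DICOM_DICT <- list(
  "524310"  = list(name = "SOPClassUID", vr = "UI"),          # 0008,0016
  "524312"  = list(name = "SOPInstanceUID", vr = "UI"),       # 0008,0018
  "524384"  = list(name = "Modality", vr = "CS"),             # 0008,0060
  "2097166" = list(name = "SeriesInstanceUID", vr = "UI"),    # 0020,000E
  "2097171" = list(name = "InstanceNumber", vr = "IS"),       # 0020,0013
  "2097202" = list(name = "ImagePositionPatient", vr = "DS"), # 0020,0032
  "2097207" = list(name = "ImageOrientationPatient", vr = "DS"), # 0020,0037
  "2621442" = list(name = "SamplesPerPixel", vr = "US"),      # 0028,0002
  "2621444" = list(name = "PhotometricInterpretation", vr = "CS"), # 0028,0004
  "2621456" = list(name = "Rows", vr = "US"),                 # 0028,0010
  "2621457" = list(name = "Columns", vr = "US"),              # 0028,0011
  "2621488" = list(name = "PixelSpacing", vr = "DS"),         # 0028,0030
  "2621696" = list(name = "BitsAllocated", vr = "US"),        # 0028,0100
  "2621697" = list(name = "BitsStored", vr = "US"),           # 0028,0101
  "2621698" = list(name = "HighBit", vr = "US"),              # 0028,0102
  "2621699" = list(name = "PixelRepresentation", vr = "US"),  # 0028,0103
  "2625618" = list(name = "RescaleIntercept", vr = "DS"),     # 0028,1052
  "2625619" = list(name = "RescaleSlope", vr = "DS"),         # 0028,1053
  "2145386512" = list(name = "PixelData", vr = "OW"))         # 7FE0,0010

# ---- writing ---------------------------------------------------------------

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, element, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    len <- len + 1
  }
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), dcm_uint32(len), value_raw)
  } else {
    c(head, dcm_uint16(len), value_raw)
  }
}

dcm_str <- function(group, element, vr, s) dcm_element(group, element, vr, charToRaw(s))
dcm_us <- function(group, element, x) dcm_element(group, element, "US", dcm_uint16(x))

write_dicom_dir <- function(vol, path) {
  d <- dim(vol$data)
  stored <- round(vol$data) + 1024  # rescale intercept -1024, slope 1
  if (any(stored < -32768 | stored > 32767))
    stop("HU values out of range for int16 DICOM storage", call. = FALSE)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  series_uid <- "1.2.826.0.1.3680043.9999.1"
  for (i in seq_len(d[1])) {
    # pixel data row-major: column index fastest within a row
    slice <- t(stored[i, , ])  # now [column, row]; R serialises column fastest
    pix <- writeBin(as.integer(slice), raw(), size = 2, endian = "little")
    ipp <- c(vol$origin[3], vol$origin[2], vol$origin[1] + (i - 1) * vol$spacing[1])
    ds <- c(
      dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str(0x0008, 0x0018, "UI", paste0(series_uid, ".", i)),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(i)),
      dcm_str(0x0020, 0x0032, "DS", paste(format(ipp, digits = 12), collapse = "\\")),
      dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_us(0x0028, 0x0002, 1),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[2]),
      dcm_us(0x0028, 0x0011, d[3]),
      dcm_str(0x0028, 0x0030, "DS",
              paste(format(c(vol$spacing[2], vol$spacing[3]), digits = 12), collapse = "\\")),
      dcm_us(0x0028, 0x0100, 16),
      dcm_us(0x0028, 0x0101, 16),
      dcm_us(0x0028, 0x0102, 15),
      dcm_us(0x0028, 0x0103, 1),
      dcm_str(0x0028, 0x1052, "DS", "-1024"),
      dcm_str(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    meta <- c(
      dcm_element(0x0002, 0x0002, "UI", charToRaw("1.2.840.10008.5.1.4.1.1.2")),
      dcm_element(0x0002, 0x0003, "UI", charToRaw(paste0(series_uid, ".", i))),
      dcm_element(0x0002, 0x0010, "UI", charToRaw(DICOM_EXPLICIT_LE)))
    meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta))), meta)
    con <- file(file.path(path, sprintf("slice%04d.dcm", i)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, ds), con)
    close(con)
  }
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

read_dicom_file <- function(file) {
  buf <- readBin(file, "raw", file.size(file))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", file, call. = FALSE)
  pos <- 133L
  u16 <- function(at) readBin(buf[at:(at + 1)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(buf[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  elems <- list()
  transfer <- DICOM_EXPLICIT_LE
  in_meta <- TRUE
  explicit <- TRUE
  while (pos + 7 <= length(buf)) {
    group <- u16(pos); element <- u16(pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      explicit <- transfer != DICOM_IMPLICIT_LE
      if (!transfer %in% c(DICOM_EXPLICIT_LE, DICOM_IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax ", transfer, " in ", file, call. = FALSE)
    }
    key <- as.character(tag_id(group, element))
    known <- DICOM_DICT[[key]]
    if (in_meta || explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- u32(pos + 8L); hdr_len <- 12L
      } else {
        len <- u16(pos + 6L); hdr_len <- 8L
      }
    } else {
      vr <- if (is.null(known)) "UN" else known$vr
      len <- u32(pos + 4L); hdr_len <- 8L
    }
    if (pos + hdr_len + len - 1L > length(buf))
      stop("truncated DICOM element at byte ", pos, " in ", file, call. = FALSE)
    if (!is.null(known)) {
      val_raw <- if (len > 0) buf[(pos + hdr_len):(pos + hdr_len + len - 1L)] else raw(0)
      elems[[known$name]] <- parse_dicom_value(val_raw, known$vr)
    } else if (group == 0x0002 && element == 0x0010) {
      tr_raw <- buf[(pos + hdr_len):(pos + hdr_len + len - 1L)]
      transfer <- trimws(rawToChar(tr_raw[tr_raw != as.raw(0)]))
    }
    pos <- pos + hdr_len + len
    if (!is.null(known) && known$name == "PixelData") break
  }
  elems
}

parse_dicom_value <- function(raw_val, vr) {
  txt <- function() trimws(rawToChar(raw_val[raw_val != as.raw(0)]))
  switch(vr,
    US = readBin(raw_val, "integer", length(raw_val) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    DS = as.double(strsplit(txt(), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(txt()),
    OW = raw_val,
    gsub(" ", "", txt(), fixed = TRUE))
}

read_dicom_dir <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("empty DICOM directory: ", path, call. = FALSE)
  slices <- lapply(files, read_dicom_file)
  ref <- slices[[1]]
  needed <- c("Rows", "Columns", "PixelSpacing", "ImagePositionPatient",
              "ImageOrientationPatient", "PixelData", "BitsAllocated")
  for (s in seq_along(slices)) {
    missing <- setdiff(needed, names(slices[[s]]))
    if (length(missing))
      stop("DICOM slice ", files[s], " lacks ", paste(missing, collapse = ", "), call. = FALSE)
    for (fld in c("Rows", "Columns"))
      if (!identical(slices[[s]][[fld]], ref[[fld]]))
        stop("mixed-series DICOM: ", fld, " differs in slice ", files[s], call. = FALSE)
    for (fld in c("PixelSpacing", "ImageOrientationPatient"))
      if (max(abs(slices[[s]][[fld]] - ref[[fld]])) > 1e-6)
        stop("mixed-series DICOM: ", fld, " differs in slice ", files[s], call. = FALSE)
  }
  iop <- ref$ImageOrientationPatient
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("oblique DICOM orientations are not supported", call. = FALSE)
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  proj <- vapply(slices, function(s) sum(s$ImagePositionPatient * normal), 0.0)
  ord <- order(proj)
  slices <- slices[ord]; files <- files[ord]; proj <- proj[ord]
  n1 <- length(slices)
  if (n1 > 1) {
    gaps <- diff(proj)
    if (any(gaps <= 0))
      stop("duplicate or unsorted DICOM slice positions near ",
           files[which(gaps <= 0)[1] + 1], call. = FALSE)
    if ((max(gaps) - min(gaps)) > 0.01 * mean(gaps))
      stop("non-uniform DICOM slice spacing (", format(min(gaps)), " to ",
           format(max(gaps)), " mm); offending slice ",
           files[which.max(abs(gaps - mean(gaps))) + 1], call. = FALSE)
    slice_sp <- mean(gaps)
  } else slice_sp <- 1
  rows <- ref$Rows; cols <- ref$Columns
  arr <- array(0, c(n1, rows, cols))
  for (s in seq_len(n1)) {
    el <- slices[[s]]
    if (el$BitsAllocated != 16)
      stop("only 16-bit DICOM pixel data is supported (", files[s], ")", call. = FALSE)
    signed <- !is.null(el$PixelRepresentation) && el$PixelRepresentation == 1
    vals <- readBin(el$PixelData, "integer", rows * cols, size = 2,
                    signed = signed, endian = "little")
    if (length(vals) != rows * cols)
      stop("DICOM pixel data truncated in ", files[s], call. = FALSE)
    slope <- (el$RescaleSlope %||% 1)
    inter <- (el$RescaleIntercept %||% 0)
    # row-major stored order: reading column-fastest gives [column, row]
    arr[s, , ] <- t(matrix(slope * vals + inter, nrow = cols, ncol = rows))
  }
  ipp1 <- slices[[1]]$ImagePositionPatient
  image_volume(arr,
               spacing = c(slice_sp, ref$PixelSpacing[1], ref$PixelSpacing[2]),
               origin = c(ipp1[3], ipp1[2], ipp1[1]))
}
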