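#' Write a triangle mesh as an STL file
#'
#' Both STL dialects are supported: the binary layout (80-byte header,
#' uint32 facet count, 50 bytes per facet) and the ASCII `solid ... endsolid`
#' form.  Binary is the default; it is compact and read by every slicer.
#' Facet normals are recomputed from the winding, so the on-disk normals
#' always agree with the face orientation.
#'
#' @param mesh a [triangle_mesh()]; must contain at least one face.
#' @param path output file path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (!inherits(mesh, "triangle_mesh")) stop("`mesh` must be a triangle_mesh", call. = FALSE)
  nf <- nrow(mesh$faces)
  if (nf == 0) stop("refusing to write an empty mesh to STL", call. = FALSE)
  cr <- face_cross(mesh)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), .Machine$double.xmin)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "hollow vascular model (binary STL, mm)"))
    writeBin(header[1:80], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 12 floats + uint16 attribute per facet
    block <- matrix(0, nrow = 12, ncol = nf)
    block[1:3, ] <- t(nrm)
    block[4:6, ] <- t(v1)
    block[7:9, ] <- t(v2)
    block[10:12, ] <- t(v3)
    floats <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
    dim(floats) <- c(48, nf)
    attr_bytes <- matrix(as.raw(0), nrow = 2, ncol = nf)
    writeBin(as.vector(rbind(floats, attr_bytes)), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    fmt <- paste0(
      "facet normal %.9g %.9g %.9g\n outer loop\n",
      "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
      " endloop\nendfacet")
    writeLines("solid model", con)
    writeLines(sprintf(fmt,
      nrm[, 1], nrm[, 2], nrm[, 3],
      v1[, 1], v1[, 2], v1[, 3],
      v2[, 1], v2[, 2], v2[, 3],
      v3[, 1], v3[, 2], v3[, 3]), con)
    writeLines("endsolid model", con)
  }
  invisible(path)
}

#' Read an STL file into a [triangle_mesh()]
#'
#' Detects the dialect from the file content.  Vertices repeated across
#' facets are merged by exact coordinate match, so a closed surface written
#' as a triangle soup comes back with shared vertices and testable
#' connectivity.
#'
#' @param path an STL file (binary or ASCII).
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("no such STL file: ", path, call. = FALSE)
  sz <- file.size(path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", min(sz, 84))
  is_ascii <- sz >= 6 && identical(rawToChar(head[1:5]), "solid") &&
    (sz < 84 || !binary_sizes_match(head, sz))
  close(con)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  weld_triangle_soup(tri)
}

binary_sizes_match <- function(head84, sz) {
  nf <- readBin(head84[81:84], "integer", size = 4, endian = "little")
  nf >= 0 && (84 + 50 * as.double(nf)) == sz
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", size = 4, endian = "little")
  expected <- 84 + 50 * as.double(nf)
  if (expected != sz)
    stop(sprintf(
      "binary STL facet-count header (%d facets, %d bytes) does not match file size %d; truncated at byte offset %d",
      nf, as.integer(min(expected, 2^31 - 1)), as.integer(sz), as.integer(min(sz, expected))),
      call. = FALSE)
  body <- readBin(con, "raw", 50 * nf)
  dim(body) <- c(50, nf)
  floats <- readBin(as.vector(body[1:48, , drop = FALSE]), "double",
                    n = 12 * nf, size = 4, endian = "little")
  dim(floats) <- c(12, nf)
  t(floats[4:12, , drop = FALSE])  # drop the stored normal, keep 3 vertices
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path, call. = FALSE)
  nums <- vapply(strsplit(trimws(vlines), "\\s+"),
                 function(p) as.double(p[2:4]), numeric(3))
  matrix(as.vector(nums), ncol = 9, byrow = TRUE)
}

# tri: m x 9 matrix (three xyz vertices per row) -> welded triangle_mesh
weld_triangle_soup <- function(tri) {
  m <- nrow(tri)
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "/")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3)  # rows of pts were stacked per corner
  triangle_mesh(pts[uniq, , drop = FALSE], faces)
}
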