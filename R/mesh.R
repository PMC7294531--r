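#' Triangle surface mesh in millimetres
#'
#' The printable surface type: vertex positions in mm with `(x, y, z)`
#' corresponding to the volume's (column, row, slice) axes, and triangular
#' faces wound counter-clockwise when seen from outside the solid, so face
#' normals point outward.
#'
#' @param vertices n-by-3 numeric matrix of vertex positions (mm).
#' @param faces m-by-3 integer matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3) stop("`faces` must have 3 columns", call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices)) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  extents %.3g x %.3g x %.3g mm\n",
                diff(bb[, 1]), diff(bb[, 2]), diff(bb[, 3])))
  }
  invisible(x)
}

# per-face normal vectors (not normalised) and areas
face_cross <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  a <- v2 - v1
  b <- v3 - v1
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total surface area of a mesh
#' @param mesh a [triangle_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  cr <- face_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes against the origin;
#' positive for a closed surface with outward-pointing normals.
#'
#' @param mesh a [triangle_mesh()].
#' @return Signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}
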