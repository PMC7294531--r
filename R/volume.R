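#' 3D image volume in Hounsfield units
#'
#' The common grid type for the whole pipeline: a dense 3D scalar array of CT
#' intensities together with its physical geometry.  The axis convention is
#' fixed throughout the package: array axis 1 is the slice direction (scanner
#' z), axes 2 and 3 are the in-plane row and column directions.  `spacing` and
#' `origin` are given in that same (slice, row, column) order, in millimetres,
#' so the physical position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`, componentwise.
#'
#' @param data 3D numeric array of intensities (HU). Must be finite.
#' @param spacing numeric length-3, voxel size in mm per array axis
#'   (slice, row, column); all components must be positive.
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1),
#'   in the same axis order as `spacing`.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.586, 0.586))
#' voxel_to_world(vol, c(2, 3, 4))
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume data must be finite", call. = FALSE)
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Physical <-> voxel coordinate conversion
#'
#' Voxel indices are 1-based; physical coordinates are mm in the package's
#' (slice, row, column) axis order.
#'
#' @param vol an [image_volume()].
#' @param ijk numeric vector of length 3 or an n-by-3 matrix of voxel indices.
#' @return Matrix (or vector) of physical positions in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @param xyz physical positions in mm (vector of length 3 or n-by-3 matrix).
#' @return For `world_to_voxel`, fractional 1-based voxel indices.
#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' Volume of one voxel in cubic millimetres
#' @param vol an [image_volume()] or [binary_mask()].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Binary occupancy mask on an image grid
#'
#' A mask shares the grid geometry of its source volume and takes only the
#' two values 0 and 255, matching the two-level scale consumed by the
#' downstream surface renderer (whose iso-level 128 is the midpoint).
#'
#' @param data 3D array containing only 0 and 255 (logical arrays are mapped
#'   to 0/255).
#' @inheritParams image_volume
#' @return An object of class `binary_mask` (also an `image_volume`).
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (is.logical(data)) {
    d <- dim(data)
    data <- array(as.double(data) * 255, d)
  }
  if (!all(data %in% c(0, 255)))
    stop("mask values must all be 0 or 255", call. = FALSE)
  vol <- image_volume(data, spacing, origin)
  class(vol) <- c("binary_mask", class(vol))
  vol
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d of %d set (255)\n",
              d[1], d[2], d[3], mask_count(x), length(x$data)))
  cat(sprintf("  spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of foreground (255) voxels in a mask
#' @param mask a [binary_mask()].
#' @return Integer count of 255-valued voxels.
#' @export
mask_count <- function(mask) sum(mask$data == 255)

# build a mask on the same grid as `vol`
mask_like <- function(vol, data) binary_mask(data, vol$spacing, vol$origin)

# error unless two grids agree in shape and geometry
check_same_grid <- function(a, b, what = "masks") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(what, " are on different grids (shape mismatch)", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop(what, " are on different grids (geometry mismatch)", call. = FALSE)
  invisible(TRUE)
}
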