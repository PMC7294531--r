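#' Segmentation parameters
#'
#' Carries the constants of the lumen segmentation: the assumed
#' surrounding-tissue intensity (80 HU) entering the partial-volume threshold
#' formula, the histogram bin width, the seed voxel used for connected
#' 3D object selection, and an optional region-cutting box.
#'
#' @param background_hu assumed surrounding tissue intensity; default 80 HU.
#' @param bin_width_hu histogram bin width in HU; default 1.
#' @param seed_point integer length-3 voxel index inside the target vessel,
#'   or `NULL` to skip component selection.
#' @param crop_box optional 2-by-3 matrix `rbind(lo, hi)` of voxel index
#'   ranges for region cutting, or `NULL`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(background_hu = 80, bin_width_hu = 1,
                                seed_point = NULL, crop_box = NULL) {
  if (!is.finite(background_hu)) stop("background_hu must be finite", call. = FALSE)
  if (!is.finite(bin_width_hu) || bin_width_hu <= 0)
    stop("bin_width_hu must be > 0", call. = FALSE)
  structure(list(background_hu = as.double(background_hu),
                 bin_width_hu = as.double(bin_width_hu),
                 seed_point = if (!is.null(seed_point)) as.integer(seed_point),
                 crop_box = crop_box),
            class = "segmentation_config")
}

#' Spherical region of interest as a mask
#'
#' Convenience builder for the histogram ROI around an aneurysm: voxels whose
#' centres lie within `radius_mm` of `center_mm`.
#'
#' @param vol the [image_volume()] defining the grid.
#' @param center_mm 3D point in mm, (slice, row, column) axis order.
#' @param radius_mm sphere radius in mm.
#' @return A [binary_mask()].
#' @export
roi_sphere <- function(vol, center_mm, radius_mm) {
  d <- dim(vol$data)
  w <- lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
  dz <- (w[[1]] - center_mm[1])^2
  dy <- (w[[2]] - center_mm[2])^2
  dx <- (w[[3]] - center_mm[3])^2
  dist2 <- outer(outer(dz, dy, "+"), dx, "+")
  mask_like(vol, dist2 <= radius_mm^2)
}

#' Intensity histogram over a region of interest
#'
#' Uniform-width binned counts of the HU values inside `roi` (or the whole
#' volume).  Bin centres fall on multiples of `bin_width_hu`, so with the
#' default 1 HU width integer-valued CT data land on bin centres.
#'
#' @param vol an [image_volume()].
#' @param roi a [binary_mask()] on the same grid selecting the histogrammed
#'   voxels, or `NULL` for the whole volume.
#' @param bin_width_hu bin width in HU (> 0), default 1.
#' @return An object of class `intensity_histogram` with fields `bin_edges`,
#'   `bin_centers`, `counts`, `roi_voxel_count`, `bin_width_hu`.
#' @export
compute_histogram <- function(vol, roi = NULL, bin_width_hu = 1) {
  if (bin_width_hu <= 0) stop("bin_width_hu must be > 0", call. = FALSE)
  if (is.null(roi)) {
    x <- as.vector(vol$data)
  } else {
    check_same_grid(vol, roi, "volume and ROI")
    x <- vol$data[roi$data == 255]
  }
  if (length(x) == 0)
    stop("empty ROI: histogram (and its peak) are undefined", call. = FALSE)
  bw <- bin_width_hu
  lo <- bw * floor(min(x) / bw)
  hi <- bw * ceiling(max(x) / bw)
  centers <- seq(lo, hi, by = bw)
  edges <- c(centers - bw / 2, centers[length(centers)] + bw / 2)
  idx <- pmin(pmax(floor((x - edges[1]) / bw) + 1, 1), length(centers))
  counts <- tabulate(idx, nbins = length(centers))
  structure(list(bin_edges = edges, bin_centers = centers, counts = counts,
                 roi_voxel_count = length(x), bin_width_hu = bw),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins of %.4g HU over [%.4g, %.4g] HU, %d voxels\n",
              length(x$counts), x$bin_width_hu,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              x$roi_voxel_count))
  invisible(x)
}

#' Mode of an intensity histogram
#'
#' The "peak distributed CT intensity": centre of the bin with the maximal
#' count.  Ties are broken toward the lowest-HU bin, which is the
#' conservative choice (a lower peak gives a lower threshold and keeps more
#' lumen).
#'
#' @param hist an [compute_histogram()] result.
#' @return The peak intensity in HU (a bin centre).
#' @export
histogram_peak <- function(hist) {
  if (all(hist$counts == 0)) stop("histogram has no counts", call. = FALSE)
  hist$bin_centers[which.max(hist$counts)]
}

#' Partial-volume threshold from the histogram peak
#'
#' The segmentation threshold used for surface-display lumen extraction:
#' the midpoint `(peak_hu + background_hu) / 2` between the lumen intensity
#' peak and the assumed surrounding tissue level (80 HU).  Boundary voxels
#' mix the two tissues, so the midpoint classifies a voxel as lumen when it
#' is at least half lumen by volume.
#'
#' @param peak_hu lumen histogram peak ("peak distributed CT intensity").
#' @param background_hu assumed surrounding tissue intensity, default 80 HU.
#' @return The threshold in HU, exactly `(peak_hu + background_hu) / 2`.
#' @examples
#' threshold_from_peak(336)  # 208
#' @export
threshold_from_peak <- function(peak_hu, background_hu = 80) {
  if (!all(is.finite(peak_hu)) || !all(is.finite(background_hu)))
    stop("threshold inputs must be finite", call. = FALSE)
  if (any(peak_hu < background_hu))
    warning("histogram peak below the background level; ",
            "the lumen is darker than the assumed surrounding tissue")
  (peak_hu + background_hu) / 2
}

#' Threshold a volume into a binary mask
#'
#' A voxel becomes foreground (255) iff its intensity is greater than or
#' equal to the threshold; the inclusive comparison keeps voxels exactly at
#' the threshold, and is fixed so runs are bit-reproducible.
#'
#' @param vol an [image_volume()].
#' @param threshold_hu scalar threshold in HU.
#' @return A [binary_mask()] on the same grid.
#' @export
apply_threshold <- function(vol, threshold_hu) {
  if (!is.finite(threshold_hu)) stop("threshold must be finite", call. = FALSE)
  mask_like(vol, vol$data >= threshold_hu)
}

#' Select the connected component containing a seed voxel
#'
#' The programmatic equivalent of interactive "3D object selection": keeps
#' exactly the 26-connected foreground component containing `seed_point` and
#' clears everything else.
#'
#' @param mask a [binary_mask()].
#' @param seed_point integer length-3 voxel index (1-based); must be a
#'   foreground voxel.
#' @return A [binary_mask()] containing a single connected component.
#' @export
select_component <- function(mask, seed_point) {
  seed_point <- as.integer(seed_point)
  d <- dim(mask$data)
  if (length(seed_point) != 3 || any(seed_point < 1) || any(seed_point > d))
    stop("seed_point outside the grid", call. = FALSE)
  if (mask$data[seed_point[1], seed_point[2], seed_point[3]] != 255)
    stop("seed_point lies on background; place it inside the target vessel",
         call. = FALSE)
  m <- array(0L, d)
  m[mask$data == 255] <- 1L
  labels <- .label_components(m, 26L)
  keep <- labels == labels[seed_point[1], seed_point[2], seed_point[3]]
  mask_like(mask, keep)
}

#' Region cutting: zero a mask outside an axis-aligned box
#'
#' Voxels outside `box` are set to background.  The grid shape and geometry
#' are unchanged, so downstream meshing sees the same physical frame.
#'
#' @param mask a [binary_mask()].
#' @param box 2-by-3 matrix `rbind(lo, hi)` of inclusive 1-based voxel index
#'   ranges.
#' @return A cropped [binary_mask()] on the unchanged grid.
#' @export
crop_box <- function(mask, box) {
  box <- rbind(box)
  if (!identical(dim(box), c(2L, 3L)))
    stop("`box` must be a 2-by-3 matrix rbind(lo, hi)", call. = FALSE)
  lo <- as.integer(box[1, ]); hi <- as.integer(box[2, ])
  d <- dim(mask$data)
  if (any(lo > hi)) stop("empty or inverted crop box", call. = FALSE)
  if (any(lo < 1) || any(hi > d)) stop("crop box outside the grid", call. = FALSE)
  keep <- array(FALSE, d)
  keep[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  out <- mask$data
  out[!keep] <- 0
  mask_like(mask, out)
}
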