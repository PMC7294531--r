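#' Hollow-model construction parameters
#'
#' The lumen mask becomes a printable model either by the block-complement
#' construction — binarize and invert, bounded to a solid block with a margin
#' of material around the lumen — or as a thin shell of constant physical
#' wall thickness.  At least one port is required: a sealed internal cavity
#' could neither drain nor accept a sheath, so the channel must open to the
#' exterior.
#'
#' @param mode `"block_complement"` (the inversion construction; default) or
#'   `"shell"`.
#' @param block_margin_mm solid material beyond the lumen bounding box in
#'   block mode; default 5 mm.
#' @param wall_thickness_mm shell wall thickness in mm (shell mode).
#' @param ports list of ports, each a list with `seed` (length-3 voxel index
#'   on the lumen) and `direction` (one of `"+slice"`, `"-slice"`, `"+row"`,
#'   `"-row"`, `"+col"`, `"-col"`): the lumen cross-section at the seed is
#'   extruded along that axis to the outer face of the model.
#' @return An object of class `hollow_config`.
#' @export
hollow_config <- function(mode = c("block_complement", "shell"),
                          block_margin_mm = 5, wall_thickness_mm = 2,
                          ports = list()) {
  mode <- match.arg(mode)
  if (block_margin_mm < 0) stop("block_margin_mm must be >= 0", call. = FALSE)
  if (wall_thickness_mm <= 0) stop("wall_thickness_mm must be > 0", call. = FALSE)
  if (length(ports) < 1)
    stop("at least one port is required: a sealed channel cannot be used",
         call. = FALSE)
  dirs <- c("+slice", "-slice", "+row", "-row", "+col", "-col")
  for (p in ports) {
    if (is.null(p$seed) || length(p$seed) != 3)
      stop("each port needs a length-3 `seed` voxel index", call. = FALSE)
    if (is.null(p$direction) || !p$direction %in% dirs)
      stop("port `direction` must be one of ", paste(dirs, collapse = ", "),
           call. = FALSE)
  }
  structure(list(mode = mode, block_margin_mm = as.double(block_margin_mm),
                 wall_thickness_mm = as.double(wall_thickness_mm),
                 ports = ports),
            class = "hollow_config")
}

#' Invert a binary mask
#'
#' Swaps 0 and 255 voxel-wise — the inversion step that turns a lumen mask
#' into the mould of a hollow vascular model.  Applying it twice is the
#' identity.
#'
#' @param mask a [binary_mask()].
#' @return The inverted [binary_mask()].
#' @export
invert_mask <- function(mask) {
  mask_like(mask, 255 - mask$data)
}

# expanded bounding box of foreground, in voxel indices; may exceed the grid
lumen_box <- function(lumen, margin_mm) {
  idx <- which(lumen$data == 255, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("lumen mask is empty", call. = FALSE)
  mv <- ceiling(margin_mm / lumen$spacing)
  list(lo = apply(idx, 2, min) - mv, hi = apply(idx, 2, max) + mv)
}

#' Block-complement hollow model
#'
#' The inversion construction realised as a bounded solid: foreground is the
#' lumen bounding box expanded by `block_margin_mm`, minus the lumen itself.
#' If the margin pushes the box outside the grid, the grid is padded with
#' background (the origin shifts accordingly), never truncated.
#'
#' @param lumen a nonempty [binary_mask()] of the vessel lumen.
#' @param cfg a [hollow_config()] with `mode = "block_complement"`.
#' @return A [binary_mask()] of the solid model (possibly on a padded grid).
#' @export
make_block_complement <- function(lumen, cfg) {
  if (cfg$mode != "block_complement")
    stop("config mode is not 'block_complement'", call. = FALSE)
  box <- lumen_box(lumen, cfg$block_margin_mm)
  d <- dim(lumen$data)
  pad_lo <- pmax(1 - box$lo, 0)
  pad_hi <- pmax(box$hi - d, 0)
  data <- lumen$data
  origin <- lumen$origin
  if (any(pad_lo > 0) || any(pad_hi > 0)) {
    nd <- d + pad_lo + pad_hi
    padded <- array(0, nd)
    padded[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
           pad_lo[3] + seq_len(d[3])] <- data
    data <- padded
    origin <- origin - pad_lo * lumen$spacing
    box$lo <- box$lo + pad_lo
    box$hi <- box$hi + pad_lo
    d <- nd
  }
  solid <- array(0, d)
  solid[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- 255
  solid[data == 255] <- 0
  out <- binary_mask(solid, lumen$spacing, origin)
  attr(out, "block_box") <- box
  out
}

#' Thin-shell hollow model
#'
#' Alternative construction: a wall of constant physical thickness around
#' the lumen, built by thresholding the anisotropy-aware Euclidean distance
#' transform at `wall_thickness_mm` and subtracting the lumen.  With voxels
#' of unequal size a voxel-count dilation would give direction-dependent
#' walls; the physical-distance criterion does not.
#'
#' @param lumen a nonempty [binary_mask()].
#' @param cfg a [hollow_config()] with `mode = "shell"`.
#' @return A [binary_mask()] of the shell.
#' @export
make_shell <- function(lumen, cfg) {
  if (cfg$mode != "shell") stop("config mode is not 'shell'", call. = FALSE)
  if (mask_count(lumen) == 0) stop("lumen mask is empty", call. = FALSE)
  if (cfg$wall_thickness_mm < max(lumen$spacing))
    warning("wall thickness below the largest voxel dimension; ",
            "the printed wall may be discontinuous")
  feat <- array(0L, dim(lumen$data))
  feat[lumen$data == 255] <- 1L
  d2 <- .edt_sq(feat, lumen$spacing)
  shell <- d2 <= cfg$wall_thickness_mm^2 & lumen$data != 255
  mask_like(lumen, shell)
}

port_axis <- function(direction) {
  axis <- switch(substring(direction, 2),
                 slice = 1L, row = 2L, col = 3L)
  sign <- if (substring(direction, 1, 1) == "+") 1L else -1L
  list(axis = axis, sign = sign)
}

#' Open ports so the cavity connects to the exterior
#'
#' For each configured port the lumen cross-section at the seed's slice is
#' extruded along the port axis to the outer face of the model, clearing
#' solid voxels on the way.  Afterwards the construction is verified: a
#' flood fill (6-connectivity) from outside the solid must reach every port
#' seed, i.e. a sheath pushed in from outside reaches the lumen.
#'
#' @param solid a [binary_mask()] of the model
#'   ([make_block_complement()] / [make_shell()] output).
#' @param lumen the lumen [binary_mask()]; if the solid grid was padded the
#'   lumen is embedded into it automatically.
#' @param cfg the [hollow_config()] carrying the ports.
#' @return The opened solid [binary_mask()].
#' @export
open_ports <- function(solid, lumen, cfg) {
  lumen <- conform_mask(lumen, solid)
  shift <- attr(lumen, "conform_shift") %||% c(0L, 0L, 0L)
  d <- dim(solid$data)
  out <- solid$data
  for (p in cfg$ports) {
    seed <- as.integer(p$seed) + shift
    if (any(seed < 1) || any(seed > d))
      stop("port seed outside the grid", call. = FALSE)
    if (lumen$data[seed[1], seed[2], seed[3]] != 255)
      stop("port seed must lie in the lumen", call. = FALSE)
    pa <- port_axis(p$direction)
    cross <- slice_mask(lumen$data, pa$axis, seed[pa$axis]) == 255
    run <- if (pa$sign > 0) seq(seed[pa$axis], d[pa$axis]) else seq(seed[pa$axis], 1)
    for (s in run) {
      plane <- slice_mask(out, pa$axis, s)
      plane[cross] <- 0
      out <- assign_slice(out, pa$axis, s, plane)
    }
  }
  opened <- binary_mask(out, solid$spacing, solid$origin)
  verify_ports_open(opened, lumen, cfg, shift)
  attr(opened, "block_box") <- attr(solid, "block_box")
  opened
}

slice_mask <- function(arr, axis, i) {
  switch(axis, arr[i, , ], arr[, i, ], arr[, , i])
}

assign_slice <- function(arr, axis, i, value) {
  switch(axis,
         { arr[i, , ] <- value; arr },
         { arr[, i, ] <- value; arr },
         { arr[, , i] <- value; arr })
}

verify_ports_open <- function(solid, lumen, cfg, shift = c(0L, 0L, 0L)) {
  d <- dim(solid$data)
  # pad one background voxel so the exterior is a single connected region
  cav <- array(1L, d + 2)
  cav[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
    ifelse(solid$data == 255, 0L, 1L)
  labels <- .label_components(cav, 6L)
  outside <- labels[1, 1, 1]
  for (p in cfg$ports) {
    seed <- as.integer(p$seed) + shift + 1L
    if (labels[seed[1], seed[2], seed[3]] != outside)
      stop("port '", p$direction, "' did not open the cavity to the exterior",
           call. = FALSE)
  }
  invisible(TRUE)
}

# embed `mask` into the (possibly padded) grid of `target`
conform_mask <- function(mask, target) {
  if (identical(dim(mask$data), dim(target$data)) &&
      max(abs(mask$origin - target$origin)) < 1e-9)
    return(mask)
  shift <- round((mask$origin - target$origin) / target$spacing)
  d <- dim(mask$data)
  td <- dim(target$data)
  if (any(shift < 0) || any(shift + d > td))
    stop("mask does not fit inside the target grid", call. = FALSE)
  data <- array(0, td)
  data[shift[1] + seq_len(d[1]), shift[2] + seq_len(d[2]),
       shift[3] + seq_len(d[3])] <- mask$data
  out <- binary_mask(data, target$spacing, target$origin)
  attr(out, "conform_shift") <- as.integer(shift)
  out
}
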