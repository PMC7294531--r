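#' Assemble a pipeline configuration
#'
#' One declarative object drives the whole fabrication pipeline: input (a
#' scan on disk or a named phantom preset), the histogram region of
#' interest, segmentation constants (80 HU background, bin width), the
#' hollow-model construction and its ports, and the surface extraction
#' (iso-level 128).
#'
#' @param input path to a volume readable by [read_volume()], or `NULL` when
#'   `phantom_preset` is given (exactly one of the two).
#' @param phantom_preset preset name for [phantom_preset()], or `NULL`.
#' @param roi list describing the histogram ROI: either
#'   `list(type = "sphere", center_mm =, radius_mm =)` or
#'   `list(type = "box", lo =, hi =)` (voxel indices).  Optional for presets
#'   (defaults to a sphere inside the aneurysm); required for file input.
#' @param segmentation a [segmentation_config()].
#' @param hollow a [hollow_config()], or `NULL` to derive default ports from
#'   a preset's vessel ends.
#' @param mesh a [mesh_config()].
#' @param output_dir directory for artifacts (created if missing).
#' @param seed integer seed forwarded to phantom generation.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, phantom_preset = NULL, roi = NULL,
                            segmentation = segmentation_config(),
                            hollow = NULL, mesh = mesh_config(),
                            output_dir = tempfile("vesselmold_run_"),
                            seed = 1L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(input) == is.null(phantom_preset))
    stop("give exactly one of `input` (a volume path) or `phantom_preset`",
         call. = FALSE)
  structure(list(input = input, phantom_preset = phantom_preset, roi = roi,
                 segmentation = segmentation, hollow = hollow, mesh = mesh,
                 output_dir = output_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipeline_config()]; the
#' `segmentation`, `hollow` and `mesh` sections mirror the corresponding
#' `*_config()` constructors.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", tolower(path))) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  seg <- do.call(segmentation_config, as_plain_list(raw$segmentation))
  hol <- if (!is.null(raw$hollow)) {
    h <- as_plain_list(raw$hollow)
    if (!is.null(h$ports))
      h$ports <- lapply(h$ports, function(p)
        list(seed = as.integer(unlist(p$seed)), direction = p$direction))
    do.call(hollow_config, h)
  }
  msh <- do.call(mesh_config, as_plain_list(raw$mesh))
  roi <- if (!is.null(raw$roi)) {
    r <- as_plain_list(raw$roi)
    if (!is.null(r$center_mm)) r$center_mm <- as.double(unlist(r$center_mm))
    if (!is.null(r$lo)) r$lo <- as.integer(unlist(r$lo))
    if (!is.null(r$hi)) r$hi <- as.integer(unlist(r$hi))
    r
  }
  pipeline_config(
    input = raw$input, phantom_preset = raw$phantom_preset, roi = roi,
    segmentation = seg, hollow = hol, mesh = msh,
    output_dir = raw$output_dir %||% tempfile("vesselmold_run_"),
    seed = raw$seed %||% 1L,
    log_level = raw$log_level %||% "info")
}

as_plain_list <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(v) if (is.list(v)) v else unlist(v))
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "info"))
    message("[vesselmold] ", sprintf(...))
  invisible(NULL)
}

resolve_input <- function(cfg) {
  if (!is.null(cfg$phantom_preset)) {
    spec <- phantom_preset(cfg$phantom_preset, seed = cfg$seed)
    ph <- generate_phantom(spec)
    list(volume = ph$volume, spec = spec, truth = ph$truth)
  } else {
    list(volume = read_volume(cfg$input), spec = NULL, truth = NULL)
  }
}

resolve_roi <- function(cfg, vol, spec) {
  roi <- cfg$roi
  if (is.null(roi)) {
    if (is.null(spec))
      stop("a histogram `roi` must be configured for file input", call. = FALSE)
    return(roi_sphere(vol, spec$aneurysm_center,
                      0.45 * spec$aneurysm_diameter_mm))
  }
  switch(roi$type,
    sphere = roi_sphere(vol, roi$center_mm, roi$radius_mm),
    box = {
      m <- mask_like(vol, array(TRUE, dim(vol$data)))
      crop_box(m, rbind(roi$lo, roi$hi))
    },
    stop("roi$type must be 'sphere' or 'box'", call. = FALSE))
}

resolve_seed_point <- function(cfg, vol, spec, threshold) {
  sp <- cfg$segmentation$seed_point
  if (!is.null(sp)) return(sp)
  if (is.null(spec))
    stop("segmentation seed_point must be configured for file input", call. = FALSE)
  round(world_to_voxel(vol, spec$aneurysm_center))[1, ]
}

resolve_hollow <- function(cfg, vol, spec) {
  if (!is.null(cfg$hollow)) return(cfg$hollow)
  if (is.null(spec))
    stop("a hollow config with ports must be given for file input", call. = FALSE)
  cl <- spec$centerline
  p1 <- round(world_to_voxel(vol, cl[1, ]))[1, ]
  p2 <- round(world_to_voxel(vol, cl[nrow(cl), ]))[1, ]
  hollow_config(ports = list(list(seed = p1, direction = "-col"),
                             list(seed = p2, direction = "+col")))
}

#' Run the full fabrication pipeline
#'
#' Phantom generation (or scan loading), aneurysm-region histogram, peak
#' detection, the partial-volume threshold `(peak + background)/2`,
#' thresholding, connected object selection, optional region cutting,
#' hollow-model construction with ports, iso-surface extraction at level 128
#' and STL export.  Artifacts written to `cfg$output_dir`: `lumen.mha`,
#' `hollow.mha`, `model.stl`, `report.json` (plus `phantom.mha` for preset
#' input).  Deterministic for a fixed config and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return An object of class `run_report` (invisibly also written as JSON):
#'   peak and threshold in HU, voxel counts, the [validate_mesh()] report,
#'   input/config MD5 hashes and per-stage timings in seconds.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("`cfg` must be a pipeline_config", call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inp <- clock("input", resolve_input(cfg))
  vol <- inp$volume
  if (!is.null(inp$spec)) {
    write_volume(vol, file.path(cfg$output_dir, "phantom.mha"))
    pipeline_log(cfg, "generated phantom preset '%s' (%s voxels)",
                 cfg$phantom_preset, paste(dim(vol$data), collapse = "x"))
  } else {
    pipeline_log(cfg, "loaded %s (%s voxels)", cfg$input,
                 paste(dim(vol$data), collapse = "x"))
  }

  seg <- cfg$segmentation
  lumen <- clock("segmentation", {
    roi <- resolve_roi(cfg, vol, inp$spec)
    hist <- compute_histogram(vol, roi, seg$bin_width_hu)
    peak <- histogram_peak(hist)
    threshold <- threshold_from_peak(peak, seg$background_hu)
    mask <- apply_threshold(vol, threshold)
    sp <- resolve_seed_point(cfg, vol, inp$spec, threshold)
    mask <- select_component(mask, sp)
    if (!is.null(seg$crop_box)) mask <- crop_box(mask, seg$crop_box)
    attr(mask, "peak_hu") <- peak
    attr(mask, "threshold_hu") <- threshold
    mask
  })
  peak <- attr(lumen, "peak_hu")
  threshold <- attr(lumen, "threshold_hu")
  pipeline_log(cfg, "histogram peak %g HU -> threshold %g HU, %d lumen voxels",
               peak, threshold, mask_count(lumen))
  write_volume(lumen, file.path(cfg$output_dir, "lumen.mha"))

  hollow_cfg <- resolve_hollow(cfg, vol, inp$spec)
  hollow <- clock("hollowing", {
    solid <- if (hollow_cfg$mode == "block_complement") {
      make_block_complement(lumen, hollow_cfg)
    } else {
      make_shell(lumen, hollow_cfg)
    }
    open_ports(solid, lumen, hollow_cfg)
  })
  pipeline_log(cfg, "%s model: %d solid voxels", hollow_cfg$mode,
               mask_count(hollow))
  write_volume(hollow, file.path(cfg$output_dir, "hollow.mha"))

  mesh <- clock("meshing", extract_surface(hollow, cfg$mesh))
  stl_path <- file.path(cfg$output_dir, "model.stl")
  write_stl(mesh, stl_path)
  report_mesh <- clock("validation", validate_mesh(mesh))
  pipeline_log(cfg, "surface: %d faces, watertight=%s, volume %.1f mm^3",
               nrow(mesh$faces), report_mesh$watertight,
               report_mesh$enclosed_volume_mm3)

  prov <- list(
    input = if (!is.null(cfg$input)) unname(tools::md5sum(cfg$input))
            else paste0("preset:", cfg$phantom_preset),
    lumen_mask = unname(tools::md5sum(file.path(cfg$output_dir, "lumen.mha"))),
    hollow_mask = unname(tools::md5sum(file.path(cfg$output_dir, "hollow.mha"))),
    stl = unname(tools::md5sum(stl_path)),
    config = config_hash(cfg))
  report <- structure(list(
    peak_hu = peak,
    threshold_hu = threshold,
    background_hu = seg$background_hu,
    lumen_voxel_count = mask_count(lumen),
    lumen_volume_mm3 = mask_count(lumen) * voxel_volume(lumen),
    mode = hollow_cfg$mode,
    mesh_report = report_mesh,
    provenance = prov,
    seed = cfg$seed,
    timings_s = as.list(timings)), class = "run_report")
  stopifnot(report$threshold_hu == (report$peak_hu + report$background_hu) / 2)
  writeLines(report_to_json(report), file.path(cfg$output_dir, "report.json"))
  invisible(report)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- cfg
  flat$output_dir <- NULL  # hash the science, not the destination
  saveRDS(flat, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

report_to_json <- function(report) {
  x <- unclass(report)
  x$mesh_report <- unclass(x$mesh_report)
  x$mesh_report$bounding_box_mm <- NULL
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  peak %g HU, threshold %g HU (background %g HU)\n",
              x$peak_hu, x$threshold_hu, x$background_hu))
  cat(sprintf("  lumen %d voxels (%.1f mm^3), mode %s\n",
              x$lumen_voxel_count, x$lumen_volume_mm3, x$mode))
  print(x$mesh_report)
  invisible(x)
}
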