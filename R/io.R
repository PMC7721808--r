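# TIFF / YAML / CSV input-output.
#
# Images are written as 32-bit TIFF. TIFF stores [0, 1] data, so each
# page is affinely rescaled into the unit interval and the original
# per-page range is recorded in a YAML sidecar (<file>.yml), making the
# files self-describing and the round trip lossless to 32-bit precision.

#' @noRd
write_float_tiff <- function(images, path, meta = list()) {
  if (is.matrix(images)) images <- list(images)
  ranges <- lapply(images, function(m) {
    r <- range(m)
    if (r[2] <= r[1]) r[2] <- r[1] + 1  # constant page
    r
  })
  scaled <- Map(function(m, r) (m - r[1]) / (r[2] - r[1]), images, ranges)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none")
  meta$page_ranges <- lapply(ranges, as.numeric)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @noRd
read_float_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  imgs <- Map(function(m, r) m * (r[2] - r[1]) + r[1], pages,
              meta$page_ranges)
  list(images = imgs, meta = meta)
}

#' Write / read a GLIM frame set as multi-page TIFF
#'
#' Four pages ordered by modulator phase, plus a YAML sidecar carrying
#' pixel size, shear geometry and per-page intensity ranges.
#'
#' @param fs a `glim_frameset`.
#' @param path output `.tif` path.
#' @return `path`, invisibly (`write_frameset`); a `glim_frameset`
#'   (`read_frameset`).
#' @export
write_frameset <- function(fs, path) {
  stopifnot(inherits(fs, "glim_frameset"))
  write_float_tiff(fs$frames, path,
                   meta = list(kind = "glim_frameset",
                               modulation_phases = fs$modulation_phases,
                               pixel_size_um = fs$pixel_size_um,
                               shear_px = fs$shear_px,
                               shear_angle_rad = fs$shear_angle_rad))
}

#' @rdname write_frameset
#' @export
read_frameset <- function(path) {
  r <- read_float_tiff(path)
  stopifnot(identical(r$meta$kind, "glim_frameset"), length(r$images) == 4L)
  new_frameset(r$images, pixel_size_um = r$meta$pixel_size_um,
               shear_px = r$meta$shear_px,
               shear_angle_rad = r$meta$shear_angle_rad)
}

#' Write / read a phase map as 32-bit TIFF
#'
#' @param phi a `phase_map`.
#' @param path output `.tif` path.
#' @export
write_phase <- function(phi, path) {
  stopifnot(inherits(phi, "phase_map"))
  write_float_tiff(phi$phi, path,
                   meta = list(kind = "phase_map", units = "radians",
                               pixel_size_um = phi$pixel_size_um))
}

#' @rdname write_phase
#' @export
read_phase <- function(path) {
  r <- read_float_tiff(path)
  stopifnot(identical(r$meta$kind, "phase_map"))
  structure(list(phi = r$images[[1]], pixel_size_um = r$meta$pixel_size_um),
            class = "phase_map")
}

#' Write a ground-truth scene to disk
#'
#' Phase and fluorescence as a multi-page 32-bit TIFF (pages: phase,
#' DAPI, DiI) with a YAML sidecar of the scene parameters; masks as
#' 8-bit TIFF.
#'
#' @param scene a `glim_scene`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  stopifnot(inherits(scene, "glim_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(stem, ".tif"))
  p <- scene$params
  write_float_tiff(list(scene$phase_truth, scene$fluor_dapi, scene$fluor_dil),
                   img_path,
                   meta = list(kind = "glim_scene",
                               pages = c("phase", "dapi", "dil"),
                               params = p[setdiff(names(p), "noise_model")],
                               noise_model = p$noise_model))
  mask_path <- file.path(dir, paste0(stem, "_masks.tif"))
  tiff::writeTIFF(list(scene$nucleus_mask + 0, scene$cell_mask + 0),
                  mask_path, bits.per.sample = 8L, compression = "none")
  invisible(c(images = img_path, masks = mask_path))
}

#' @noRd
write_records_csv <- function(records, path) {
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(x) signif(x, 12))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
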