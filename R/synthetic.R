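# Synthetic adherent-cell scenes and the GLIM forward model.
#
# Scenes emulate sparse-to-confluent monolayers: elliptical cells with
# denser elliptical nuclei, phase proportional to dry-mass density, a
# DIC shear-difference forward model and Poisson/Gaussian camera noise.
# Every downstream stage of the pipeline can therefore be exercised with
# known ground truth and no external data.

#' Parameters of a synthetic cell scene
#'
#' Bundles the geometry, optics and noise settings from which
#' [generate_scene()] and [simulate_glim_frames()] are deterministic
#' functions. Defaults describe a moderately sparse monolayer of
#' adherent epithelial-like cells imaged at high magnification.
#'
#' @param field_size_px integer length-2, image height and width in pixels.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param n_cells number of cells attempted (overlap rejection may place
#'   fewer in crowded fields).
#' @param cell_radius_um mean and sd of the equivalent cell radius, in
#'   micrometres (length-2 numeric).
#' @param nucleus_fraction nucleus radius as a fraction of the cell radius,
#'   in (0, 1).
#' @param peak_phase_rad maximum phase delay at the cell centre, radians.
#' @param nucleus_phase_boost multiplicative density excess of the nucleus
#'   over the surrounding cytoplasm (>= 1); nuclei are denser in QPI data.
#' @param eccentricity_range range of the minor/major axis ratio of the
#'   random ellipses; `c(1, 1)` forces circular cells.
#' @param blur_sigma_px optical blur applied to the phase map (pixels).
#' @param shear_px DIC shear magnitude in pixels (>= 0).
#' @param shear_angle_rad shear direction, measured from the +x axis.
#' @param noise_model list with elements `gaussian_sd` (additive read noise
#'   on intensity frames) and `poisson_scale` (photons per intensity unit;
#'   0 disables shot noise).
#' @param seed integer seed; the same seed reproduces the scene bit for bit.
#'
#' @return An object of class `scene_params`.
#' @seealso [generate_scene()], [simulate_glim_frames()]
#' @export
#' @examples
#' p <- scene_params(field_size_px = c(128, 128), n_cells = 5, seed = 1)
#' sc <- generate_scene(p)
#' range(sc$phase_truth)
scene_params <- function(field_size_px = c(256, 256),
                         pixel_size_um = 0.3,
                         n_cells = 12,
                         cell_radius_um = c(6, 1),
                         nucleus_fraction = 0.5,
                         peak_phase_rad = 2,
                         nucleus_phase_boost = 1.5,
                         eccentricity_range = c(0.6, 1),
                         blur_sigma_px = 1,
                         shear_px = 2,
                         shear_angle_rad = 0.5,
                         noise_model = list(gaussian_sd = 0.005,
                                            poisson_scale = 0),
                         seed = 1L) {
  field_size_px <- as.integer(field_size_px)
  stopifnot(length(field_size_px) == 2L, all(field_size_px > 0),
            is_scalar_num(pixel_size_um), pixel_size_um > 0,
            n_cells >= 0,
            length(cell_radius_um) == 2L, cell_radius_um[1] > 0,
            cell_radius_um[2] >= 0,
            is_scalar_num(nucleus_fraction),
            nucleus_fraction > 0, nucleus_fraction < 1,
            is_scalar_num(peak_phase_rad), peak_phase_rad > 0,
            is_scalar_num(nucleus_phase_boost), nucleus_phase_boost >= 1,
            length(eccentricity_range) == 2L,
            all(eccentricity_range > 0), all(eccentricity_range <= 1),
            is_scalar_num(shear_px), shear_px >= 0,
            is_scalar_num(shear_angle_rad))
  if (cell_radius_um[1] / pixel_size_um > min(field_size_px) / 2) {
    stop("mean cell radius exceeds half the field of view")
  }
  noise_model$gaussian_sd <- noise_model$gaussian_sd %||% 0
  noise_model$poisson_scale <- noise_model$poisson_scale %||% 0
  structure(list(field_size_px = field_size_px,
                 pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells),
                 cell_radius_um = cell_radius_um,
                 nucleus_fraction = nucleus_fraction,
                 peak_phase_rad = peak_phase_rad,
                 nucleus_phase_boost = nucleus_phase_boost,
                 eccentricity_range = eccentricity_range,
                 blur_sigma_px = blur_sigma_px,
                 shear_px = shear_px,
                 shear_angle_rad = shear_angle_rad,
                 noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' @export
print.scene_params <- function(x, ...) {
  cat("<scene_params> ", x$field_size_px[1], "x", x$field_size_px[2],
      " px, ", x$n_cells, " cells, shear ", x$shear_px, " px @ ",
      round(x$shear_angle_rad, 3), " rad, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Rasterise a filled ellipse: TRUE where
# ((x-cx)cosA + (y-cy)sinA)^2/a^2 + (-(x-cx)sinA + (y-cy)cosA)^2/b^2 <= 1.
# Pixel (i, j) is sampled at its centre (y = i, x = j), 1-based.
#' @noRd
ellipse_mask <- function(dim_hw, cy, cx, a, b, angle = 0) {
  y <- matrix(seq_len(dim_hw[1]), dim_hw[1], dim_hw[2])
  x <- matrix(seq_len(dim_hw[2]), dim_hw[1], dim_hw[2], byrow = TRUE)
  u <- (x - cx) * cos(angle) + (y - cy) * sin(angle)
  v <- -(x - cx) * sin(angle) + (y - cy) * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

# Smooth dome profile over the same ellipse: max(0, 1 - r^2), so each cell
# contributes a paraboloid cap of unit height (phase ~ dry-mass density).
#' @noRd
ellipse_dome <- function(dim_hw, cy, cx, a, b, angle = 0) {
  y <- matrix(seq_len(dim_hw[1]), dim_hw[1], dim_hw[2])
  x <- matrix(seq_len(dim_hw[2]), dim_hw[1], dim_hw[2], byrow = TRUE)
  u <- (x - cx) * cos(angle) + (y - cy) * sin(angle)
  v <- -(x - cx) * sin(angle) + (y - cy) * cos(angle)
  pmax(1 - (u / a)^2 - (v / b)^2, 0)
}

#' Generate a ground-truth cell scene
#'
#' Places random ellipses (cells) with concentric denser nuclei, rejecting
#' candidates that would overlap existing cells by more than half their
#' area, and builds the true phase map as a blurred sum of unit-height
#' cell-body domes plus nuclear excess. Fluorescence channels are derived
#' from the masks by [simulate_fluorescence()].
#'
#' @param params a [scene_params()] object.
#' @return An object of class `glim_scene`: a list with `phase_truth`
#'   (radians, >= 0), logical `nucleus_mask` and `cell_mask`
#'   (`nucleus_mask` is a subset of `cell_mask`), fluorescence channels
#'   `fluor_dapi` and `fluor_dil`, the per-cell geometry table `cells`,
#'   and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$seed, generate_scene_impl(params))
}

#' @noRd
generate_scene_impl <- function(params) {
  hw <- params$field_size_px
  cell_mask <- matrix(FALSE, hw[1], hw[2])
  nucleus_mask <- matrix(FALSE, hw[1], hw[2])
  phase <- matrix(0, hw[1], hw[2])
  cells <- list()
  r_px_mean <- params$cell_radius_um[1] / params$pixel_size_um
  r_px_sd <- params$cell_radius_um[2] / params$pixel_size_um
  n_placed <- 0L
  if (params$n_cells > 0) {
    for (k in seq_len(params$n_cells)) {
      for (try in seq_len(25L)) {
        r <- max(2, stats::rnorm(1, r_px_mean, r_px_sd))
        ecc <- stats::runif(1, params$eccentricity_range[1],
                            params$eccentricity_range[2])
        a <- r / sqrt(ecc); b <- r * sqrt(ecc)  # preserve area ~ pi r^2
        ang <- stats::runif(1, 0, pi)
        cy <- stats::runif(1, 1 + b, hw[1] - b)
        cx <- stats::runif(1, 1 + b, hw[2] - b)
        cand <- ellipse_mask(hw, cy, cx, a, b, ang)
        if (sum(cand & cell_mask) <= 0.5 * sum(cand)) {
          n_placed <- n_placed + 1L
          cell_mask <- cell_mask | cand
          nuc <- ellipse_mask(hw, cy, cx, a * params$nucleus_fraction,
                              b * params$nucleus_fraction, ang)
          nucleus_mask <- nucleus_mask | nuc
          phase <- phase +
            params$peak_phase_rad * ellipse_dome(hw, cy, cx, a, b, ang) +
            params$peak_phase_rad * (params$nucleus_phase_boost - 1) *
              ellipse_dome(hw, cy, cx, a * params$nucleus_fraction,
                           b * params$nucleus_fraction, ang)
          cells[[n_placed]] <- data.frame(cy = cy, cx = cx, a = a, b = b,
                                          angle = ang)
          break
        }
      }
    }
  }
  nucleus_mask <- nucleus_mask & cell_mask
  if (params$blur_sigma_px > 0) {
    phase <- pmax(gaussian_blur(phase, params$blur_sigma_px), 0)
  }
  fl <- simulate_fluorescence(list(nucleus = nucleus_mask, cell = cell_mask),
                              blur_sigma = params$blur_sigma_px,
                              noise_model = list(gaussian_sd = 0,
                                                 poisson_scale = 0))
  structure(list(phase_truth = phase,
                 nucleus_mask = nucleus_mask,
                 cell_mask = cell_mask,
                 fluor_dapi = fl$dapi,
                 fluor_dil = fl$dil,
                 cells = if (n_placed) do.call(rbind, cells) else
                   data.frame(cy = numeric(), cx = numeric(), a = numeric(),
                              b = numeric(), angle = numeric()),
                 params = params),
            class = "glim_scene")
}

#' @export
print.glim_scene <- function(x, ...) {
  cat("<glim_scene> ", nrow(x$phase_truth), "x", ncol(x$phase_truth),
      " px, ", nrow(x$cells), " cells, confluence ",
      round(mean(x$cell_mask), 3), "\n", sep = "")
  invisible(x)
}

#' Simulate fluorescence channels from compartment masks
#'
#' Emulates the co-registered training channels: a DAPI-like image supported
#' on the nucleus mask and a DiI-like image supported on the cell-body mask,
#' each `gain * mask + background`, optionally blurred and corrupted by
#' Poisson shot noise and Gaussian read noise.
#'
#' @param masks list with logical `nucleus` and `cell` matrices.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param noise_model list with `gaussian_sd` and `poisson_scale` (photons
#'   per intensity unit; 0 disables shot noise).
#' @param gain,background intensity of the stained region and the
#'   unstained floor.
#' @return list with non-negative matrices `dapi` and `dil`.
#' @export
simulate_fluorescence <- function(masks, blur_sigma = 0,
                                  noise_model = list(gaussian_sd = 0,
                                                     poisson_scale = 0),
                                  gain = 1, background = 0) {
  stopifnot(is.logical(masks$nucleus), is.logical(masks$cell),
            all(dim(masks$nucleus) == dim(masks$cell)))
  one <- function(m) {
    img <- gain * (m + 0) + background
    if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
    ps <- noise_model$poisson_scale %||% 0
    if (ps > 0) img <- stats::rpois(length(img), pmax(img, 0) * ps) / ps
    gs <- noise_model$gaussian_sd %||% 0
    if (gs > 0) img <- img + stats::rnorm(length(img), 0, gs)
    matrix(pmax(img, 0), nrow(m), ncol(m))
  }
  list(dapi = one(masks$nucleus), dil = one(masks$cell))
}

#' Forward-simulate a four-frame GLIM acquisition
#'
#' The GLIM camera records the interference of the sample field with its
#' shear-displaced copy while the modulator steps the offset phase through
#' 0, pi/2, pi, 3*pi/2:
#' \deqn{I_n = I_1 + I_2 + 2\sqrt{I_1 I_2}\cos(\Delta\phi + n\pi/2),}
#' where \eqn{\Delta\phi(x) = \phi(x) - \phi(x - s)} is the phase difference
#' along the shear vector \eqn{s} (computed exactly, with periodic
#' boundary). Camera noise follows `params$noise_model` unless disabled.
#'
#' @param scene a `glim_scene` (or any list with a `phase_truth` matrix).
#' @param params a [scene_params()] object; supplies shear and noise.
#' @param beam_intensity intensities `c(I1, I2)` of the two sheared beams.
#' @param noiseless logical; if `TRUE` the closed-form frames are returned
#'   with no noise regardless of `params$noise_model`.
#' @return A `glim_frameset`: list with `frames` (list of four matrices),
#'   `modulation_phases`, `pixel_size_um`, `shear_px`, `shear_angle_rad`,
#'   and the true gradient `dphi_truth`.
#' @export
simulate_glim_frames <- function(scene, params, beam_intensity = c(0.5, 0.5),
                                 noiseless = FALSE) {
  stopifnot(inherits(params, "scene_params"), params$shear_px >= 0,
            length(beam_intensity) == 2L, all(beam_intensity > 0))
  dphi <- shear_difference(scene$phase_truth, params$shear_px,
                           params$shear_angle_rad)
  i1 <- beam_intensity[1]; i2 <- beam_intensity[2]
  amp <- 2 * sqrt(i1 * i2)
  mk <- function(n) i1 + i2 + amp * cos(dphi + n * pi / 2)
  frames <- lapply(0:3, mk)
  if (!noiseless) {
    frames <- withr::with_seed(params$seed + 7919L, lapply(frames, function(f) {
      ps <- params$noise_model$poisson_scale %||% 0
      if (ps > 0) f <- stats::rpois(length(f), pmax(f, 0) * ps) / ps
      gs <- params$noise_model$gaussian_sd %||% 0
      if (gs > 0) f <- f + stats::rnorm(length(f), 0, gs)
      matrix(f, nrow(dphi), ncol(dphi))
    }))
  }
  new_frameset(frames, pixel_size_um = params$pixel_size_um,
               shear_px = params$shear_px,
               shear_angle_rad = params$shear_angle_rad,
               dphi_truth = dphi)
}

#' Construct a GLIM frame set
#'
#' @param frames list of exactly four numeric matrices of identical shape,
#'   ordered by modulator phase 0, pi/2, pi, 3*pi/2.
#' @param pixel_size_um pixel pitch.
#' @param shear_px,shear_angle_rad shear geometry used at acquisition.
#' @param dphi_truth optional ground-truth gradient (simulation only).
#' @return object of class `glim_frameset`.
#' @export
new_frameset <- function(frames, pixel_size_um = 1, shear_px = NA_real_,
                         shear_angle_rad = NA_real_, dphi_truth = NULL) {
  stopifnot(is.list(frames), length(frames) == 4L)
  d <- dim(frames[[1]])
  for (f in frames) {
    stopifnot(is.matrix(f), all(dim(f) == d), all(is.finite(f)))
  }
  structure(list(frames = frames,
                 modulation_phases = c(0, pi / 2, pi, 3 * pi / 2),
                 pixel_size_um = pixel_size_um,
                 shear_px = shear_px,
                 shear_angle_rad = shear_angle_rad,
                 dphi_truth = dphi_truth),
            class = "glim_frameset")
}

#' Generate a synthetic time-lapse with exponential dry-mass growth
#'
#' Keeps the geometry of each field of view fixed (one seeded scene per
#' FOV) and scales the phase map as \eqn{2^{t/T_d}} so that total, nuclear
#' and cytoplasmic dry mass all double every `doubling_time_h` hours --
#' the idealised regime against which the quantification stage is
#' validated.
#'
#' @param params base [scene_params()]; each FOV uses `seed + fov`.
#' @param times_h numeric vector of acquisition times (hours).
#' @param doubling_time_h dry-mass doubling time (hours).
#' @param n_fov number of fields of view.
#' @return list of FOVs; each has `scene` (the t = 0 scene) and `frames`,
#'   a list (over time) of `glim_frameset`s, plus `phase_t`, the true
#'   scaled phase maps.
#' @export
generate_timelapse <- function(params, times_h, doubling_time_h = 24,
                               n_fov = 1) {
  stopifnot(inherits(params, "scene_params"), length(times_h) >= 1,
            doubling_time_h > 0, n_fov >= 1)
  lapply(seq_len(n_fov), function(fv) {
    p <- params
    p$seed <- params$seed + fv
    sc <- generate_scene(p)
    phase_t <- lapply(times_h, function(t) sc$phase_truth * 2^(t / doubling_time_h))
    frames <- lapply(seq_along(times_h), function(ti) {
      pt <- p
      pt$seed <- p$seed + 1000L * ti  # independent noise per timepoint
      simulate_glim_frames(list(phase_truth = phase_t[[ti]]), pt)
    })
    list(fov = fv, scene = sc, times_h = times_h, phase_t = phase_t,
         frames = frames)
  })
}
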