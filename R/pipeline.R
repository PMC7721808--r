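# End-to-end orchestration: simulate -> reconstruct -> train -> infer ->
# quantify, mirroring the two-step experimental protocol in silico: the
# time-lapse is recorded label-free, the (synthetic) stain exists only at
# the final timepoint, the network is trained on those final-timepoint
# pairs, and inference runs backwards over the whole sequence.

#' Configuration of an end-to-end run
#'
#' @param out_dir artifact directory (created).
#' @param scene a [scene_params()]; per-FOV seeds are derived from it.
#' @param times_h acquisition times in hours.
#' @param doubling_time_h true dry-mass doubling time of the simulation.
#' @param n_fov number of fields of view.
#' @param predictor `"network"` (train and apply the U-Net) or `"oracle"`
#'   (use the ground-truth fluorescence as the prediction, bypassing the
#'   network; the quantification-only ablation).
#' @param unet a [unet_spec()] for the network mode.
#' @param train_cfg a [train_config()].
#' @param mass_cfg a [dry_mass_config()]; pixel size is taken from the
#'   scene.
#' @param epsilon integration regulariser.
#' @param pad_px inference mirror padding.
#' @param thresholds,min_object_px segmentation settings (see
#'   [segment()]).
#' @param baseline_h growth-curve baseline window (hours).
#' @param seed master seed for the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       scene = scene_params(),
                       times_h = seq(0, 12, by = 2),
                       doubling_time_h = 24,
                       n_fov = 2,
                       predictor = c("network", "oracle"),
                       unet = unet_spec(depth = 3, base_width = 8),
                       train_cfg = train_config(epochs = 10),
                       mass_cfg = dry_mass_config(),
                       epsilon = 1e-3,
                       pad_px = 32,
                       thresholds = list(),
                       min_object_px = 9,
                       baseline_h = 6,
                       seed = 1L) {
  predictor <- match.arg(predictor)
  mass_cfg$pixel_size_um <- scene$pixel_size_um
  mass_cfg$pixel_area_um2 <- scene$pixel_size_um^2
  structure(list(out_dir = out_dir, scene = scene, times_h = times_h,
                 doubling_time_h = doubling_time_h, n_fov = n_fov,
                 predictor = predictor, unet = unet, train_cfg = train_cfg,
                 mass_cfg = mass_cfg, epsilon = epsilon, pad_px = pad_px,
                 thresholds = thresholds, min_object_px = min_object_px,
                 baseline_h = baseline_h, seed = as.integer(seed)),
            class = "run_config")
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full PICS pipeline on synthetic data
#'
#' Generates a seeded time-lapse per field of view, reconstructs phase
#' from the simulated four-frame acquisitions, trains one U-Net per
#' fluorophore on the final timepoint (or uses the ground-truth
#' fluorescence in oracle mode), infers specificity maps for every
#' timepoint, segments them, and writes per-timepoint mass records,
#' normalized growth curves, and a JSON manifest into `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return list with `records` (mass-record data.frame), `growth`
#'   (see [growth_curves()]), `models` (trained checkpoints or NULL),
#'   `manifest`, and `paths` of the written artifacts.
#' @export
run_end_to_end <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  scene_p <- cfg$scene
  scene_p$seed <- cfg$seed * 1000L + scene_p$seed

  tl <- stage("simulate", generate_timelapse(scene_p, cfg$times_h,
                                             cfg$doubling_time_h, cfg$n_fov))

  recon <- stage("reconstruct", lapply(tl, function(fov) {
    lapply(fov$frames, function(fs) {
      g <- reconstruct_gradient(fs)
      rebase_phase(integrate_gradient(g, epsilon = cfg$epsilon))
    })
  }))

  n_t <- length(cfg$times_h)
  phase_rng <- stage("normalize", compute_range(
    lapply(recon, function(f) f[[n_t]]$phi)))
  fl_rng <- list(
    dapi = compute_range(lapply(tl, function(f) f$scene$fluor_dapi)),
    dil = compute_range(lapply(tl, function(f) f$scene$fluor_dil)))

  models <- NULL
  if (cfg$predictor == "network") {
    models <- stage("train", {
      mk_pairs <- function(channel) {
        lapply(seq_along(tl), function(fv) {
          list(x = normalize_image(recon[[fv]][[n_t]]$phi, phase_rng),
               y = normalize_image(
                 tl[[fv]]$scene[[paste0("fluor_", channel)]], fl_rng[[channel]]))
        })
      }
      lapply(c(dapi = "dapi", dil = "dil"), function(ch) {
        m <- build_model(cfg$unet, seed = cfg$seed)
        m$norm <- list(input = phase_rng, output = fl_rng[[ch]])
        fit <- train(m, mk_pairs(ch), cfg$train_cfg)
        fit$model
      })
    })
    for (ch in names(models)) {
      saveRDS(models[[ch]], file.path(cfg$out_dir,
                                      paste0("model_", ch, ".rds")))
    }
  }

  predict_channel <- function(fv, ti, ch) {
    if (cfg$predictor == "oracle") {
      normalize_image(tl[[fv]]$scene[[paste0("fluor_", ch)]], fl_rng[[ch]])
    } else {
      infer(models[[ch]], normalize_image(recon[[fv]][[ti]]$phi, phase_rng),
            pad_px = cfg$pad_px)
    }
  }

  records <- stage("quantify", {
    rows <- list()
    for (fv in seq_along(tl)) {
      for (ti in seq_len(n_t)) {
        pm <- recon[[fv]][[ti]]
        masks <- segment(predict_channel(fv, ti, "dapi"),
                         predict_channel(fv, ti, "dil"),
                         thresholds = cfg$thresholds,
                         min_object_px = cfg$min_object_px)
        rows[[length(rows) + 1]] <-
          mass_record(pm, masks, cfg$mass_cfg,
                      time_h = cfg$times_h[ti], fov_id = fv)
      }
      write_phase(recon[[fv]][[n_t]],
                  file.path(cfg$out_dir, sprintf("phase_fov%02d.tif", fv)))
    }
    do.call(rbind, rows)
  })

  growth <- stage("growth", growth_curves(records,
                                          baseline_h = cfg$baseline_h))

  paths <- list(records = file.path(cfg$out_dir, "mass_records.csv"),
                growth = file.path(cfg$out_dir, "growth_curves.csv"),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  write_records_csv(records, paths$records)
  write_records_csv(growth$per_fov, paths$growth)
  manifest <- list(package = "pics",
                   version = as.character(utils::packageVersion("pics")),
                   seed = cfg$seed, predictor = cfg$predictor,
                   n_fov = cfg$n_fov, times_h = cfg$times_h,
                   doubling_time_h = cfg$doubling_time_h,
                   field_size_px = scene_p$field_size_px,
                   doubling_time_est_h = unname(growth$doubling_time_h),
                   outputs = list.files(cfg$out_dir))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(records = records, growth = growth, models = models,
       manifest = manifest, paths = paths)
}

#' @noRd
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Compare predicted channels against ground truth
#'
#' Computes the pooled Pearson correlation per channel, the Jaccard index
#' of the segmentation masks derived from predicted vs. true channels,
#' and the percent dry-mass discrepancy between the two nucleus masks.
#'
#' @param pred list with `dapi` and `dil`: lists of predicted matrices in
#'   [0, 1].
#' @param truth list with `dapi` and `dil` (same layout), and optionally
#'   `phase` (list of matrices or `phase_map`s for the mass comparison).
#' @param mass_cfg a [dry_mass_config()].
#' @param thresholds,min_object_px segmentation settings.
#' @param json_path optional path; when given the report is also written
#'   as JSON.
#' @return list (stable schema): `rho` (per channel), `jaccard`
#'   (nucleus/cell), `mass_discrepancy_pct` (per image, nucleus masks),
#'   `n_images`.
#' @export
validate_against_truth <- function(pred, truth, mass_cfg = dry_mass_config(),
                                   thresholds = list(), min_object_px = 9,
                                   json_path = NULL) {
  stopifnot(length(pred$dapi) == length(truth$dapi),
            length(pred$dil) == length(truth$dil))
  n <- length(pred$dapi)
  rho <- list(dapi = pearson_quality(pred$dapi, truth$dapi),
              dil = pearson_quality(pred$dil, truth$dil))
  jn <- jc <- mass_pct <- numeric(n)
  for (i in seq_len(n)) {
    mp <- segment(pred$dapi[[i]], pred$dil[[i]], thresholds, min_object_px)
    mt <- segment(truth$dapi[[i]], truth$dil[[i]], thresholds, min_object_px)
    jn[i] <- jaccard(mp$nucleus, mt$nucleus)
    jc[i] <- jaccard(mp$cell, mt$cell)
    mass_pct[i] <- if (!is.null(truth$phase)) {
      ph <- truth$phase[[i]]
      if (inherits(ph, "phase_map")) ph <- ph$phi
      if (dry_mass(ph, mt$nucleus, mass_cfg) > 0) {
        mask_mass_discrepancy(ph, mp$nucleus, mt$nucleus, mass_cfg)
      } else NA_real_
    } else NA_real_
  }
  report <- list(rho = rho,
                 jaccard = list(nucleus = mean(jn), cell = mean(jc)),
                 mass_discrepancy_pct = if (all(is.na(mass_pct))) NULL else
                   mean(mass_pct, na.rm = TRUE),
                 n_images = n)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
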