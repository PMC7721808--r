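# Compartment masks, dry mass, confluence and growth curves.

#' Dry-mass conversion constants
#'
#' The standard QPI dry-mass relation converts integrated phase to mass:
#' \deqn{m = \frac{\lambda}{2\pi\gamma} \sum_{\mathrm{mask}} \phi(x, y)\,
#' A_{\mathrm{pixel}},}
#' with \eqn{\lambda} the centre illumination wavelength and \eqn{\gamma}
#' the refractive increment of protein. Both are literature defaults
#' (0.55 um white-light centre; 0.2 ml/g), configurable here. With
#' \eqn{\lambda} in um, area in um^2 and \eqn{\gamma} in ml/g
#' (= um^3/pg), the mass comes out in picograms.
#'
#' @param wavelength_um centre illumination wavelength (um).
#' @param refractive_increment_ml_per_g protein refractive increment
#'   (ml/g).
#' @param pixel_size_um pixel pitch (um); pixel area is its square.
#' @return object of class `dry_mass_config`.
#' @export
dry_mass_config <- function(wavelength_um = 0.55,
                            refractive_increment_ml_per_g = 0.2,
                            pixel_size_um = 0.3) {
  stopifnot(wavelength_um > 0, refractive_increment_ml_per_g > 0,
            pixel_size_um > 0)
  structure(list(wavelength_um = wavelength_um,
                 refractive_increment_ml_per_g = refractive_increment_ml_per_g,
                 pixel_size_um = pixel_size_um,
                 pixel_area_um2 = pixel_size_um^2),
            class = "dry_mass_config")
}

#' Segment predicted fluorescence into compartment masks
#'
#' Thresholds the DAPI-like (nucleus) and DiI-like (cell body) channels --
#' Otsu's method per image by default, or fixed values -- removes objects
#' smaller than `min_object_px`, clips the nucleus mask to the cell mask,
#' and takes the set difference as cytoplasm, yielding the semantic
#' segmentation map that distinguishes nuclear from non-nuclear content.
#'
#' @param pred_dapi,pred_dil matrices in [0, 1].
#' @param thresholds optional list with numeric `dapi` and/or `dil`
#'   overriding Otsu.
#' @param min_object_px connected components smaller than this are
#'   dropped (default 9).
#' @return object of class `compartment_masks`: logical `nucleus`, `cell`,
#'   `cytoplasm` matrices with `cytoplasm == cell & !nucleus`.
#' @export
segment <- function(pred_dapi, pred_dil, thresholds = list(),
                    min_object_px = 9) {
  stopifnot(is.matrix(pred_dapi), is.matrix(pred_dil),
            all(dim(pred_dapi) == dim(pred_dil)),
            all(pred_dapi >= 0 & pred_dapi <= 1),
            all(pred_dil >= 0 & pred_dil <= 1))
  one <- function(img, thr) {
    if (is.null(thr)) {
      if (diff(range(img)) < .Machine$double.eps) {
        return(matrix(FALSE, nrow(img), ncol(img)))  # empty field
      }
      thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    }
    m <- img > thr
    drop_small_objects(m, min_object_px)
  }
  cell <- one(pred_dil, thresholds$dil)
  nucleus <- one(pred_dapi, thresholds$dapi) & cell
  structure(list(nucleus = nucleus, cell = cell,
                 cytoplasm = cell & !nucleus),
            class = "compartment_masks")
}

#' @noRd
drop_small_objects <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask + 0))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
}

#' Dry mass under a mask
#'
#' Linear in the phase, additive over disjoint masks, zero for an empty
#' mask. See [dry_mass_config()] for the conversion.
#'
#' @param phi a `phase_map` or matrix (radians).
#' @param mask logical matrix, same shape.
#' @param cfg a [dry_mass_config()]; its `pixel_size_um` is overridden by
#'   the phase map's own, when present.
#' @return dry mass in picograms.
#' @export
dry_mass <- function(phi, mask, cfg = dry_mass_config()) {
  stopifnot(inherits(cfg, "dry_mass_config"))
  px <- cfg$pixel_area_um2
  if (inherits(phi, "phase_map")) {
    if (is.finite(phi$pixel_size_um)) px <- phi$pixel_size_um^2
    phi <- phi$phi
  }
  stopifnot(is.matrix(phi), is.logical(mask), all(dim(mask) == dim(phi)))
  cfg$wavelength_um / (2 * pi * cfg$refractive_increment_ml_per_g) *
    sum(phi[mask]) * px
}

#' Confluence of a field
#'
#' Fraction of the field area occupied by cells.
#'
#' @param cell_mask logical matrix.
#' @return scalar in [0, 1].
#' @export
confluence <- function(cell_mask) {
  stopifnot(is.logical(cell_mask))
  mean(cell_mask)
}

#' Count cells from a nucleus mask
#'
#' Connected-component count after small-object removal. Touching nuclei
#' merge into a single component -- the documented failure mode of
#' mask-based counting in confluent fields.
#'
#' @param nucleus_mask logical matrix.
#' @param min_object_px drop components smaller than this.
#' @return integer count.
#' @export
count_cells <- function(nucleus_mask, min_object_px = 9) {
  stopifnot(is.logical(nucleus_mask))
  m <- drop_small_objects(nucleus_mask, min_object_px)
  if (!any(m)) return(0L)
  max(as.integer(EBImage::bwlabel(EBImage::Image(m + 0))))
}

#' Percent dry-mass discrepancy between two masks
#'
#' `|m_a - m_b| / m_b * 100`, the error metric used to compare masks
#' derived from predicted vs. actual fluorescence. The symmetric variant
#' divides by the mean of the two masses instead.
#'
#' @param phi a `phase_map` or matrix.
#' @param mask_a,mask_b logical matrices.
#' @param cfg a [dry_mass_config()].
#' @param symmetric use the symmetric denominator.
#' @return percent discrepancy (>= 0).
#' @export
mask_mass_discrepancy <- function(phi, mask_a, mask_b,
                                  cfg = dry_mass_config(),
                                  symmetric = FALSE) {
  ma <- dry_mass(phi, mask_a, cfg)
  mb <- dry_mass(phi, mask_b, cfg)
  den <- if (symmetric) (ma + mb) / 2 else mb
  if (den == 0) stop("reference mask carries zero mass")
  abs(ma - mb) / den * 100
}

#' Build one mass record for a field of view
#'
#' @param phi a `phase_map` or matrix (radians, background-zeroed).
#' @param masks a `compartment_masks`.
#' @param cfg a [dry_mass_config()].
#' @param time_h acquisition time in hours.
#' @param fov_id field-of-view identifier.
#' @return one-row data.frame with nuclear / cytoplasmic / total dry mass
#'   (pg), areas (um^2), confluence and the nuclear-cytoplasmic mass
#'   ratio (NCR).
#' @export
mass_record <- function(phi, masks, cfg = dry_mass_config(), time_h = 0,
                        fov_id = 1L) {
  stopifnot(inherits(masks, "compartment_masks"))
  px_area <- if (inherits(phi, "phase_map") && is.finite(phi$pixel_size_um)) {
    phi$pixel_size_um^2
  } else cfg$pixel_area_um2
  m_nuc <- dry_mass(phi, masks$nucleus, cfg)
  m_cyt <- dry_mass(phi, masks$cytoplasm, cfg)
  data.frame(time_h = time_h, fov_id = fov_id,
             nuclear_mass_pg = m_nuc, cyto_mass_pg = m_cyt,
             total_mass_pg = m_nuc + m_cyt,
             nuclear_area_um2 = sum(masks$nucleus) * px_area,
             cell_area_um2 = sum(masks$cell) * px_area,
             confluence = confluence(masks$cell),
             ncr = if (m_cyt > 0) m_nuc / m_cyt else NA_real_)
}

#' Normalized growth curves and doubling times
#'
#' Divides each per-FOV series by its mean over the first `baseline_h`
#' hours, computes the median curve across FOVs per timepoint, and
#' estimates a doubling time by least squares on log2(mass) over time.
#' FOVs with a non-positive baseline are excluded with a warning; a flat
#' series has an infinite doubling time (growth rate 0).
#'
#' @param records data.frame of [mass_record()] rows (any number of FOVs
#'   and timepoints).
#' @param value column to analyse (default `"total_mass_pg"`).
#' @param baseline_h baseline window length in hours (default 6).
#' @param fit_window_h optional `c(t0, t1)` restricting the log-linear
#'   doubling-time fit; default uses the full series.
#' @return list with `per_fov` (data.frame: time_h, fov_id, value,
#'   normalized), `median_curve` (data.frame: time_h, normalized), and
#'   `doubling_time_h` (per-FOV named vector; `Inf` when the fitted
#'   growth rate is not positive).
#' @export
growth_curves <- function(records, value = "total_mass_pg", baseline_h = 6,
                          fit_window_h = NULL) {
  stopifnot(is.data.frame(records), value %in% names(records),
            all(c("time_h", "fov_id") %in% names(records)))
  out <- list(); td <- c()
  for (fv in unique(records$fov_id)) {
    r <- records[records$fov_id == fv, ]
    r <- r[order(r$time_h), ]
    base <- r[[value]][r$time_h <= r$time_h[1] + baseline_h]
    if (!length(base)) {
      warning("FOV ", fv, " has no record inside the baseline window; skipped")
      next
    }
    b <- mean(base)
    if (!is.finite(b) || b <= 0) {
      warning("FOV ", fv, " has non-positive baseline mass; skipped")
      next
    }
    norm <- r[[value]] / b
    out[[length(out) + 1]] <- data.frame(time_h = r$time_h, fov_id = fv,
                                         value = r[[value]],
                                         normalized = norm)
    rf <- r
    if (!is.null(fit_window_h)) {
      rf <- r[r$time_h >= fit_window_h[1] & r$time_h <= fit_window_h[2], ]
    }
    td[as.character(fv)] <- if (nrow(rf) >= 2 && all(rf[[value]] > 0)) {
      slope <- stats::coef(stats::lm(log2(rf[[value]]) ~ rf$time_h))[2]
      if (slope > 1e-9) 1 / slope else Inf  # below: no resolvable growth
    } else NA_real_
  }
  if (!length(out)) stop("no usable FOV series")
  per_fov <- do.call(rbind, out)
  med <- stats::aggregate(normalized ~ time_h, per_fov, stats::median)
  list(per_fov = per_fov, median_curve = med, doubling_time_h = td)
}
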