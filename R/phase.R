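# Phase retrieval: four-frame phase-shifting demodulation followed by
# Fourier-domain integration of the DIC shear gradient.

#' Demodulate a four-frame GLIM acquisition into a shear-gradient map
#'
#' With modulator phases 0, pi/2, pi, 3*pi/2 the frames are
#' \eqn{I_n = A + B\cos(\Delta\phi + n\pi/2)}, so the classical four-step
#' estimator
#' \deqn{\Delta\phi = \mathrm{atan2}(I_{3\pi/2} - I_{\pi/2},\; I_0 - I_\pi)}
#' recovers the phase difference between the two sheared beams at every
#' pixel, independently of the common background \eqn{A}. Pixels with zero
#' modulation depth (all four frames equal) are undefined; they are set to
#' 0 and flagged in the validity mask.
#'
#' @param fs a `glim_frameset` (see [new_frameset()]).
#' @param depth_tol modulation-depth threshold below which a pixel is
#'   flagged invalid, as a fraction of the maximum depth in the field.
#' @return A `gradient_map`: list with `dphi` (radians, in (-pi, pi]),
#'   `shear_px`, `shear_angle_rad`, `valid` (logical matrix) and
#'   `pixel_size_um`.
#' @export
#' @examples
#' fs <- new_frameset(lapply(c(4, 2, 0, 2), function(v) matrix(v, 8, 8)))
#' g <- reconstruct_gradient(fs)
#' stopifnot(all(g$dphi == 0))
reconstruct_gradient <- function(fs, depth_tol = 1e-9) {
  stopifnot(inherits(fs, "glim_frameset"))
  num <- fs$frames[[4]] - fs$frames[[2]]  # B sin(dphi) * 2
  den <- fs$frames[[1]] - fs$frames[[3]]  # B cos(dphi) * 2
  depth <- sqrt(num^2 + den^2)
  valid <- depth > depth_tol * max(depth, .Machine$double.eps)
  dphi <- atan2(num, den)
  dphi[!valid] <- 0
  structure(list(dphi = dphi,
                 shear_px = fs$shear_px,
                 shear_angle_rad = fs$shear_angle_rad,
                 valid = valid,
                 pixel_size_um = fs$pixel_size_um),
            class = "gradient_map")
}

#' Integrate a shear-gradient map into a quantitative phase map
#'
#' The measured gradient is the finite shear difference
#' \eqn{g(x) = \phi(x) - \phi(x - s)}, whose transfer function in the
#' Fourier domain is \eqn{H(k) = 1 - e^{-i k \cdot s}}. Integration is the
#' regularised deconvolution
#' \deqn{\hat\phi = \mathcal{F}^{-1}\!\left[\frac{\bar H\,G}{|H|^2 +
#' \epsilon^2}\right],}
#' the Fourier/Hilbert-transform reading of shear-artifact removal. The DC
#' component is unobservable in shearing interferometry, so the returned
#' phase has zero spatial mean; see [rebase_phase()] for an absolute zero
#' reference.
#'
#' @param g a `gradient_map` from [reconstruct_gradient()], or a plain
#'   matrix (then `shear_px` / `shear_angle_rad` must be supplied).
#' @param epsilon Tikhonov regulariser for near-zeros of the transfer
#'   function (dimensionless, > 0). Default `1e-3`.
#' @param shear_px,shear_angle_rad shear geometry, overriding the map's.
#' @return A `phase_map`: list with `phi` (radians, zero mean) and
#'   `pixel_size_um`.
#' @export
integrate_gradient <- function(g, epsilon = 1e-3,
                               shear_px = NULL, shear_angle_rad = NULL) {
  if (is.matrix(g)) {
    g <- structure(list(dphi = g, shear_px = shear_px,
                        shear_angle_rad = shear_angle_rad,
                        pixel_size_um = 1),
                   class = "gradient_map")
  }
  stopifnot(inherits(g, "gradient_map"))
  shear_px <- shear_px %||% g$shear_px
  shear_angle_rad <- shear_angle_rad %||% g$shear_angle_rad
  stopifnot(is_scalar_num(shear_px), shear_px > 0,
            is_scalar_num(shear_angle_rad))
  if (!is_scalar_num(epsilon) || epsilon <= 0) {
    stop("epsilon must be a positive scalar (the DC pole needs regularization)")
  }
  h <- nrow(g$dphi); w <- ncol(g$dphi)
  dx <- shear_px * cos(shear_angle_rad)
  dy <- shear_px * sin(shear_angle_rad)
  ks <- outer(fft_freq(h) * dy, fft_freq(w) * dx, `+`)
  H <- 1 - exp(-1i * ks)
  G <- stats::fft(g$dphi)
  phi_hat <- Conj(H) * G / (Mod(H)^2 + epsilon^2)
  phi_hat[1, 1] <- 0
  phi <- Re(stats::fft(phi_hat, inverse = TRUE)) / (h * w)
  phi <- phi - mean(phi)
  structure(list(phi = phi, pixel_size_um = g$pixel_size_um %||% 1),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("<phase_map> ", nrow(x$phi), "x", ncol(x$phi), " px, range [",
      round(min(x$phi), 3), ", ", round(max(x$phi), 3), "] rad\n", sep = "")
  invisible(x)
}

#' Re-zero a phase map on the empty substrate
#'
#' The integrated phase is zero-mean by convention because the additive
#' constant is unobservable. Dry-mass work needs phase measured relative
#' to the cell-free background; at sub-confluent coverage the per-field
#' median is a robust estimate of that background level, so it is
#' subtracted here.
#'
#' @param phi a `phase_map` or matrix.
#' @param stat background statistic: `"median"` (default) or `"mean"`.
#' @return same type as the input, background-subtracted.
#' @export
rebase_phase <- function(phi, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  if (inherits(phi, "phase_map")) {
    phi$phi <- phi$phi - f(phi$phi)
    phi
  } else {
    phi - f(phi)
  }
}

#' Log-scale scattering display of a phase map
#'
#' For turbid, strongly scattering structures the dynamic range of the
#' phase map is too large for linear display, so the absolute value of the
#' phase is shown on a log scale: `log(|phi| + floor)`. Monotone in |phi|
#' and invariant to the sign of the phase.
#'
#' @param phi a `phase_map` or matrix (radians).
#' @param floor positive additive floor inside the logarithm; `floor = 1`
#'   makes zero phase map exactly to zero output.
#' @return matrix of display values.
#' @export
scattering_display <- function(phi, floor = 1) {
  stopifnot(is_scalar_num(floor), floor > 0)
  m <- if (inherits(phi, "phase_map")) phi$phi else phi
  log(abs(m) + floor)
}
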