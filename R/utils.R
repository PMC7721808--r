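# Internal helpers shared across modules.

#' @noRd
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Angular spatial frequencies (rad / pixel) for an n-point DFT, in fft order.
#' @noRd
fft_freq <- function(n) {
  k <- c(seq.int(0L, floor(n / 2)), seq.int(-ceiling(n / 2) + 1L, -1L))
  2 * pi * k / n
}

# Subpixel-exact circular shift of a real image by (dy, dx) pixels,
# implemented as a linear phase ramp in the Fourier domain.
#' @noRd
fourier_shift <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  ky <- fft_freq(h); kx <- fft_freq(w)
  ramp <- exp(-1i * outer(ky * dy, kx * dx, `+`))
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / (h * w)
}

# Exact shear-difference operator: phi(x) - phi(x - s) for shear vector
# s = shear_px * (cos a, sin a), periodic boundary. The measured GLIM
# gradient is this finite difference, not the infinitesimal gradient.
#' @noRd
shear_difference <- function(phi, shear_px, shear_angle_rad) {
  dx <- shear_px * cos(shear_angle_rad)
  dy <- shear_px * sin(shear_angle_rad)
  phi - fourier_shift(phi, dy, dx)
}

#' @noRd
mirror_pad <- function(img, pad_top, pad_bottom = pad_top,
                       pad_left = pad_top, pad_right = pad_left) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(pad_top < h, pad_bottom < h, pad_left < w, pad_right < w)
  ri <- c(rev(seq_len(pad_top) + 1L), seq_len(h), h - seq_len(pad_bottom))
  ci <- c(rev(seq_len(pad_left) + 1L), seq_len(w), w - seq_len(pad_right))
  img[ri, ci, drop = FALSE]
}

#' @noRd
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  # EBImage::gblur needs a filter radius well inside the image
  r <- min(floor((min(dim(img)) - 1) / 2), max(3, ceiling(3 * sigma)))
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma,
                                           radius = 2 * r + 1))
  matrix(out, nrow(img), ncol(img))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
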