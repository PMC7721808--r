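# Preprocessing for learning: intensity normalization, focus scoring and
# best-focus surface interpolation across mosaic tiles.

#' Global normalization range of a training set
#'
#' Scans all pixels of all supplied images and records the global minimum
#' and maximum. Ranges are computed per modality (phase and each
#' fluorophore separately), since their physical units differ.
#'
#' @param training_images list of numeric matrices (one modality).
#' @return object of class `normalization_range` with fields `rho_min`,
#'   `rho_max`.
#' @export
compute_range <- function(training_images) {
  if (is.matrix(training_images)) training_images <- list(training_images)
  stopifnot(is.list(training_images), length(training_images) >= 1)
  rng <- range(vapply(training_images, function(im) {
    stopifnot(is.numeric(im), all(is.finite(im)))
    range(im)
  }, numeric(2)))
  if (rng[2] <= rng[1]) {
    stop("degenerate normalization range: all pixels share one value")
  }
  structure(list(rho_min = rng[1], rho_max = rng[2]),
            class = "normalization_range")
}

#' Normalize an image into [0, 1]
#'
#' Affine rescaling by the global training-set range followed by a clamp:
#' \deqn{I' = \mathrm{med}\left(0, \frac{I - \rho_{\min}}{\rho_{\max} -
#' \rho_{\min}}, 1\right),}
#' where the pixel-wise median of \{0, v, 1\} is exactly the clamp of v to
#' [0, 1]. Values at `rho_min` map to 0, at `rho_max` to 1; out-of-range
#' values saturate. Idempotent once the range is the unit interval.
#'
#' @param I numeric matrix.
#' @param r a `normalization_range`, or any list with `rho_min`, `rho_max`.
#' @return matrix with values in [0, 1].
#' @export
normalize_image <- function(I, r) {
  stopifnot(is.numeric(I), is.numeric(r$rho_min), is.numeric(r$rho_max))
  if (!(r$rho_max > r$rho_min)) stop("rho_max must exceed rho_min")
  clamp01((I - r$rho_min) / (r$rho_max - r$rho_min))
}

#' Haar-wavelet focus score
#'
#' One level of the 2D Haar transform splits the image into approximation
#' and horizontal / vertical / diagonal detail bands. In-focus images
#' carry more energy in the detail bands, so the score is the total
#' first-level detail energy divided by the AC energy of the image
#' (sum of squared deviations from the mean). The score is 0 for constant
#' images and invariant to adding a constant.
#'
#' @param I numeric matrix, at least 2 x 2. Odd trailing row/column are
#'   ignored by the dyadic transform.
#' @return scalar focus score in [0, 1].
#' @export
focus_score <- function(I) {
  stopifnot(is.matrix(I), nrow(I) >= 2, ncol(I) >= 2)
  h <- 2L * (nrow(I) %/% 2L); w <- 2L * (ncol(I) %/% 2L)
  I <- I[seq_len(h), seq_len(w), drop = FALSE]
  a <- I[seq(1, h, 2), seq(1, w, 2)]
  b <- I[seq(1, h, 2), seq(2, w, 2)]
  c <- I[seq(2, h, 2), seq(1, w, 2)]
  d <- I[seq(2, h, 2), seq(2, w, 2)]
  hh <- (a - b + c - d) / 2   # horizontal detail
  vv <- (a + b - c - d) / 2   # vertical detail
  dd <- (a - b - c + d) / 2   # diagonal detail
  detail <- sum(hh^2) + sum(vv^2) + sum(dd^2)
  ac <- sum((I - mean(I))^2)
  if (ac == 0) return(0)
  detail / ac
}

#' Select the most in-focus slices of a z-stack
#'
#' Scores every slice with `scorer` (the Haar criterion by default) and
#' returns the indices of the `k` highest scores. Ties are broken in
#' favour of slices nearer the stack centre, where the best focus is
#' expected a priori.
#'
#' @param stack list with `images` (list of matrices) and optionally
#'   `z_positions_um` (strictly monotone), or a plain list of matrices.
#' @param k number of slices to keep (default 3, the standard training
#'   augmentation depth).
#' @param scorer function(matrix) -> scalar; higher = sharper.
#' @return integer indices into the stack, ordered best first.
#' @export
select_in_focus <- function(stack, k = 3, scorer = focus_score) {
  images <- if (!is.null(stack$images)) stack$images else stack
  if (!is.null(stack$z_positions_um)) {
    z <- stack$z_positions_um
    stopifnot(length(z) == length(images), all(diff(z) > 0) || all(diff(z) < 0))
  }
  stopifnot(length(images) >= k, k >= 1)
  scores <- vapply(images, scorer, numeric(1))
  centre_dist <- abs(seq_along(images) - (length(images) + 1) / 2)
  ord <- order(-scores, centre_dist, seq_along(images))
  ord[seq_len(k)]
}

# ---- Delaunay triangulation (Bowyer-Watson) --------------------------------
# Desk-scale implementation for the handful of focus points of a multiwell
# mosaic; no installed package provides one.

#' @noRd
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(x = ux, y = uy, r2 = (ux - ax)^2 + (uy - ay)^2)
}

# Bowyer-Watson incremental Delaunay triangulation of points (x, y).
# Returns integer matrix of triangle vertex indices (rows).
#' @noRd
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  # reject collinear input
  A <- cbind(x - mean(x), y - mean(y))
  if (qr(A)$rank < 2) stop("focus points are collinear; cannot triangulate")
  # super-triangle enclosing everything
  cx <- mean(range(x)); cy <- mean(range(y))
  dmax <- max(diff(range(x)), diff(range(y)), 1e-9)
  px <- c(cx - 20 * dmax, cx + 20 * dmax, cx)
  py <- c(cy - 10 * dmax, cy - 10 * dmax, cy + 20 * dmax)
  X <- c(x, px[1:3]); Y <- c(y, py[1:3])
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- list(c(s1, s2, s3))
  for (i in seq_len(n)) {
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      v <- tris[[t]]
      cc <- circumcircle(c(X[v[1]], Y[v[1]]), c(X[v[2]], Y[v[2]]),
                         c(X[v[3]], Y[v[3]]))
      if (is.null(cc)) { bad[t] <- TRUE; next }
      bad[t] <- (X[i] - cc$x)^2 + (Y[i] - cc$y)^2 <= cc$r2 * (1 + 1e-12)
    }
    # boundary of the cavity = edges of bad triangles not shared twice
    edges <- list()
    for (t in which(bad)) {
      v <- tris[[t]]
      edges <- c(edges, list(sort(v[1:2]), sort(v[2:3]), sort(v[c(1, 3)])))
    }
    if (length(edges)) {
      key <- vapply(edges, paste, character(1), collapse = "-")
      keep <- names(which(table(key) == 1))
      boundary <- edges[match(keep, key)]
      tris <- tris[!bad]
      for (e in boundary) tris <- c(tris, list(c(e, i)))
    }
  }
  tris <- Filter(function(v) all(v <= n), tris)
  if (!length(tris)) stop("triangulation failed")
  do.call(rbind, tris)
}

#' @noRd
barycentric <- function(tri_xy, p) {
  # tri_xy: 3x2 matrix; returns weights w (length 3) with sum 1
  T <- cbind(tri_xy[1, ] - tri_xy[3, ], tri_xy[2, ] - tri_xy[3, ])
  det <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  if (abs(det) < 1e-14) return(NULL)
  l1 <- ((tri_xy[2, 2] - tri_xy[3, 2]) * (p[1] - tri_xy[3, 1]) +
           (tri_xy[3, 1] - tri_xy[2, 1]) * (p[2] - tri_xy[3, 2])) / det
  l2 <- ((tri_xy[3, 2] - tri_xy[1, 2]) * (p[1] - tri_xy[3, 1]) +
           (tri_xy[1, 1] - tri_xy[3, 1]) * (p[2] - tri_xy[3, 2])) / det
  c(l1, l2, 1 - l1 - l2)
}

#' Interpolate the best-focus surface across mosaic tiles
#'
#' Builds a Delaunay triangulation of the user-supplied focus points and
#' evaluates the piecewise-linear (barycentric) interpolant at each tile
#' position. The interpolant is exact at the focus points and reproduces
#' any affine surface z = a + bx + cy exactly. Tiles outside the convex
#' hull are extrapolated with the plane of the nearest triangle and
#' flagged, since mosaic corners routinely fall outside the focus points.
#'
#' @param focus_points data.frame or matrix with columns x, y, z
#'   (>= 3 non-collinear points).
#' @param tiles data.frame or matrix with columns x, y.
#' @return data.frame with columns `x`, `y`, `z`, `extrapolated`.
#' @export
interpolate_focus_surface <- function(focus_points, tiles) {
  fp <- as.matrix(focus_points)[, 1:3, drop = FALSE]
  qt <- as.matrix(tiles)[, 1:2, drop = FALSE]
  stopifnot(nrow(fp) >= 3)
  tri <- delaunay_triangulate(fp[, 1], fp[, 2])
  z <- numeric(nrow(qt)); extra <- logical(nrow(qt))
  for (q in seq_len(nrow(qt))) {
    p <- qt[q, ]
    best_w <- NULL; best_t <- NA_integer_; best_pen <- Inf
    for (t in seq_len(nrow(tri))) {
      w <- barycentric(fp[tri[t, ], 1:2, drop = FALSE], p)
      if (is.null(w)) next
      pen <- max(0, -min(w))  # 0 inside the triangle
      if (pen < best_pen) { best_pen <- pen; best_w <- w; best_t <- t }
      if (pen == 0) break
    }
    if (is.null(best_w)) stop("no valid triangle for query point")
    z[q] <- sum(best_w * fp[tri[best_t, ], 3])
    extra[q] <- best_pen > 1e-9
  }
  if (any(extra)) {
    warning(sum(extra), " tile(s) outside the focus-point hull; ",
            "extrapolated from the nearest simplex")
  }
  data.frame(x = qt[, 1], y = qt[, 2], z = z, extrapolated = extra)
}
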