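# Layer primitives for the U-Net, with hand-derived backpropagation.
#
# Feature maps are stored as (N*H*W) x C matrices: rows run column-major
# within each image, images stacked along rows. All spatial wiring
# (3x3 neighbourhoods, 2x2 pooling quadrants) is precomputed per image
# geometry as integer index vectors, so every layer reduces to BLAS
# matrix products plus vectorised gathers/scatters.

.grid_cache <- new.env(parent = emptyenv())

# Index vector mapping each output pixel to its input pixel under a
# (di, dj) shift; out-of-bounds neighbours point at a sentinel zero row.
#' @noRd
shift_index <- function(H, W, di, dj) {
  M <- matrix(seq_len(H * W), H, W)
  out <- matrix(H * W + 1L, H, W)
  ri <- seq_len(H); rj <- seq_len(W)
  vi <- ri + di >= 1L & ri + di <= H
  vj <- rj + dj >= 1L & rj + dj <= W
  out[ri[vi], rj[vj]] <- M[ri[vi] + di, rj[vj] + dj]
  as.integer(out)
}

#' @noRd
expand_batch_index <- function(idx, hw, n, sentinel_in, sentinel_out) {
  rep_idx <- rep.int(idx, n) + rep(seq.int(0L, n - 1L) * hw, each = length(idx))
  rep_idx[rep.int(idx, n) == sentinel_in] <- sentinel_out
  rep_idx
}

# Geometry bundle for one (H, W, N): 3x3 shift indices and the four
# quadrant index sets linking this grid to the next-coarser one.
#' @noRd
grid_for <- function(H, W, N) {
  key <- paste(H, W, N, sep = "x")
  g <- .grid_cache[[key]]
  if (!is.null(g)) return(g)
  hw <- H * W; P <- hw * N
  offs <- expand.grid(di = -1:1, dj = -1:1)
  idx9 <- lapply(seq_len(9), function(o) {
    expand_batch_index(shift_index(H, W, offs$di[o], offs$dj[o]),
                       hw, N, hw + 1L, P + 1L)
  })
  quad <- NULL
  if (H %% 2L == 0L && W %% 2L == 0L) {
    Fm <- matrix(seq_len(hw), H, W)
    quad <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                   function(ab) {
                     q <- as.integer(Fm[seq(1L + ab[1], H, 2L),
                                        seq(1L + ab[2], W, 2L)])
                     expand_batch_index(q, hw, N, hw + 1L, P + 1L)
                   })
  }
  g <- list(H = H, W = W, N = N, P = P, idx9 = idx9, quad = quad)
  .grid_cache[[key]] <- g
  g
}

# ---- 3x3 convolution (same padding) ---------------------------------------

#' @noRd
conv_forward <- function(X, W, b, grid) {
  cin <- ncol(X); cout <- length(b)
  Xz <- rbind(X, 0)
  Y <- matrix(rep(b, each = grid$P), grid$P, cout)
  for (o in seq_len(9)) {
    rows <- (o - 1L) * cin + seq_len(cin)
    Y <- Y + Xz[grid$idx9[[o]], , drop = FALSE] %*% W[rows, , drop = FALSE]
  }
  Y
}

#' @noRd
conv_backward <- function(dY, X, W, grid) {
  cin <- ncol(X)
  Xz <- rbind(X, 0)
  dW <- W * 0; db <- colSums(dY)
  dX <- matrix(0, grid$P, cin)
  for (o in seq_len(9)) {
    rows <- (o - 1L) * cin + seq_len(cin)
    idx <- grid$idx9[[o]]
    dW[rows, ] <- crossprod(Xz[idx, , drop = FALSE], dY)
    dXs <- dY %*% t(W[rows, , drop = FALSE])
    sel <- idx <= grid$P
    tgt <- idx[sel]
    dX[tgt, ] <- dX[tgt, , drop = FALSE] + dXs[sel, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# ---- batch normalization --------------------------------------------------
# Statistics are taken over every pixel of the mini-batch, per channel.

#' @noRd
bn_forward <- function(X, bn, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, invstd, "*")
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * v
  } else {
    invstd <- 1 / sqrt(bn$rvar + eps)
    xhat <- sweep(sweep(X, 2, bn$rmean), 2, invstd, "*")
  }
  Y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(Y = Y, bn = bn, cache = list(xhat = xhat, invstd = invstd))
}

#' @noRd
bn_backward <- function(dY, bn, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, bn$gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*"),
              2, cache$invstd, "*")
  list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

# ---- conv -> [bn] -> relu block -------------------------------------------

#' @noRd
block_forward <- function(X, layer, grid, train) {
  Y <- conv_forward(X, layer$W, layer$b, grid)
  cache <- list(X = X)
  if (!is.null(layer$bn)) {
    r <- bn_forward(Y, layer$bn, train)
    Y <- r$Y; layer$bn <- r$bn; cache$bn <- r$cache
  }
  cache$mask <- Y > 0
  list(Y = Y * cache$mask, layer = layer, cache = cache)
}

#' @noRd
block_backward <- function(dOut, layer, cache, grid) {
  dY <- dOut * cache$mask
  g <- list()
  if (!is.null(layer$bn)) {
    r <- bn_backward(dY, layer$bn, cache$bn)
    g$bn <- list(gamma = r$dgamma, beta = r$dbeta)
    dY <- r$dX
  }
  cv <- conv_backward(dY, cache$X, layer$W, grid)
  g$W <- cv$dW; g$b <- cv$db
  list(grad = g, dX = cv$dX)
}

# ---- 2x2 max pooling -------------------------------------------------------

#' @noRd
pool_forward <- function(X, grid_fine) {
  q <- grid_fine$quad
  Y <- X[q[[1]], , drop = FALSE]
  amax <- matrix(1L, nrow(Y), ncol(Y))
  for (k in 2:4) {
    Xk <- X[q[[k]], , drop = FALSE]
    upd <- Xk > Y
    Y[upd] <- Xk[upd]
    amax[upd] <- k
  }
  list(Y = Y, amax = amax)
}

#' @noRd
pool_backward <- function(dY, amax, grid_fine) {
  dX <- matrix(0, grid_fine$P, ncol(dY))
  for (k in 1:4) {
    contrib <- dY * (amax == k)
    tgt <- grid_fine$quad[[k]]
    dX[tgt, ] <- dX[tgt, , drop = FALSE] + contrib
  }
  dX
}

# ---- 2x2 up-convolution (transposed conv, stride 2) ------------------------

#' @noRd
upconv_forward <- function(X, up, grid_fine) {
  cin <- ncol(X); cout <- length(up$b)
  Y <- matrix(rep(up$b, each = grid_fine$P), grid_fine$P, cout)
  for (k in 1:4) {
    rows <- (k - 1L) * cin + seq_len(cin)
    Y[grid_fine$quad[[k]], ] <- Y[grid_fine$quad[[k]], , drop = FALSE] +
      X %*% up$W[rows, , drop = FALSE]
  }
  Y
}

#' @noRd
upconv_backward <- function(dY, X, up, grid_fine) {
  cin <- ncol(X)
  dW <- up$W * 0
  db <- colSums(dY)
  dX <- matrix(0, nrow(X), cin)
  for (k in 1:4) {
    rows <- (k - 1L) * cin + seq_len(cin)
    dYk <- dY[grid_fine$quad[[k]], , drop = FALSE]
    dW[rows, ] <- crossprod(X, dYk)
    dX <- dX + dYk %*% t(up$W[rows, , drop = FALSE])
  }
  list(dW = dW, db = db, dX = dX)
}
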