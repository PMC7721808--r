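# Full-network forward/backward passes, the ADAM optimiser, training and
# padded inference.

# Grids per resolution level for an (H, W, N) input.
#' @noRd
unet_grids <- function(spec, H, W, N) {
  div <- 2L^(spec$depth - 1L)
  if (H %% div != 0L || W %% div != 0L) {
    stop("input of ", H, "x", W, " is not divisible by 2^(depth-1) = ", div)
  }
  if (min(H, W) / div < 1) stop("input too small for network depth")
  lapply(seq_len(spec$depth), function(d) {
    grid_for(H %/% 2L^(d - 1L), W %/% 2L^(d - 1L), N)
  })
}

# Forward pass. X is (N*H*W) x in_channels. Returns the prediction, the
# (possibly updated, via batch-norm running stats) parameters, and the
# caches needed for backprop.
#' @noRd
unet_forward <- function(par, spec, X, grids, train = FALSE) {
  fwd <- function(d, Xd) {
    lv <- par$enc[[d]]
    b1 <- block_forward(Xd, lv$c1, grids[[d]], train)
    b2 <- block_forward(b1$Y, lv$c2, grids[[d]], train)
    par$enc[[d]]$c1 <<- b1$layer; par$enc[[d]]$c2 <<- b2$layer
    cache <- list(e1 = b1$cache, e2 = b2$cache)
    if (d == spec$depth) return(list(Y = b2$Y, cache = cache))
    pl <- pool_forward(b2$Y, grids[[d]])
    cache$amax <- pl$amax
    inner <- fwd(d + 1L, pl$Y)
    cache$inner <- inner$cache
    dv <- par$dec[[d]]
    up <- upconv_forward(inner$Y, dv$up, grids[[d]])
    cache$up_in <- inner$Y
    cat_ <- cbind(up, b2$Y)
    d1 <- block_forward(cat_, dv$c1, grids[[d]], train)
    d2 <- block_forward(d1$Y, dv$c2, grids[[d]], train)
    par$dec[[d]]$c1 <<- d1$layer; par$dec[[d]]$c2 <<- d2$layer
    cache$d1 <- d1$cache; cache$d2 <- d2$cache
    list(Y = d2$Y, cache = cache)
  }
  top <- fwd(1L, X)
  out <- top$Y %*% par$final$W
  out <- sweep(out, 2, par$final$b, "+")
  if (spec$residual) out <- out + X
  list(Y = out, par = par, cache = list(feats = top$Y, levels = top$cache))
}

# Backward pass; returns the gradient tree (same shape as the trainable
# parameters).
#' @noRd
unet_backward <- function(par, spec, X, cache, dOut, grids) {
  grad <- list(enc = vector("list", spec$depth),
               dec = vector("list", max(spec$depth - 1L, 0L)),
               final = list(W = crossprod(cache$feats, dOut),
                            b = colSums(dOut)))
  dFeats <- dOut %*% t(par$final$W)
  bwd <- function(d, dY, cc) {
    if (d < spec$depth) {
      dv <- par$dec[[d]]
      r2 <- block_backward(dY, dv$c2, cc$d2, grids[[d]])
      r1 <- block_backward(r2$dX, dv$c1, cc$d1, grids[[d]])
      w <- ncol(r2$dX)  # decoder width at this level
      dup <- r1$dX[, seq_len(w), drop = FALSE]
      dskip <- r1$dX[, w + seq_len(ncol(r1$dX) - w), drop = FALSE]
      uv <- upconv_backward(dup, cc$up_in, dv$up, grids[[d]])
      dInner <- bwd(d + 1L, uv$dX, cc$inner)
      dPooled <- pool_backward(dInner, cc$amax, grids[[d]])
      dH <- dskip + dPooled
      grad$dec[[d]] <<- list(up = list(W = uv$dW, b = uv$db),
                             c1 = r1$grad, c2 = r2$grad)
    } else {
      dH <- dY
    }
    lv <- par$enc[[d]]
    e2 <- block_backward(dH, lv$c2, cc$e2, grids[[d]])
    e1 <- block_backward(e2$dX, lv$c1, cc$e1, grids[[d]])
    grad$enc[[d]] <<- list(c1 = e1$grad, c2 = e2$grad)
    e1$dX
  }
  bwd(1L, dFeats, cache$levels)
  grad
}

# ---- generic trees of numeric leaves --------------------------------------

#' @noRd
tree_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  keys <- if (is.null(names(b))) seq_along(b) else names(b)
  for (nm in keys) {
    if (!is.null(b[[nm]])) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
  }
  out
}

#' @noRd
tree_zero_like <- function(g) {
  if (is.numeric(g)) return(g * 0)
  lapply(g, tree_zero_like)
}

# One ADAM step over the trainable leaves present in `grad`.
#' @noRd
adam_step <- function(par, grad, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  if (is.null(state$m)) {
    state$m <- tree_zero_like(grad)
    state$v <- tree_zero_like(grad)
  }
  state$m <- tree_map2(state$m, grad, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grad, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  par <- tree_map2(par, upd, function(p, u) p - u)
  list(par = par, state = state)
}

#' Training configuration
#'
#' The optimiser is ADAM against a mean-squared-error criterion. The seed
#' fixes weight initialisation (via [build_model()]) and shuffling, making
#' training reproducible.
#'
#' @param lr learning rate.
#' @param beta1,beta2 ADAM moment decay rates.
#' @param epochs number of passes over the training pairs.
#' @param batch_size images per gradient step.
#' @param val_fraction fraction of pairs held out for validation (0 for
#'   none); the checkpoint with the best validation loss is returned.
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, epochs = 20,
                         batch_size = 4, val_fraction = 0, seed = 1L,
                         verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' @noRd
stack_pairs <- function(pairs, which) {
  matrix(unlist(lapply(pairs, function(p) as.vector(p[[which]])),
                use.names = FALSE), ncol = 1)
}

#' Train a U-Net on phase / fluorescence image pairs
#'
#' Minimises the mean squared error between predicted and true
#' fluorescence with ADAM. Inputs are expected normalized to [0, 1]
#' (see [normalize_image()]); each pair is a list with elements `x`
#' (phase) and `y` (fluorescence target), all of one size.
#'
#' @param model a `unet_model` from [build_model()].
#' @param pairs non-empty list of `list(x =, y =)` matrices.
#' @param cfg a [train_config()].
#' @return list with `model` (best checkpoint) and `history` (data.frame
#'   of per-epoch training and validation loss).
#' @export
train <- function(model, pairs, cfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  if (!is.list(pairs) || length(pairs) == 0) {
    stop("training requires at least one (phase, fluorescence) pair")
  }
  dims <- dim(pairs[[1]]$x)
  for (p in pairs) {
    if (!all(dim(p$x) == dims) || !all(dim(p$y) == dims)) {
      stop("all phase and fluorescence images must share one shape")
    }
  }
  spec <- model$spec
  withr::with_seed(cfg$seed, {
    n <- length(pairs)
    n_val <- floor(cfg$val_fraction * n)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(tr_idx)) stop("validation split leaves no training pairs")
    par <- model$par
    state <- list(t = 0L)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best <- list(loss = Inf, par = par)
    eval_loss <- function(par, idx) {
      if (!length(idx)) return(NA_real_)
      tot <- 0
      for (i in idx) {
        g <- unet_grids(spec, dims[1], dims[2], 1L)
        fw <- unet_forward(par, spec, stack_pairs(pairs[i], "x"), g,
                           train = FALSE)
        tot <- tot + mean((fw$Y - stack_pairs(pairs[i], "y"))^2)
      }
      tot / length(idx)
    }
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0; ep_n <- 0
      for (b in batches) {
        grids <- unet_grids(spec, dims[1], dims[2], length(b))
        X <- stack_pairs(pairs[b], "x")
        Tt <- stack_pairs(pairs[b], "y")
        fw <- unet_forward(par, spec, X, grids, train = TRUE)
        par <- fw$par
        resid <- fw$Y - Tt
        ep_loss <- ep_loss + mean(resid^2) * length(b)
        ep_n <- ep_n + length(b)
        dOut <- 2 * resid / length(resid)
        grad <- unet_backward(par, spec, X, fw$cache, dOut, grids)
        st <- adam_step(par, grad, state, cfg$lr, cfg$beta1, cfg$beta2)
        par <- st$par; state <- st$state
      }
      vl <- eval_loss(par, val_idx)
      tl <- ep_loss / ep_n
      history <- rbind(history, data.frame(epoch = ep, train_loss = tl,
                                           val_loss = vl))
      score <- if (is.na(vl)) tl else vl
      if (score < best$loss) best <- list(loss = score, par = par)
      if (cfg$verbose) {
        message(sprintf("epoch %3d  train %.3e  val %s", ep, tl,
                        if (is.na(vl)) "-" else sprintf("%.3e", vl)))
      }
    }
    model$par <- best$par
    model$trained <- TRUE
    list(model = model, history = history)
  })
}

#' Run inference with mirror padding
#'
#' Mirror-pads the input by `pad_px` on every side (plus whatever extra
#' right/bottom padding makes the size divisible by the network stride),
#' runs the network, and crops back to the input geometry, suppressing
#' the edge artifacts typical of convolutional networks. Batch-norm
#' layers use their running statistics.
#'
#' @param model a `unet_model`.
#' @param phase numeric matrix, normalized to [0, 1].
#' @param pad_px mirror padding width in pixels (default 32).
#' @param clip clip the output to [0, 1] for rendering (default TRUE).
#' @return matrix of the predicted channel, same shape as `phase`.
#' @export
infer <- function(model, phase, pad_px = 32, clip = TRUE) {
  stopifnot(inherits(model, "unet_model"), is.matrix(phase), pad_px >= 0)
  spec <- model$spec
  div <- 2L^(spec$depth - 1L)
  h <- nrow(phase); w <- ncol(phase)
  pb <- pad_px + (div - (h + 2L * pad_px) %% div) %% div
  pr <- pad_px + (div - (w + 2L * pad_px) %% div) %% div
  Xp <- mirror_pad(phase, pad_px, pb, pad_px, pr)
  grids <- unet_grids(spec, nrow(Xp), ncol(Xp), 1L)
  fw <- unet_forward(model$par, spec, matrix(as.vector(Xp), ncol = 1),
                     grids, train = FALSE)
  out <- matrix(fw$Y, nrow(Xp), ncol(Xp))
  out <- out[pad_px + seq_len(h), pad_px + seq_len(w), drop = FALSE]
  if (clip) out <- clamp01(out)
  out
}

#' Pooled Pearson correlation between predicted and true channels
#'
#' The quality metric for virtual staining: the Pearson correlation
#' between the predicted and actual fluorescence signals pooled over the
#' entire evaluation set.
#'
#' @param pred_set,truth_set matrices or lists of matrices of equal
#'   shapes and counts.
#' @return scalar correlation in [-1, 1].
#' @export
pearson_quality <- function(pred_set, truth_set) {
  if (is.matrix(pred_set)) pred_set <- list(pred_set)
  if (is.matrix(truth_set)) truth_set <- list(truth_set)
  stopifnot(length(pred_set) == length(truth_set), length(pred_set) >= 1)
  for (i in seq_along(pred_set)) {
    stopifnot(all(dim(pred_set[[i]]) == dim(truth_set[[i]])))
  }
  p <- unlist(lapply(pred_set, as.vector), use.names = FALSE)
  t <- unlist(lapply(truth_set, as.vector), use.names = FALSE)
  if (stats::sd(p) == 0 || stats::sd(t) == 0) {
    stop("zero variance in pooled pixels; correlation undefined")
  }
  stats::cor(p, t)
}
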