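# A compact, dependency-free U-net for rib segmentation: encoder/decoder
# with skip connections, trained with Adam on binary cross-entropy.
# Convolutions are 3x3 (same padding) via im2col matrix products; pooling
# is 2x2 max; upsampling is nearest-neighbour followed by a convolution.
# Designed for small images and CPU training; the sequence labeler accepts
# a rib mask from any segmenter, so this arm is optional end to end.

#' U-net configuration
#'
#' @param depth number of encoder levels (poolings); default 4, the
#'   classic configuration.
#' @param base_filters filters at the first level, doubled per level;
#'   default 64.
#' @param input_size `c(rows, cols)`; both must be divisible by
#'   `2^depth`.
#' @param batch_size training batch size (default 8).
#' @param max_epochs epoch cap (default 300).
#' @param patience early-stopping patience on validation loss.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of the training pairs held out for the
#'   early-stopping validation loss.
#' @param threshold probability cut for the binary output mask.
#' @param seed integer seed for weight initialization and shuffling.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_filters = 64L,
                        input_size = c(512L, 512L), batch_size = 8L,
                        max_epochs = 300L, patience = 10L, lr = 1e-3,
                        val_fraction = 0.2, threshold = 0.5, seed = 1L) {
  depth <- as.integer(depth)
  input_size <- as.integer(input_size)
  if (any(input_size %% 2L^depth != 0L))
    stop("parameter error: input dimensions must be divisible by 2^depth", call. = FALSE)
  structure(list(depth = depth, base_filters = as.integer(base_filters),
                 input_size = input_size, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 val_fraction = val_fraction, threshold = threshold,
                 seed = as.integer(seed)),
            class = "unet_config")
}

# ---- geometry caches -------------------------------------------------------

# im2col gather indices for a 3x3 same-padded convolution on an H x W grid:
# a (H*W) x 9 matrix of source pixel indices, H*W + 1 meaning zero pad
conv_gather <- function(H, W) {
  n <- H * W
  y <- rep(seq_len(H), W)
  x <- rep(seq_len(W), each = H)
  g <- matrix(n + 1L, n, 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    yy <- y + dy; xx <- x + dx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    g[ok, k] <- yy[ok] + (xx[ok] - 1L) * H
  }
  g
}

# 2x2 max-pool candidate indices: (H/2 * W/2) x 4
pool_gather <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yo <- rep(seq_len(Ho), Wo)
  xo <- rep(seq_len(Wo), each = Ho)
  cbind((2L * yo - 1L) + (2L * xo - 2L) * H,
        (2L * yo) + (2L * xo - 2L) * H,
        (2L * yo - 1L) + (2L * xo - 1L) * H,
        (2L * yo) + (2L * xo - 1L) * H)
}

# nearest-neighbour 2x upsampling source index for each output pixel
up_gather <- function(Ho, Wo) {
  H <- 2L * Ho
  y <- rep(seq_len(H), 2L * Wo)
  x <- rep(seq_len(2L * Wo), each = H)
  ((y + 1L) %/% 2L) + (((x + 1L) %/% 2L) - 1L) * Ho
}

# ---- layers ----------------------------------------------------------------

conv_fwd <- function(feat, lay, g) {
  fz <- rbind(feat, 0)
  xcol <- do.call(cbind, lapply(seq_len(9L), function(k) fz[g[, k], , drop = FALSE]))
  list(out = sweep(xcol %*% lay$W, 2L, lay$b, `+`), xcol = xcol)
}

conv_bwd <- function(dout, lay, xcol, g, n_in, c_in) {
  dW <- crossprod(xcol, dout)
  db <- colSums(dout)
  dxcol <- dout %*% t(lay$W)
  dfeat <- matrix(0, n_in, c_in)
  for (k in seq_len(9L)) {
    idx <- g[, k]
    ok <- idx <= n_in
    blk <- dxcol[, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
    dfeat[idx[ok], ] <- dfeat[idx[ok], , drop = FALSE] + blk[ok, , drop = FALSE]
  }
  list(dfeat = dfeat, dW = dW, db = db)
}

pool_fwd <- function(feat, pg) {
  c1 <- feat[pg[, 1], , drop = FALSE]; c2 <- feat[pg[, 2], , drop = FALSE]
  c3 <- feat[pg[, 3], , drop = FALSE]; c4 <- feat[pg[, 4], , drop = FALSE]
  m <- pmax(c1, c2, c3, c4)
  arg <- 1L * (c1 == m)
  arg[c2 == m & arg == 0L] <- 2L
  arg[c3 == m & arg == 0L] <- 3L
  arg[c4 == m & arg == 0L] <- 4L
  list(out = m, arg = arg)
}

pool_bwd <- function(dout, arg, pg, n_in) {
  dfeat <- matrix(0, n_in, ncol(dout))
  for (k in 1:4) {
    sel <- arg == k
    contrib <- dout * sel
    dfeat[pg[, k], ] <- dfeat[pg[, k], , drop = FALSE] + contrib
  }
  dfeat
}

#' Build an untrained U-net model
#'
#' Allocates He-initialized weights for the encoder-decoder described by
#' the configuration and precomputes the per-level index caches.
#'
#' @param cfg a [unet_config()].
#' @return An object of class `unet_model` (environment holding weights,
#'   Adam state and geometry caches).
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  d <- cfg$depth
  filters <- cfg$base_filters * 2L^(0:d)   # levels 1..d, then bottleneck
  env <- new.env(parent = emptyenv())
  env$cfg <- cfg
  env$filters <- filters
  env$geom <- list()
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  for (l in seq_len(d + 1L)) {
    env$geom[[l]] <- list(H = H, W = W, g = conv_gather(H, W),
                          pg = if (l <= d) pool_gather(H, W),
                          ug = if (l <= d) up_gather(H %/% 2L, W %/% 2L))
    H <- H %/% 2L; W <- W %/% 2L
  }
  env$weights <- with_local_seed(cfg$seed, {
    w <- list()
    he <- function(c_in, c_out, k = 9L)
      list(W = matrix(stats::rnorm(k * c_in * c_out, 0, sqrt(2 / (k * c_in))),
                      k * c_in, c_out),
           b = rep(0, c_out))
    c_prev <- 1L
    for (l in seq_len(d + 1L)) {             # encoder levels + bottleneck
      w[[paste0("enc", l, "a")]] <- he(c_prev, filters[l])
      w[[paste0("enc", l, "b")]] <- he(filters[l], filters[l])
      c_prev <- filters[l]
    }
    for (l in rev(seq_len(d))) {             # decoder levels
      w[[paste0("up", l)]] <- he(filters[l + 1L], filters[l])
      w[[paste0("dec", l, "a")]] <- he(2L * filters[l], filters[l])
      w[[paste0("dec", l, "b")]] <- he(filters[l], filters[l])
    }
    w[["out"]] <- list(W = matrix(stats::rnorm(filters[1], 0, sqrt(2 / filters[1])),
                                  filters[1], 1L),
                       b = 0)
    w
  })
  env$adam <- list(t = 0L, m = rapply(env$weights, function(x) x * 0, how = "replace"),
                   v = rapply(env$weights, function(x) x * 0, how = "replace"))
  class(env) <- "unet_model"
  env
}

# forward pass for one image (vector of H*W intensities in [0, 1]);
# returns logits and, if train = TRUE, the caches needed for backprop
unet_forward <- function(model, img, train = FALSE) {
  w <- model$weights; d <- model$cfg$depth
  cache <- list()
  feat <- matrix(img, ncol = 1L)
  skips <- list()
  for (l in seq_len(d + 1L)) {
    g <- model$geom[[l]]$g
    a <- conv_fwd(feat, w[[paste0("enc", l, "a")]], g)
    ra <- pmax(a$out, 0)
    b <- conv_fwd(ra, w[[paste0("enc", l, "b")]], g)
    rb <- pmax(b$out, 0)
    if (train) cache[[paste0("enc", l)]] <- list(in_feat = feat, a = a, ra = ra, b = b, rb = rb)
    if (l <= d) {
      skips[[l]] <- rb
      pf <- pool_fwd(rb, model$geom[[l]]$pg)
      if (train) cache[[paste0("pool", l)]] <- pf$arg
      feat <- pf$out
    } else feat <- rb
  }
  for (l in rev(seq_len(d))) {
    gl <- model$geom[[l]]
    upin <- feat[gl$ug, , drop = FALSE]
    u <- conv_fwd(upin, w[[paste0("up", l)]], gl$g)
    ru <- pmax(u$out, 0)
    cat_feat <- cbind(skips[[l]], ru)
    a <- conv_fwd(cat_feat, w[[paste0("dec", l, "a")]], gl$g)
    ra <- pmax(a$out, 0)
    b <- conv_fwd(ra, w[[paste0("dec", l, "b")]], gl$g)
    rb <- pmax(b$out, 0)
    if (train) cache[[paste0("dec", l)]] <- list(upin = upin, u = u, ru = ru,
                                                 cat_feat = cat_feat, a = a, ra = ra,
                                                 b = b, rb = rb)
    feat <- rb
  }
  logits <- sweep(feat %*% w$out$W, 2L, w$out$b, `+`)
  if (train) cache$final_feat <- feat
  list(logits = logits, cache = cache)
}

unet_backward <- function(model, fw, dlogits) {
  w <- model$weights; d <- model$cfg$depth; cache <- fw$cache
  grads <- list()
  grads$out <- list(W = crossprod(cache$final_feat, dlogits),
                    b = sum(dlogits))
  dfeat <- dlogits %*% t(w$out$W)
  dskips <- list()
  for (l in seq_len(d)) {
    gl <- model$geom[[l]]
    cc <- cache[[paste0("dec", l)]]
    n <- gl$H * gl$W
    fl <- model$filters[l]
    drb <- dfeat * (cc$b$out > 0)
    bb <- conv_bwd(drb, w[[paste0("dec", l, "b")]], cc$b$xcol, gl$g, n, fl)
    grads[[paste0("dec", l, "b")]] <- list(W = bb$dW, b = bb$db)
    dra <- bb$dfeat * (cc$a$out > 0)
    ba <- conv_bwd(dra, w[[paste0("dec", l, "a")]], cc$a$xcol, gl$g, n, 2L * fl)
    grads[[paste0("dec", l, "a")]] <- list(W = ba$dW, b = ba$db)
    dskips[[l]] <- ba$dfeat[, seq_len(fl), drop = FALSE]
    dru <- ba$dfeat[, fl + seq_len(fl), drop = FALSE] * (cc$u$out > 0)
    bu <- conv_bwd(dru, w[[paste0("up", l)]], cc$u$xcol, gl$g, n, model$filters[l + 1L])
    grads[[paste0("up", l)]] <- list(W = bu$dW, b = bu$db)
    # upsample backward: sum the 2x2 block gradients onto each source pixel
    src <- gl$ug
    dlow <- rowsum(bu$dfeat, src)
    dfeat <- dlow[order(as.integer(rownames(dlow))), , drop = FALSE]
    dimnames(dfeat) <- NULL
  }
  for (l in rev(seq_len(d + 1L))) {
    gl <- model$geom[[l]]
    cc <- cache[[paste0("enc", l)]]
    n <- gl$H * gl$W
    if (l <= d) {
      dpool <- pool_bwd(dfeat, cache[[paste0("pool", l)]], gl$pg, n)
      dfeat <- dpool + dskips[[l]]
    }
    drb <- dfeat * (cc$b$out > 0)
    bb <- conv_bwd(drb, w[[paste0("enc", l, "b")]], cc$b$xcol, gl$g, n, model$filters[l])
    grads[[paste0("enc", l, "b")]] <- list(W = bb$dW, b = bb$db)
    dra <- bb$dfeat * (cc$a$out > 0)
    c_in <- if (l == 1L) 1L else model$filters[l - 1L]
    ba <- conv_bwd(dra, w[[paste0("enc", l, "a")]], cc$a$xcol, gl$g, n, c_in)
    grads[[paste0("enc", l, "a")]] <- list(W = ba$dW, b = ba$db)
    dfeat <- ba$dfeat
  }
  grads
}

adam_step <- function(model, grads) {
  a <- model$adam
  a$t <- a$t + 1L
  lr <- model$cfg$lr; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr <- lr * sqrt(1 - b2^a$t) / (1 - b1^a$t)
  for (nm in names(model$weights)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      a$m[[nm]][[part]] <- b1 * a$m[[nm]][[part]] + (1 - b1) * g
      a$v[[nm]][[part]] <- b2 * a$v[[nm]][[part]] + (1 - b2) * g^2
      model$weights[[nm]][[part]] <- model$weights[[nm]][[part]] -
        corr * a$m[[nm]][[part]] / (sqrt(a$v[[nm]][[part]]) + eps)
    }
  }
  model$adam <- a
  invisible(model)
}

bce_loss <- function(logits, y) {
  p <- 1 / (1 + exp(-logits))
  eps <- 1e-7
  list(loss = -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))),
       dlogits = (p - y) / length(y))
}

as_unit_image <- function(m) {
  m <- as.matrix(m)
  if (max(m) > 1) m <- m / 255
  m
}

as_mask01 <- function(m) {
  m <- as.matrix(m)
  1 * (m > if (max(m) > 1) 127 else 0.5)
}

#' Train a U-net on image/mask pairs
#'
#' Mini-batch Adam on binary cross-entropy, honoring the configured batch
#' size, epoch cap and early stopping on validation loss (a
#' `val_fraction` split of the supplied pairs).  The best-validation
#' weights are restored on return.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param images list of matrices (intensities in 0..1 or 0..255) sized
#'   to the configured input size.
#' @param masks list of matrices (binary, 0/1 or 0/255) aligned with
#'   `images`.
#' @param verbose print per-epoch losses.
#' @return The model, with a `history` element (data frame of train and
#'   validation loss per epoch).
#' @export
train_unet <- function(model, images, masks, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), length(images) == length(masks))
  cfg <- model$cfg
  sz <- cfg$input_size
  for (im in images) if (!all(dim(im) == sz))
    stop("parameter error: image size does not match the configured input size", call. = FALSE)
  xs <- lapply(images, function(m) as.vector(as_unit_image(m)))
  ys <- lapply(masks, function(m) as.vector(as_mask01(m)))
  n <- length(xs)
  n_val <- max(1L, round(cfg$val_fraction * n))
  ord <- with_local_seed(cfg$seed + 1L, sample.int(n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- setdiff(ord, val_idx)
  if (length(tr_idx) == 0L) stop("parameter error: no training images left after validation split", call. = FALSE)

  best <- list(loss = Inf, weights = NULL, epoch = 0L)
  hist <- list()
  wait <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    sh <- with_local_seed(cfg$seed + 1000L + epoch, sample(tr_idx))
    tr_loss <- 0
    batches <- split(sh, ceiling(seq_along(sh) / cfg$batch_size))
    for (bt in batches) {
      gacc <- NULL
      bl <- 0
      for (i in bt) {
        fw <- unet_forward(model, xs[[i]], train = TRUE)
        lo <- bce_loss(fw$logits, ys[[i]])
        bl <- bl + lo$loss
        g <- unet_backward(model, fw, lo$dlogits / length(bt))
        gacc <- if (is.null(gacc)) g else mapply(function(a, b)
          list(W = a$W + b$W, b = a$b + b$b), gacc, g, SIMPLIFY = FALSE)
      }
      adam_step(model, gacc)
      tr_loss <- tr_loss + bl
    }
    tr_loss <- tr_loss / length(sh)
    val_loss <- mean(vapply(val_idx, function(i)
      bce_loss(unet_forward(model, xs[[i]])$logits, ys[[i]])$loss, numeric(1)))
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                val_loss = val_loss)
    if (verbose) message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tr_loss, val_loss))
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, weights = model$weights, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (!is.null(best$weights)) model$weights <- best$weights
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  invisible(model)
}

#' Predict a rib mask with a trained U-net
#'
#' Runs the network on every axial slice and thresholds the sigmoid
#' output into a binary mask.
#'
#' @param model a trained `unet_model`.
#' @param win a [windowed_volume()] whose slices match the configured
#'   input size.
#' @return A [rib_mask()] (empty provenance; the labeler accepts it
#'   like any other mask).
#' @export
predict_mask <- function(model, win) {
  stopifnot(inherits(model, "unet_model"), inherits(win, "windowed_volume"))
  d <- dim(win$voxels)
  if (!all(d[1:2] == model$cfg$input_size))
    stop("parameter error: slice size does not match the configured input size", call. = FALSE)
  out <- array(0L, d)
  for (z in seq_len(d[3])) {
    logits <- unet_forward(model, as.vector(win$voxels[, , z] / 255))$logits
    p <- 1 / (1 + exp(-logits))
    out[, , z] <- ifelse(matrix(p, d[1], d[2]) > model$cfg$threshold, 255L, 0L)
  }
  rib_mask(binary_volume(out, win$spacing))
}

#' @export
print.unet_model <- function(x, ...) {
  npar <- sum(vapply(x$weights, function(wb) length(wb$W) + length(wb$b), numeric(1)))
  cat(sprintf("<unet_model> depth %d, base filters %d, input %d x %d, %s parameters%s\n",
              x$cfg$depth, x$cfg$base_filters, x$cfg$input_size[1], x$cfg$input_size[2],
              format(npar, big.mark = ","),
              if (!is.null(x$history)) sprintf(", trained %d epochs", nrow(x$history)) else ""))
  invisible(x)
}
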