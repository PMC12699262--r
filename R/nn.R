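# ---------------------------------------------------------------------------
# Minimal CNN toolkit (single-image forward/backward, SGD)
# ---------------------------------------------------------------------------
# A compact, dependency-free convolutional network engine: BLAS-backed
# im2col convolutions, ReLU, per-image (instance) normalization, 2x2 max
# pooling, global average pooling, linear heads and residual blocks, with
# hand-written backward passes.  Mini-batch size is 1 throughout (matching
# the classifier's training protocol), which keeps every tensor a plain
# H x W x C array.  Per-image normalization is used both at train and eval
# time, so inference is deterministic and batch-free.

nn_init_conv <- function(in_ch, out_ch, k) {
  fan_in <- k * k * in_ch
  list(type = "conv", k = k, in_ch = in_ch, out_ch = out_ch,
       W = matrix(rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)), fan_in, out_ch),
       b = numeric(out_ch))
}

nn_init_conv1x1 <- function(in_ch, out_ch) {
  list(type = "conv1x1", in_ch = in_ch, out_ch = out_ch,
       W = matrix(rnorm(in_ch * out_ch, 0, sqrt(2 / in_ch)), in_ch, out_ch),
       b = numeric(out_ch))
}

nn_init_linear <- function(in_n, out_n) {
  list(type = "linear", W = matrix(rnorm(in_n * out_n, 0, sqrt(2 / in_n)), out_n, in_n),
       b = numeric(out_n))
}

nn_init_bn <- function(ch) list(type = "bn", gamma = rep(1, ch), beta = numeric(ch), eps = 1e-5)

nn_relu <- function() list(type = "relu")
nn_pool <- function() list(type = "pool")
nn_gap <- function() list(type = "gap")
nn_residual <- function(layers) list(type = "residual", layers = layers)

# -- im2col / col2im (odd k, same padding) ----------------------------------

im2col <- function(x, k) {
  H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]; p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, C))
  xp[p + seq_len(H), p + seq_len(W), ] <- x
  out <- matrix(0, H * W, k * k * C)
  col <- 1L
  for (ch in seq_len(C)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    out[, col] <- xp[dy + seq_len(H), dx + seq_len(W), ch]
    col <- col + 1L
  }
  out
}

col2im <- function(cols, H, W, C, k) {
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, C))
  col <- 1L
  for (ch in seq_len(C)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    xp[dy + seq_len(H), dx + seq_len(W), ch] <-
      xp[dy + seq_len(H), dx + seq_len(W), ch] + matrix(cols[, col], H, W)
    col <- col + 1L
  }
  xp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

# -- forward / backward per layer -------------------------------------------

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      H <- dim(x)[1L]; W <- dim(x)[2L]
      cols <- im2col(x, layer$k)
      y <- array(cols %*% layer$W +
                   matrix(layer$b, H * W, layer$out_ch, byrow = TRUE),
                 c(H, W, layer$out_ch))
      list(y = y, cache = list(cols = cols, dims = dim(x)))
    },
    conv1x1 = {
      H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]
      xm <- matrix(x, H * W, C)
      y <- array(xm %*% layer$W +
                   matrix(layer$b, H * W, layer$out_ch, byrow = TRUE),
                 c(H, W, layer$out_ch))
      list(y = y, cache = list(xm = xm, dims = dim(x)))
    },
    relu = list(y = pmax(x, 0), cache = list(pos = x > 0)),
    bn = {
      H <- dim(x)[1L]; W <- dim(x)[2L]; C <- dim(x)[3L]; N <- H * W
      xm <- matrix(x, N, C)
      mu <- colMeans(xm)
      xc <- sweep(xm, 2L, mu)
      v <- colMeans(xc^2)
      istd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2L, istd, `*`)
      y <- array(sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`), dim(x))
      list(y = y, cache = list(xhat = xhat, istd = istd, xc = xc, dims = dim(x)))
    },
    pool = {
      H <- dim(x)[1L] - dim(x)[1L] %% 2L; W <- dim(x)[2L] - dim(x)[2L] %% 2L
      C <- dim(x)[3L]
      x <- x[seq_len(H), seq_len(W), , drop = FALSE]
      ro <- seq(1L, H, 2L); co <- seq(1L, W, 2L)
      cand <- array(0, c(H / 2L, W / 2L, C, 4L))
      cand[, , , 1L] <- x[ro, co, , drop = FALSE]
      cand[, , , 2L] <- x[ro + 1L, co, , drop = FALSE]
      cand[, , , 3L] <- x[ro, co + 1L, , drop = FALSE]
      cand[, , , 4L] <- x[ro + 1L, co + 1L, , drop = FALSE]
      y <- pmax(cand[, , , 1L], cand[, , , 2L], cand[, , , 3L], cand[, , , 4L])
      if (length(dim(y)) == 2L) y <- array(y, c(H / 2L, W / 2L, C))
      amax <- array(1L, c(H / 2L, W / 2L, C))
      best <- cand[, , , 1L]
      for (j in 2:4) {
        better <- cand[, , , j] > best
        amax[better] <- j
        best[better] <- cand[, , , j][better]
      }
      list(y = y, cache = list(amax = amax, in_dims = dim(x)))
    },
    gap = {
      C <- dim(x)[3L]
      list(y = colMeans(matrix(x, prod(dim(x)[1:2]), C)), cache = list(dims = dim(x)))
    },
    linear = list(y = as.numeric(layer$W %*% x + layer$b), cache = list(x = x)),
    residual = {
      sub <- nn_forward_layers(layer$layers, x)
      list(y = x + sub$out, cache = list(sub_caches = sub$caches, sub_outputs = sub$outputs))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      H <- cache$dims[1L]; W <- cache$dims[2L]; C <- cache$dims[3L]
      dym <- matrix(dy, H * W, layer$out_ch)
      grads <- list(W = crossprod(cache$cols, dym), b = colSums(dym))
      dx <- col2im(dym %*% t(layer$W), H, W, C, layer$k)
      list(dx = dx, grads = grads)
    },
    conv1x1 = {
      H <- cache$dims[1L]; W <- cache$dims[2L]; C <- cache$dims[3L]
      dym <- matrix(dy, H * W, layer$out_ch)
      grads <- list(W = crossprod(cache$xm, dym), b = colSums(dym))
      list(dx = array(dym %*% t(layer$W), cache$dims), grads = grads)
    },
    relu = list(dx = dy * cache$pos, grads = NULL),
    bn = {
      dims <- cache$dims; N <- dims[1L] * dims[2L]; C <- dims[3L]
      dym <- matrix(dy, N, C)
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2L, layer$gamma, `*`)
      # dx = istd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
      s1 <- colSums(dxhat); s2 <- colSums(dxhat * cache$xhat)
      dxm <- sweep(N * dxhat - matrix(s1, N, C, byrow = TRUE) -
                     cache$xhat * matrix(s2, N, C, byrow = TRUE),
                   2L, cache$istd / N, `*`)
      list(dx = array(dxm, dims), grads = list(gamma = dgamma, beta = dbeta))
    },
    pool = {
      H <- cache$in_dims[1L]; W <- cache$in_dims[2L]; C <- cache$in_dims[3L]
      dx <- array(0, cache$in_dims)
      ho <- dim(dy)[1L]; wo <- dim(dy)[2L]
      offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
      for (j in 1:4) {
        sel <- cache$amax == j
        tmp <- array(0, dim(dy)); tmp[sel] <- dy[sel]
        dx[seq(1L, 2L * ho, 2L) + offs[[j]][1L],
           seq(1L, 2L * wo, 2L) + offs[[j]][2L], ] <-
          dx[seq(1L, 2L * ho, 2L) + offs[[j]][1L],
             seq(1L, 2L * wo, 2L) + offs[[j]][2L], , drop = FALSE] + tmp
      }
      list(dx = dx, grads = NULL)
    },
    gap = {
      N <- cache$dims[1L] * cache$dims[2L]
      dx <- array(rep(dy / N, each = N), cache$dims)
      list(dx = dx, grads = NULL)
    },
    linear = list(dx = as.numeric(crossprod(layer$W, dy)),
                  grads = list(W = outer(as.numeric(dy), cache$x), b = as.numeric(dy))),
    residual = {
      sub <- nn_backward_layers(layer$layers, cache$sub_caches, dy)
      list(dx = dy + sub$dx, grads = list(sub_grads = sub$grads))
    },
    stop("unknown layer type: ", layer$type))
}

nn_forward_layers <- function(layers, x) {
  caches <- vector("list", length(layers))
  outputs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x)
    x <- fw$y
    caches[[i]] <- fw$cache
    outputs[[i]] <- x
  }
  list(out = x, caches = caches, outputs = outputs)
}

nn_backward_layers <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  d_outputs <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    d_outputs[i] <- list(dout)
    bw <- layer_backward(layers[[i]], caches[[i]], dout)
    grads[i] <- list(bw$grads)   # [[<- would drop NULL entries and shift indices
    dout <- bw$dx
  }
  list(dx = dout, grads = grads, d_outputs = d_outputs)
}

#' Forward pass of a layer list
#'
#' @param net list of layers (internal layer records).
#' @param x input H x W x C array.
#' @return list with \code{out}, per-layer \code{caches} and \code{outputs}.
#' @keywords internal
nn_forward <- function(net, x) nn_forward_layers(net, x)

#' Backward pass of a layer list
#' @keywords internal
nn_backward <- function(net, caches, dout) nn_backward_layers(net, caches, dout)

nn_sgd_step <- function(layers, grads, lr) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (layers[[i]]$type == "residual") {
      layers[[i]]$layers <- nn_sgd_step(layers[[i]]$layers, g$sub_grads, lr)
    } else if (layers[[i]]$type == "bn") {
      layers[[i]]$gamma <- layers[[i]]$gamma - lr * g$gamma
      layers[[i]]$beta <- layers[[i]]$beta - lr * g$beta
    } else {
      layers[[i]]$W <- layers[[i]]$W - lr * g$W
      layers[[i]]$b <- layers[[i]]$b - lr * g$b
    }
  }
  layers
}

# Per-pixel softmax cross-entropy for a logits raster (H x W x K) against an
# integer target raster (values 1..K).  Returns mean loss and dlogits.
softmax_xent_raster <- function(logits, targets) {
  H <- dim(logits)[1L]; W <- dim(logits)[2L]; K <- dim(logits)[3L]
  lm <- matrix(logits, H * W, K)
  lm <- lm - apply(lm, 1L, max)
  el <- exp(lm)
  probs <- el / rowSums(el)
  idx <- cbind(seq_len(H * W), as.integer(targets))
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dl <- probs
  dl[idx] <- dl[idx] - 1
  list(loss = loss, probs = probs, dlogits = array(dl / (H * W), c(H, W, K)))
}

# Softmax cross-entropy for a logit vector against a class index.
softmax_xent_vec <- function(logits, target) {
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  list(loss = -log(max(p[target], 1e-12)), probs = p,
       dlogits = { d <- p; d[target] <- d[target] - 1; d })
}
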