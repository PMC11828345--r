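# Small convolutional backbones with hand-written backprop.
#
# No deep-learning runtime is required: convolution is im2col + matrix
# multiply, training is minibatch Adam on the cross-entropy loss. The
# backbones are deliberately small (they train on a single CPU core in
# seconds per epoch at 32x32 input) and serve as pluggable base models for
# the ensemble; the CSAE operator is inserted between the last feature stage
# and global average pooling when requested.

# channel widths per named backbone variant; `extra_conv` adds one more 3x3
# stage without pooling
tiny_backbones <- list(
  tiny_cnn = list(channels = c(8L, 16L, 16L), extra_conv = FALSE),
  tiny_cnn_wide = list(channels = c(12L, 24L, 24L), extra_conv = FALSE),
  tiny_cnn_deep = list(channels = c(8L, 16L, 16L), extra_conv = TRUE)
)

pretrained_backbones <- c("resnet18", "mobilenetv3_small", "googlenet",
                          "efficientnet_b0")

he_init <- function(n_out, fan_in) {
  matrix(rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

# Initialise parameters for a tiny backbone. Layout:
#  conv1 (3 -> c1, 3x3, pad 1), relu, maxpool2
#  conv2 (c1 -> c2, 3x3, pad 1), relu, maxpool2
#  conv3 (c2 -> c3, 3x3, pad 1), relu           [conv4 if extra_conv]
#  [CSAE on the C x H x W feature map]
#  global average pool, dense c3 -> K, softmax
net_init <- function(backbone, num_classes, use_csae, csae_kernel = 3L,
                     seed = 1L) {
  if (backbone %in% pretrained_backbones) {
    stop(sprintf(paste0(
      "backbone '%s' needs a deep-learning runtime and published pretrained ",
      "weights, neither of which this package bundles; use one of: %s"
    ), backbone, paste(names(tiny_backbones), collapse = ", ")), call. = FALSE)
  }
  arch <- tiny_backbones[[backbone]]
  if (is.null(arch)) {
    stop(sprintf("unknown backbone '%s'", backbone), call. = FALSE)
  }
  ch <- arch$channels
  with_seed(seed, {
    params <- list(
      W1 = he_init(ch[1L], 9L * 3L), b1 = numeric(ch[1L]),
      W2 = he_init(ch[2L], 9L * ch[1L]), b2 = numeric(ch[2L]),
      W3 = he_init(ch[3L], 9L * ch[2L]), b3 = numeric(ch[3L]),
      Wfc = he_init(num_classes, ch[3L]), bfc = numeric(num_classes)
    )
    if (arch$extra_conv) {
      params$W4 <- he_init(ch[3L], 9L * ch[3L])
      params$b4 <- numeric(ch[3L])
    }
    if (use_csae) {
      k <- as.integer(csae_kernel)
      delta <- numeric(k); delta[(k + 1L) / 2L] <- 1
      params$gc <- delta + rnorm(k, sd = 0.05)
      params$gs <- delta + rnorm(k, sd = 0.05)
    }
    attr(params, "backbone") <- backbone
    attr(params, "use_csae") <- use_csae
    params
  })
}

# im2col for a 3x3 convolution with zero padding 1; x is h x w x cin.
im2col3 <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; cin <- dim(x)[3L]
  xp <- array(0, dim = c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  col <- matrix(0, h * w, 9L * cin)
  idx <- 0L
  for (ci in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        idx <- idx + 1L
        col[, idx] <- xp[(1L + di):(h + di), (1L + dj):(w + dj), ci]
      }
    }
  }
  col
}

col2im3 <- function(dcol, h, w, cin) {
  dxp <- array(0, dim = c(h + 2L, w + 2L, cin))
  idx <- 0L
  for (ci in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        idx <- idx + 1L
        dxp[(1L + di):(h + di), (1L + dj):(w + dj), ci] <-
          dxp[(1L + di):(h + di), (1L + dj):(w + dj), ci] +
          matrix(dcol[, idx], h, w)
      }
    }
  }
  dxp[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

conv3_forward <- function(x, W, b) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  col <- im2col3(x)
  out <- col %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, dim = c(h, w, ncol(W))), col = col)
}

conv3_backward <- function(dout, col, W, h, w, cin) {
  dmat <- matrix(dout, h * w, ncol(W))
  list(
    dW = crossprod(col, dmat),
    db = colSums(dmat),
    dx = col2im3(dmat %*% t(W), h, w, cin)
  )
}

maxpool2_forward <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  o <- seq(1L, h, by = 2L); e <- seq(2L, h, by = 2L)
  ow <- seq(1L, w, by = 2L); ew <- seq(2L, w, by = 2L)
  a <- x[o, ow, , drop = FALSE]; b <- x[e, ow, , drop = FALSE]
  cc <- x[o, ew, , drop = FALSE]; d <- x[e, ew, , drop = FALSE]
  out <- pmax(a, b, cc, d)
  # first-wins routing masks for the backward pass
  m1 <- a == out
  m2 <- (b == out) & !m1
  m3 <- (cc == out) & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  list(out = out, masks = list(m1, m2, m3, m4), in_dim = c(h, w, dim(x)[3L]))
}

maxpool2_backward <- function(dout, cache) {
  h <- cache$in_dim[1L]; w <- cache$in_dim[2L]
  dx <- array(0, dim = cache$in_dim)
  o <- seq(1L, h, by = 2L); e <- seq(2L, h, by = 2L)
  ow <- seq(1L, w, by = 2L); ew <- seq(2L, w, by = 2L)
  dx[o, ow, ] <- dout * cache$masks[[1L]]
  dx[e, ow, ] <- dx[e, ow, ] + dout * cache$masks[[2L]]
  dx[o, ew, ] <- dx[o, ew, ] + dout * cache$masks[[3L]]
  dx[e, ew, ] <- dx[e, ew, ] + dout * cache$masks[[4L]]
  dx
}

# Forward pass on one image (h x w x 3, values roughly centred; see
# prepare_input). Returns class probabilities and, when `keep_cache`, all
# intermediates for backprop.
net_forward <- function(params, x, keep_cache = FALSE) {
  use_csae <- attr(params, "use_csae")
  extra <- !is.null(params$W4)
  c1 <- conv3_forward(x, params$W1, params$b1)
  r1 <- pmax(c1$out, 0)
  p1 <- maxpool2_forward(r1)
  c2 <- conv3_forward(p1$out, params$W2, params$b2)
  r2 <- pmax(c2$out, 0)
  p2 <- maxpool2_forward(r2)
  c3 <- conv3_forward(p2$out, params$W3, params$b3)
  r3 <- pmax(c3$out, 0)
  if (extra) {
    c4 <- conv3_forward(r3, params$W4, params$b4)
    feat <- pmax(c4$out, 0)
  } else {
    c4 <- NULL
    feat <- r3
  }
  if (use_csae) {
    fmap <- aperm(feat, c(3L, 1L, 2L)) # C x H x W
    cs <- csae_forward_cache(fmap, params$gc, params$gs)
    fm <- fmap_to_matrix(cs$out)
  } else {
    cs <- NULL
    d <- dim(feat)
    fm <- t(matrix(feat, d[1L] * d[2L], d[3L]))
  }
  g <- rowMeans(fm) # global average pool, length C
  logits <- as.vector(t(params$Wfc) %*% g + params$bfc) # Wfc is C x K
  probs <- softmax_vec(logits)
  if (!keep_cache) return(list(probs = probs))
  list(
    probs = probs,
    cache = list(x = x, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                 c3 = c3, r3 = r3, c4 = c4, feat = feat, cs = cs, g = g,
                 extra = extra, use_csae = use_csae, feat_dim = dim(feat))
  )
}

# Backward pass for one image given dlogits (probs - onehot for CE loss).
net_backward <- function(params, fwd, dlogits) {
  cache <- fwd$cache
  grads <- list()
  grads$Wfc <- outer(cache$g, dlogits)
  grads$bfc <- dlogits
  dg <- as.vector(params$Wfc %*% dlogits)
  fd <- cache$feat_dim
  P <- fd[1L] * fd[2L]
  C <- fd[3L]
  if (cache$use_csae) {
    dfm <- matrix(dg / P, C, P) # grad through rowMeans, C x P
    dcs <- csae_backward(cache$cs, matrix_to_fmap(dfm, c(C, fd[1L], fd[2L])))
    grads$gc <- dcs$dgc
    grads$gs <- dcs$dgs
    dfeat <- aperm(dcs$df, c(2L, 3L, 1L)) # back to h x w x C
  } else {
    dfeat <- array(rep(dg / P, each = P), dim = fd)
  }
  if (cache$extra) {
    dfeat <- dfeat * (cache$c4$out > 0)
    bb <- conv3_backward(dfeat, cache$c4$col, params$W4,
                         fd[1L], fd[2L], dim(cache$r3)[3L])
    grads$W4 <- bb$dW; grads$b4 <- bb$db
    dr3 <- bb$dx
  } else {
    dr3 <- dfeat
  }
  dr3 <- dr3 * (cache$c3$out > 0)
  b3 <- conv3_backward(dr3, cache$c3$col, params$W3,
                       dim(dr3)[1L], dim(dr3)[2L], dim(cache$p2$out)[3L])
  grads$W3 <- b3$dW; grads$b3 <- b3$db
  dp2 <- maxpool2_backward(b3$dx, cache$p2)
  dp2 <- dp2 * (cache$c2$out > 0)
  b2 <- conv3_backward(dp2, cache$c2$col, params$W2,
                       dim(dp2)[1L], dim(dp2)[2L], dim(cache$p1$out)[3L])
  grads$W2 <- b2$dW; grads$b2 <- b2$db
  dp1 <- maxpool2_backward(b2$dx, cache$p1)
  dp1 <- dp1 * (cache$c1$out > 0)
  b1 <- conv3_backward(dp1, cache$c1$col, params$W1,
                       dim(dp1)[1L], dim(dp1)[2L], 3L)
  grads$W1 <- b1$dW; grads$b1 <- b1$db
  grads
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Scale a 0..255 image to zero-centred inputs.
prepare_input <- function(img) img / 255 - 0.5

# Predicted class probabilities for a list of prepared inputs.
net_predict_probs <- function(params, inputs) {
  t(vapply(inputs, function(x) net_forward(params, x)$probs,
           numeric(length(params$bfc))))
}

net_accuracy <- function(params, inputs, y) {
  probs <- net_predict_probs(params, inputs)
  mean(max.col(probs, ties.method = "first") == y)
}

# Minibatch Adam training of one backbone. `inputs` are prepared input
# arrays; `y` integer labels in 1..K. Records validation accuracy per epoch
# and returns the parameters of the best validation epoch (standard early
# checkpointing; ties go to the earlier epoch).
net_train <- function(params, inputs, y, val_inputs, val_y,
                      epochs, batch_size, lr, seed) {
  state <- adam_init(params)
  n <- length(inputs)
  val_acc <- numeric(epochs)
  train_loss <- numeric(epochs)
  best <- list(acc = -Inf, params = params)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste("epoch", ep)), sample.int(n))
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      grads_sum <- NULL
      batch_loss <- 0
      for (i in idx) {
        fwd <- net_forward(params, inputs[[i]], keep_cache = TRUE)
        p <- fwd$probs
        batch_loss <- batch_loss - log(max(p[y[i]], 1e-12))
        dlogits <- p
        dlogits[y[i]] <- dlogits[y[i]] - 1
        g <- net_backward(params, fwd, dlogits)
        grads_sum <- if (is.null(grads_sum)) g else {
          Map(`+`, grads_sum, g)
        }
      }
      if (!all(is.finite(batch_loss))) {
        stop("non-finite training loss; aborting", call. = FALSE)
      }
      grads_mean <- lapply(grads_sum, function(g) g / length(idx))
      upd <- adam_step(params, grads_mean, state, lr)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, batch_loss / length(idx))
    }
    train_loss[ep] <- mean(losses)
    val_acc[ep] <- net_accuracy(params, val_inputs, val_y)
    if (val_acc[ep] > best$acc) best <- list(acc = val_acc[ep], params = params)
  }
  list(params = best$params, final_params = params, val_acc = val_acc,
       train_loss = train_loss)
}

# Exact parameter count of a parameter list.
net_param_count <- function(params) {
  sum(vapply(params, length, integer(1)))
}
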