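# Native neural-network engine.
#
# No deep-learning framework is available to R in this environment, so the
# convolutional classifier is implemented directly on top of BLAS. Design:
#
#  * Activations for a batch of N inputs are (C*H*W, N) matrices with
#    channel-fastest flattening: vector index = c + C*(h + H*w). Because the
#    channel index varies fastest, the same memory reinterprets freely as a
#    (C, H*W*N) matrix for per-channel ops (batch norm) via dim<-.
#  * Convolutions use im2col expressed as one precomputed gather-index
#    vector per layer (patch-element-fastest ordering): the forward pass is
#    a row gather feeding a dense BLAS GEMM, the backward col2im is a
#    rowsum() scatter-add. Zero padding maps to a sentinel row appended to
#    the input.
#  * Max pooling precomputes the 3x3 offset maps once per geometry.
#
# Layers are plain lists; a network is a list of layers plus metadata.
# Forward passes record per-layer caches for backprop; Adam keeps first and
# second moments per parameter, addressed by (layer index, parameter name).

.conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# im2col gather index for (C, H, W) inputs: a length-K*P vector of source
# row indices into the flattened input, with D+1 marking zero padding (the
# forward pass appends one zero row). Patch-element index varies fastest.
.build_im2col <- function(C, H, W, k, stride, pad) {
  outH <- .conv_out_dim(H, k, stride, pad)
  outW <- .conv_out_dim(W, k, stride, pad)
  if (outH < 1L || outW < 1L) {
    stop("input spatial dims (", H, "x", W, ") too small for ", k, "x", k,
         " kernel with stride ", stride, "; minimum is ",
         k - 2L * pad, "x", k - 2L * pad)
  }
  K <- C * k * k
  P <- outH * outW
  grid_k <- expand.grid(c = 0:(C - 1L), ki = 0:(k - 1L), kj = 0:(k - 1L))
  grid_p <- expand.grid(oh = 0:(outH - 1L), ow = 0:(outW - 1L))
  kk <- grid_k[rep(seq_len(K), times = P), ]
  pp <- grid_p[rep(seq_len(P), each = K), ]
  h <- pp$oh * stride - pad + kk$ki
  w <- pp$ow * stride - pad + kk$kj
  inside <- h >= 0L & h < H & w >= 0L & w < W
  D <- C * H * W
  gidx <- rep.int(D + 1L, K * P)
  gidx[inside] <- (kk$c + C * (h + H * w))[inside] + 1L
  present <- sort(unique(gidx))
  list(gidx = gidx, D = D, present = present)
}

.he_init <- function(n_out, fan_in) {
  matrix(rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), nrow = n_out)
}

layer_conv <- function(in_shape, out_channels, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  G <- .build_im2col(C, H, W, k, stride, pad)
  outH <- .conv_out_dim(H, k, stride, pad)
  outW <- .conv_out_dim(W, k, stride, pad)
  K <- C * k * k
  list(type = "conv",
       params = list(W = .he_init(out_channels, K)),
       gidx = G$gidx, present = G$present, D = G$D,
       K = K, P = outH * outW,
       in_shape = in_shape, out_shape = c(out_channels, outH, outW))
}

layer_bn <- function(in_shape, eps = 1e-5, momentum = 0.1) {
  C <- in_shape[1]
  list(type = "bn",
       params = list(gamma = rep(1, C), beta = rep(0, C)),
       state = list(mean = rep(0, C), var = rep(1, C)),
       eps = eps, momentum = momentum,
       in_shape = in_shape, out_shape = in_shape)
}

layer_relu <- function(in_shape) {
  list(type = "relu", params = list(), in_shape = in_shape,
       out_shape = in_shape)
}

layer_maxpool <- function(in_shape, k = 3L, stride = 2L, pad = 1L) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  outH <- .conv_out_dim(H, k, stride, pad)
  outW <- .conv_out_dim(W, k, stride, pad)
  if (outH < 1L || outW < 1L) stop("input too small for pooling")
  P <- outH * outW
  grid_p <- expand.grid(oh = 0:(outH - 1L), ow = 0:(outW - 1L))
  # spatial source index (1-based, NA when padding) per output pos and offset
  smap <- matrix(NA_integer_, nrow = P, ncol = k * k)
  j <- 0L
  for (kj in 0:(k - 1L)) {
    for (ki in 0:(k - 1L)) {
      j <- j + 1L
      h <- grid_p$oh * stride - pad + ki
      w <- grid_p$ow * stride - pad + kj
      ok <- h >= 0L & h < H & w >= 0L & w < W
      smap[ok, j] <- (h + H * w)[ok] + 1L
    }
  }
  list(type = "maxpool", params = list(), smap = smap,
       S_in = H * W, P = P,
       in_shape = in_shape, out_shape = c(C, outH, outW))
}

layer_gap <- function(in_shape) {
  C <- in_shape[1]; S <- in_shape[2] * in_shape[3]
  # (C, C*S) sparse averaging matrix over the channel-fastest layout
  Pm <- Matrix::sparseMatrix(i = rep(seq_len(C), S),
                             j = seq_len(C * S), x = 1 / S,
                             dims = c(C, C * S))
  list(type = "gap", params = list(), Pm = Pm,
       in_shape = in_shape, out_shape = c(C, 1L, 1L))
}

layer_dense <- function(n_in, n_out) {
  list(type = "dense",
       params = list(W = .he_init(n_out, n_in), b = rep(0, n_out)),
       in_shape = c(n_in, 1L, 1L), out_shape = c(n_out, 1L, 1L))
}

# residual basic block: conv-bn-relu-conv-bn + shortcut, then relu.
# shortcut is identity, or 1x1 conv + bn when stride != 1 or channels change.
layer_resblock <- function(in_shape, out_channels, stride = 1L) {
  main <- list(layer_conv(in_shape, out_channels, 3L, stride))
  main <- c(main, list(layer_bn(main[[1]]$out_shape),
                       layer_relu(main[[1]]$out_shape)))
  main <- c(main, list(layer_conv(main[[1]]$out_shape, out_channels, 3L, 1L)))
  main <- c(main, list(layer_bn(main[[4]]$out_shape)))
  shortcut <- list()
  if (stride != 1L || in_shape[1] != out_channels) {
    shortcut <- list(layer_conv(in_shape, out_channels, 1L, stride, pad = 0L))
    shortcut <- c(shortcut, list(layer_bn(shortcut[[1]]$out_shape)))
  }
  list(type = "resblock", params = list(), main = main, shortcut = shortcut,
       in_shape = in_shape, out_shape = main[[4]]$out_shape)
}

# ---------------------------------------------------------------------------
# forward / backward

.fw_layer <- function(layer, X, N, training) {
  switch(layer$type,
    conv = {
      Xp <- rbind(X, rep.int(0, N)) # row D+1 supplies the zero padding
      Xcol <- Xp[layer$gidx, , drop = FALSE]
      dim(Xcol) <- c(layer$K, layer$P * N)
      Y <- layer$params$W %*% Xcol
      dim(Y) <- c(prod(layer$out_shape), N)
      list(Y = Y, cache = list(Xcol = Xcol))
    },
    bn = {
      C <- layer$in_shape[1]
      M <- length(X) / C
      dim(X) <- c(C, M)
      if (training) {
        ones <- rep.int(1 / M, M)
        mu <- drop(X %*% ones)
        xc <- X - mu
        v <- drop((xc * xc) %*% ones)
        invstd <- 1 / sqrt(v + layer$eps)
        xhat <- xc * invstd
        # running stats updated by the caller through the returned state
        state <- list(
          mean = (1 - layer$momentum) * layer$state$mean + layer$momentum * mu,
          var = (1 - layer$momentum) * layer$state$var + layer$momentum * v)
      } else {
        invstd <- 1 / sqrt(layer$state$var + layer$eps)
        xhat <- (X - layer$state$mean) * invstd
        state <- NULL
      }
      Y <- layer$params$gamma * xhat + layer$params$beta
      dim(Y) <- c(length(Y) / N, N)
      list(Y = Y, cache = list(xhat = xhat, invstd = invstd, M = M),
           state = state)
    },
    relu = {
      Y <- X
      Y[Y < 0] <- 0
      list(Y = Y, cache = list(mask = X > 0))
    },
    maxpool = {
      C <- layer$in_shape[1]
      S <- layer$S_in
      P <- layer$P
      Xc <- X
      dim(Xc) <- c(C, S * N)
      best <- matrix(-Inf, C, P * N)
      arg <- matrix(0L, C, P * N)
      offs <- rep((0:(N - 1L)) * S, each = P)
      offs_out <- seq_len(P * N)
      for (j in seq_len(ncol(layer$smap))) {
        sIn <- layer$smap[, j]
        ok <- !is.na(sIn)
        cols_in <- rep(sIn, N)[rep(ok, N)] + offs[rep(ok, N)]
        cols_out <- offs_out[rep(ok, N)]
        vals <- Xc[, cols_in, drop = FALSE]
        cur <- best[, cols_out, drop = FALSE]
        upd <- vals > cur
        if (any(upd)) {
          cur[upd] <- vals[upd]
          best[, cols_out] <- cur
          a <- arg[, cols_out, drop = FALSE]
          a[upd] <- j
          arg[, cols_out] <- a
        }
      }
      Y <- best
      dim(Y) <- c(C * P, N)
      list(Y = Y, cache = list(arg = arg, offs = offs, offs_out = offs_out))
    },
    gap = {
      Y <- as.matrix(layer$Pm %*% X)
      list(Y = Y, cache = NULL)
    },
    dense = {
      list(Y = layer$params$W %*% X + layer$params$b, cache = list(X = X))
    },
    resblock = {
      main_out <- X
      main_caches <- vector("list", length(layer$main))
      main_states <- vector("list", length(layer$main))
      for (i in seq_along(layer$main)) {
        r <- .fw_layer(layer$main[[i]], main_out, N, training)
        main_out <- r$Y
        main_caches[i] <- list(r$cache)
        main_states[i] <- list(r$state)
      }
      if (length(layer$shortcut)) {
        sc_out <- X
        sc_caches <- vector("list", length(layer$shortcut))
        sc_states <- vector("list", length(layer$shortcut))
        for (i in seq_along(layer$shortcut)) {
          r <- .fw_layer(layer$shortcut[[i]], sc_out, N, training)
          sc_out <- r$Y
          sc_caches[i] <- list(r$cache)
          sc_states[i] <- list(r$state)
        }
      } else {
        sc_out <- X
        sc_caches <- list()
        sc_states <- list()
      }
      pre <- main_out + sc_out
      Y <- pre
      Y[Y < 0] <- 0
      list(Y = Y,
           cache = list(main = main_caches, shortcut = sc_caches,
                        mask = pre > 0),
           state = list(main = main_states, shortcut = sc_states))
    },
    stop("unknown layer type ", layer$type))
}

.bw_layer <- function(layer, dY, cache, N, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      dYm <- dY
      dim(dYm) <- c(layer$out_shape[1], layer$P * N)
      dW <- tcrossprod(dYm, cache$Xcol)
      dX <- NULL
      if (need_dx) {
        dXcol <- crossprod(layer$params$W, dYm)
        dim(dXcol) <- c(layer$K * layer$P, N)
        # scatter-add back to input rows (col2im)
        acc <- rowsum(dXcol, layer$gidx, reorder = TRUE)
        dXp <- matrix(0, layer$D + 1L, N)
        dXp[layer$present, ] <- acc
        dX <- dXp[-(layer$D + 1L), , drop = FALSE]
      }
      list(dX = dX, grads = list(W = dW))
    },
    bn = {
      C <- layer$in_shape[1]
      M <- cache$M
      dYm <- dY
      dim(dYm) <- c(C, M)
      ones <- rep.int(1, M)
      dgamma <- drop((dYm * cache$xhat) %*% ones)
      dbeta <- drop(dYm %*% ones)
      dX <- (layer$params$gamma * cache$invstd / M) *
        (M * dYm - dbeta - cache$xhat * dgamma)
      dim(dX) <- c(length(dX) / N, N)
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = {
      list(dX = dY * cache$mask, grads = list())
    },
    maxpool = {
      C <- layer$in_shape[1]
      S <- layer$S_in
      P <- layer$P
      dYm <- dY
      dim(dYm) <- c(C, P * N)
      dX <- matrix(0, C, S * N)
      for (j in seq_len(ncol(layer$smap))) {
        sIn <- layer$smap[, j]
        ok <- !is.na(sIn)
        cols_in <- rep(sIn, N)[rep(ok, N)] + cache$offs[rep(ok, N)]
        cols_out <- cache$offs_out[rep(ok, N)]
        sel <- cache$arg[, cols_out, drop = FALSE] == j
        if (any(sel)) {
          block <- dX[, cols_in, drop = FALSE]
          block[sel] <- block[sel] + dYm[, cols_out, drop = FALSE][sel]
          dX[, cols_in] <- block
        }
      }
      dim(dX) <- c(C * S, N)
      list(dX = dX, grads = list())
    },
    gap = {
      list(dX = as.matrix(Matrix::crossprod(layer$Pm, dY)), grads = list())
    },
    dense = {
      list(dX = crossprod(layer$params$W, dY),
           grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
    },
    resblock = {
      dpre <- dY * cache$mask
      # main branch
      d_main <- dpre
      main_grads <- vector("list", length(layer$main))
      for (i in rev(seq_along(layer$main))) {
        r <- .bw_layer(layer$main[[i]], d_main, cache$main[[i]], N)
        d_main <- r$dX
        main_grads[[i]] <- r$grads
      }
      if (length(layer$shortcut)) {
        d_sc <- dpre
        sc_grads <- vector("list", length(layer$shortcut))
        for (i in rev(seq_along(layer$shortcut))) {
          r <- .bw_layer(layer$shortcut[[i]], d_sc, cache$shortcut[[i]], N)
          d_sc <- r$dX
          sc_grads[[i]] <- r$grads
        }
      } else {
        d_sc <- dpre
        sc_grads <- list()
      }
      list(dX = d_main + d_sc,
           grads = list(main = main_grads, shortcut = sc_grads))
    },
    stop("unknown layer type ", layer$type))
}

# full-network forward; returns logits plus caches and updated BN states
nn_forward <- function(net, X, training = FALSE) {
  N <- ncol(X)
  caches <- vector("list", length(net$layers))
  states <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- .fw_layer(net$layers[[i]], X, N, training)
    X <- r$Y
    caches[i] <- list(r$cache)
    states[i] <- list(r$state)
  }
  list(logits = X, caches = caches, states = states)
}

nn_backward <- function(net, caches, dlogits) {
  N <- ncol(dlogits)
  grads <- vector("list", length(net$layers))
  dY <- dlogits
  for (i in rev(seq_along(net$layers))) {
    r <- .bw_layer(net$layers[[i]], dY, caches[[i]], N, need_dx = i > 1L)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  grads
}

# apply freshly computed BN batch statistics to the stored running stats
nn_commit_states <- function(net, states) {
  apply_state <- function(layer, st) {
    if (is.null(st)) return(layer)
    if (layer$type == "bn") {
      layer$state <- st
    } else if (layer$type == "resblock") {
      for (i in seq_along(layer$main)) {
        layer$main[[i]] <- apply_state(layer$main[[i]], st$main[[i]])
      }
      for (i in seq_along(layer$shortcut)) {
        layer$shortcut[[i]] <- apply_state(layer$shortcut[[i]], st$shortcut[[i]])
      }
    }
    layer
  }
  for (i in seq_along(net$layers)) {
    net$layers[[i]] <- apply_state(net$layers[[i]], states[[i]])
  }
  net
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

# cross-entropy loss and gradient for one-hot labels given as class indices
softmax_xent <- function(logits, y_idx) {
  N <- ncol(logits)
  p <- softmax_cols(logits)
  picked <- p[cbind(y_idx, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(y_idx, seq_len(N))] <-
    dlogits[cbind(y_idx, seq_len(N))] - 1
  list(loss = loss, dlogits = dlogits / N)
}

# ---------------------------------------------------------------------------
# parameter traversal + Adam

# walk all parameterized layers; f(path, layer) is called for each. Returns
# modified net when f returns a layer.
.param_paths <- function(layers, prefix = character()) {
  out <- list()
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    if (layer$type == "resblock") {
      out <- c(out,
               .param_paths(layer$main, c(prefix, i, "main")),
               .param_paths(layer$shortcut, c(prefix, i, "shortcut")))
    } else if (length(layer$params)) {
      out <- c(out, list(c(prefix, i)))
    }
  }
  out
}

.get_layer <- function(layers, path) {
  while (length(path) > 1L) {
    layers <- layers[[as.integer(path[1])]][[path[2]]]
    path <- path[-(1:2)]
  }
  layers[[as.integer(path[1])]]
}

.set_layer <- function(layers, path, value) {
  if (length(path) == 1L) {
    layers[[as.integer(path[1])]] <- value
    return(layers)
  }
  i <- as.integer(path[1])
  branch <- path[2]
  layers[[i]][[branch]] <- .set_layer(layers[[i]][[branch]], path[-(1:2)], value)
  layers
}

.get_grads <- function(grads, path) {
  while (length(path) > 1L) {
    grads <- grads[[as.integer(path[1])]][[path[2]]]
    path <- path[-(1:2)]
  }
  grads[[as.integer(path[1])]]
}

adam_init <- function(net, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  paths <- .param_paths(net$layers)
  moments <- lapply(paths, function(p) {
    layer <- .get_layer(net$layers, p)
    lapply(layer$params, function(w) list(m = w * 0, v = w * 0))
  })
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       paths = paths, moments = moments)
}

adam_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in seq_along(opt$paths)) {
    path <- opt$paths[[k]]
    layer <- .get_layer(net$layers, path)
    g <- .get_grads(grads, path)
    for (nm in names(layer$params)) {
      mo <- opt$moments[[k]][[nm]]
      mo$m <- opt$beta1 * mo$m + (1 - opt$beta1) * g[[nm]]
      mo$v <- opt$beta2 * mo$v + (1 - opt$beta2) * g[[nm]]^2
      opt$moments[[k]][[nm]] <- mo
      layer$params[[nm]] <- layer$params[[nm]] -
        opt$lr * (mo$m / bc1) / (sqrt(mo$v / bc2) + opt$eps)
    }
    net$layers <- .set_layer(net$layers, path, layer)
  }
  list(net = net, opt = opt)
}
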