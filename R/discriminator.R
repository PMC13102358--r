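# Four-class residual-network discriminator over window tensors.

#' Build the residual-network window classifier
#'
#' The `"paper"` preset reproduces the ResNet-34 layout: a 7x7/stride-2
#' convolution with batch normalization, ReLU, and 3x3/stride-2 max pooling,
#' then 16 basic residual blocks in four stages of (3, 4, 6, 3) blocks with
#' (64, 128, 256, 512) channels and identity/projection shortcuts, ending in
#' global average pooling and a 4-unit classification layer. The `"desk"`
#' preset keeps the identical code path at CPU scale: one block per stage
#' with (8, 16, 32, 64) channels.
#'
#' @param input_shape integer(3): (layers, haplotypes, SNPs), default
#'   c(2, 44, 128).
#' @param preset `"desk"` or `"paper"`.
#' @param seed seed for weight initialization.
#' @return a `discriminator` network object.
#' @export
build_network <- function(input_shape = c(2L, 44L, 128L),
                          preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1L))
  blocks <- if (preset == "paper") c(3L, 4L, 6L, 3L) else c(1L, 1L, 1L, 1L)
  widths <- if (preset == "paper") c(64L, 128L, 256L, 512L)
            else c(8L, 16L, 32L, 64L)
  with_seed(seed, {
    layers <- list(layer_conv(input_shape, widths[1], 7L, 2L, 3L))
    shape <- layers[[1]]$out_shape
    layers <- c(layers, list(layer_bn(shape), layer_relu(shape)))
    mp <- layer_maxpool(shape)
    layers <- c(layers, list(mp))
    shape <- mp$out_shape
    for (stage in 1:4) {
      for (b in seq_len(blocks[stage])) {
        stride <- if (stage > 1L && b == 1L) 2L else 1L
        blk <- layer_resblock(shape, widths[stage], stride)
        layers <- c(layers, list(blk))
        shape <- blk$out_shape
      }
    }
    layers <- c(layers, list(layer_gap(shape)))
    layers <- c(layers, list(layer_dense(shape[1], 4L)))
    structure(list(layers = layers, input_shape = as.integer(input_shape),
                   preset = preset, class_order = SCENARIO_CLASSES,
                   version = 1L),
              class = "discriminator")
  })
}

#' @export
print.discriminator <- function(x, ...) {
  cat(sprintf("<discriminator %s> input (%s), %d residual blocks\n",
              x$preset, paste(x$input_shape, collapse = ", "),
              n_residual_blocks(x)))
  invisible(x)
}

#' Count residual blocks in a discriminator
#' @param net a `discriminator`.
#' @export
n_residual_blocks <- function(net) {
  sum(vapply(net$layers, function(l) l$type == "resblock", TRUE))
}

# tensors: array (2, H, W, n) -> activation matrix (2*H*W, n) in the
# engine's channel-fastest layout (layer index varies fastest)
.tensors_to_matrix <- function(tensors) {
  d <- dim(tensors)
  if (length(d) == 3L) dim(tensors) <- c(d, 1L)
  d <- dim(tensors)
  matrix(as.numeric(tensors), nrow = prod(d[1:3]), ncol = d[4])
}

#' Class probabilities for a batch of window tensors
#'
#' @param net a trained (or freshly built) `discriminator`.
#' @param tensors array (2, H, W, n), a single (2, H, W) tensor, or a
#'   pre-flattened activation matrix.
#' @param batch_size forward-pass chunk size.
#' @return an n x 4 matrix of softmax probabilities, columns in
#'   [SCENARIO_CLASSES] order; rows sum to 1.
#' @export
predict_discriminator <- function(net, tensors, batch_size = 64L) {
  stopifnot(inherits(net, "discriminator"))
  X <- if (is.matrix(tensors)) tensors else .tensors_to_matrix(tensors)
  if (nrow(X) != prod(net$input_shape)) {
    stop("tensor shape does not match network input shape (",
         paste(net$input_shape, collapse = ", "), ")")
  }
  n <- ncol(X)
  out <- matrix(0, nrow = n, ncol = 4L,
                dimnames = list(NULL, net$class_order))
  for (beg in seq(1L, n, by = batch_size)) {
    idx <- beg:min(beg + batch_size - 1L, n)
    logits <- nn_forward(net, X[, idx, drop = FALSE], training = FALSE)$logits
    out[idx, ] <- base::t(softmax_cols(logits))
  }
  out
}

#' Training configuration for the discriminator
#'
#' Defaults are the study's settings: Adam (learning rate 0.001, moment
#' coefficients 0.9/0.999), batch size 16, at most 100 epochs of 1,500 steps,
#' early stopping after 10 consecutive epochs without the validation loss
#' dropping below the best seen.
#'
#' @param lr,beta1,beta2 Adam settings.
#' @param batch_size minibatch size.
#' @param max_epochs,steps_per_epoch epoch budget.
#' @param patience consecutive non-improving epochs before early stop.
#' @param augment `"none"` (the study-scale default) or `"permute"`:
#'   scenario labels are invariant to reordering haplotype rows within a
#'   population layer, so desk-scale runs may permute each minibatch
#'   tensor's rows per layer to prevent memorization of small training sets.
#' @param seed training seed.
#' @return a `train_config`.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 16L, max_epochs = 100L,
                         steps_per_epoch = 1500L, patience = 10L,
                         augment = c("none", "permute"), seed = 1L) {
  augment <- match.arg(augment)
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, steps_per_epoch >= 1,
            patience >= 1, patience <= max_epochs)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 patience = as.integer(patience), augment = augment,
                 seed = seed),
            class = "train_config")
}

# per-sample random row permutation within each population layer of a
# flattened (2*H*W, n) batch; labels are invariant to this reordering
.augment_permute <- function(Xb, shape) {
  H <- shape[2]
  W <- shape[3]
  base <- array(seq_len(prod(shape)), dim = shape)
  for (j in seq_len(ncol(Xb))) {
    idx <- base
    idx[1L, , ] <- base[1L, sample.int(H), ]
    idx[2L, , ] <- base[2L, sample.int(H), ]
    Xb[, j] <- Xb[as.vector(idx), j]
  }
  Xb
}

#' Early-stopping bookkeeping
#'
#' "Improving" means strictly lower than the best validation loss so far
#' (best-weights checkpointing semantics). Exposed for testability.
#'
#' @param state NULL (fresh) or a previous state.
#' @param val_loss this epoch's validation loss.
#' @param patience allowed consecutive non-improving epochs.
#' @return list(best, since_best, improved, stop).
#' @export
early_stop_update <- function(state, val_loss, patience) {
  if (is.null(state)) state <- list(best = Inf, since_best = 0L)
  improved <- val_loss < state$best
  if (improved) {
    state$best <- val_loss
    state$since_best <- 0L
  } else {
    state$since_best <- state$since_best + 1L
  }
  state$improved <- improved
  state$stop <- state$since_best >= patience
  state
}

.collect_weights <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "resblock") {
      list(main = .collect_weights(l$main),
           shortcut = .collect_weights(l$shortcut))
    } else {
      list(params = l$params, state = l$state)
    }
  })
}

.restore_weights <- function(layers, w) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "resblock") {
      layers[[i]]$main <- .restore_weights(layers[[i]]$main, w[[i]]$main)
      layers[[i]]$shortcut <- .restore_weights(layers[[i]]$shortcut,
                                               w[[i]]$shortcut)
    } else {
      layers[[i]]$params <- w[[i]]$params
      if (!is.null(w[[i]]$state)) layers[[i]]$state <- w[[i]]$state
    }
  }
  layers
}

.xent_eval <- function(net, X, y_idx, batch_size = 64L) {
  n <- ncol(X)
  tot <- 0
  correct <- 0L
  for (beg in seq(1L, n, by = batch_size)) {
    idx <- beg:min(beg + batch_size - 1L, n)
    logits <- nn_forward(net, X[, idx, drop = FALSE], training = FALSE)$logits
    ls <- softmax_xent(logits, y_idx[idx])
    tot <- tot + ls$loss * length(idx)
    correct <- correct + sum(apply(logits, 2L, which.max) == y_idx[idx])
  }
  list(loss = tot / n, acc = correct / n)
}

#' Train the discriminator on a tensor store
#'
#' Each epoch draws `steps_per_epoch` minibatches by shuffling the training
#' pool and cycling through it (the step budget is fixed, not the number of
#' passes over the data). After each epoch the validation loss is computed
#' with running batch-norm statistics; the weights achieving the lowest
#' validation loss so far are recorded and returned on termination (early
#' stop after `patience` consecutive epochs without improvement, or at
#' `max_epochs`).
#'
#' @param store an opened `tensor_store` whose manifest carries a
#'   `validation` flag, or a list `list(tensors=, labels=, validation=)`.
#' @param config a [train_config()].
#' @param net optionally a pre-built `discriminator` (defaults to the desk
#'   preset for the store's shape).
#' @param verbose print per-epoch progress.
#' @return list with `net` (best weights), `history` (per-epoch train/val
#'   loss data.frame) and `best_epoch`.
#' @export
train_discriminator <- function(store, config = train_config(), net = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (inherits(store, "tensor_store")) {
    Xraw <- tensor_store_read_raw(store) # raw bytes until batched
    shape <- store$shape
    labels <- store$records$label
    validation <- store$records$validation
  } else {
    shape <- dim(store$tensors)[1:3]
    Xraw <- .tensors_to_matrix(store$tensors)
    labels <- store$labels
    validation <- store$validation
  }
  D <- prod(shape)
  get_cols <- function(idx) {
    matrix(as.numeric(Xraw[, idx, drop = FALSE]), nrow = D)
  }
  y_idx <- match(labels, SCENARIO_CLASSES)
  if (anyNA(y_idx)) stop("unknown labels in store")
  if (length(unique(y_idx[!validation])) < 4L) {
    stop("every scenario class must be present in the training split")
  }
  if (is.null(net)) {
    net <- build_network(shape, "desk",
                         seed = derive_seed(config$seed, "init"))
  }
  tr <- which(!validation)
  va <- which(validation)
  if (length(va) == 0L) stop("validation split is empty")
  Xva <- get_cols(va)
  yva <- y_idx[va]

  opt <- adam_init(net, lr = config$lr, beta1 = config$beta1,
                   beta2 = config$beta2)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  es <- NULL
  best_weights <- .collect_weights(net$layers)
  best_epoch <- 0L

  with_seed(derive_seed(config$seed, "train"), {
    queue <- sample(tr)
    for (ep in seq_len(config$max_epochs)) {
      ep_loss <- 0
      for (step in seq_len(config$steps_per_epoch)) {
        if (length(queue) < config$batch_size) {
          queue <- c(queue, sample(tr))
        }
        take <- queue[seq_len(config$batch_size)]
        queue <- queue[-seq_len(config$batch_size)]
        Xb <- get_cols(take)
        if (config$augment == "permute") Xb <- .augment_permute(Xb, shape)
        fw <- nn_forward(net, Xb, training = TRUE)
        net <- nn_commit_states(net, fw$states)
        ls <- softmax_xent(fw$logits, y_idx[take])
        grads <- nn_backward(net, fw$caches, ls$dlogits)
        st <- adam_step(net, grads, opt)
        net <- st$net
        opt <- st$opt
        ep_loss <- ep_loss + ls$loss
      }
      val <- .xent_eval(net, Xva, yva)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / config$steps_per_epoch,
        val_loss = val$loss, val_acc = val$acc))
      es <- early_stop_update(es, val$loss, config$patience)
      if (es$improved) {
        best_weights <- .collect_weights(net$layers)
        best_epoch <- ep
      }
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f acc %.3f%s", ep,
                        ep_loss / config$steps_per_epoch, val$loss, val$acc,
                        if (es$improved) " *" else ""))
      }
      if (es$stop) break
    }
  })
  net$layers <- .restore_weights(net$layers, best_weights)
  list(net = net, history = history, best_epoch = best_epoch)
}

#' Save a discriminator checkpoint
#'
#' The checkpoint stores the architecture configuration, class order, and all
#' weights/normalization statistics under a versioned schema; restoring it
#' reproduces bit-identical predictions.
#'
#' @param net a `discriminator`.
#' @param path output file.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "discriminator"))
  saveRDS(list(schema = 1L, preset = net$preset,
               input_shape = net$input_shape,
               class_order = net$class_order,
               weights = .collect_weights(net$layers)),
          path)
  invisible(path)
}

#' Load a discriminator checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `discriminator`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, 1L)) stop("unknown checkpoint schema")
  net <- build_network(ck$input_shape, ck$preset)
  if (!identical(ck$class_order, net$class_order)) {
    stop("checkpoint class order mismatch")
  }
  net$layers <- .restore_weights(net$layers, ck$weights)
  net
}

#' Training history as CSV
#' @param history data.frame from [train_discriminator()].
#' @param path output path.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
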