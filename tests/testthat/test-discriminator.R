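# Network construction, gradients, training behavior, checkpoints.

test_that("presets reproduce the expected residual structure", {
  desk <- build_network(c(2, 44, 128), "desk", seed = 1)
  expect_equal(n_residual_blocks(desk), 4L)
  paper <- build_network(c(2, 44, 128), "paper", seed = 1)
  expect_equal(n_residual_blocks(paper), 16L) # ResNet-34: (3, 4, 6, 3)
  last <- paper$layers[[length(paper$layers)]]
  expect_equal(last$out_shape[1], 4L) # 4-unit classification head
  expect_error(build_network(c(2, 0, 128), "desk"))
  # unpadded convolutions state their minimum spatial size
  expect_error(introscan:::layer_conv(c(2, 4, 4), 8L, 7L, 1L, pad = 0L),
               "too small")
})

test_that("forward pass yields valid, deterministic probabilities", {
  net <- build_network(c(2, 16, 128), "desk", seed = 3)
  zero <- array(0, dim = c(2, 16, 128, 3))
  p <- predict_discriminator(net, zero)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  x <- array(as.numeric(runif(2 * 16 * 128 * 5) < 0.3), c(2, 16, 128, 5))
  expect_identical(predict_discriminator(net, x),
                   predict_discriminator(net, x)) # inference determinism
  # permuting a batch permutes outputs identically
  perm <- c(3, 5, 1, 4, 2)
  expect_equal(predict_discriminator(net, x[, , , perm]),
               predict_discriminator(net, x)[perm, ], tolerance = 1e-12)
  expect_error(predict_discriminator(net, array(0, c(2, 9, 128, 1))),
               "shape")
})

test_that("analytic gradients match numerical differentiation", {
  shape <- c(2, 8, 12)
  net <- build_network(shape, "desk", seed = 5)
  set.seed(6)
  X <- matrix(rnorm(prod(shape) * 3), ncol = 3)
  y <- c(1L, 3L, 4L)
  fw <- introscan:::nn_forward(net, X, training = TRUE)
  ls <- introscan:::softmax_xent(fw$logits, y)
  gr <- introscan:::nn_backward(net, fw$caches, ls$dlogits)
  loss_at <- function(n2) {
    f <- introscan:::nn_forward(n2, X, training = TRUE)
    introscan:::softmax_xent(f$logits, y)$loss
  }
  paths <- introscan:::.param_paths(net$layers)
  eps <- 1e-5
  for (p in paths) {
    layer <- introscan:::.get_layer(net$layers, p)
    g <- introscan:::.get_grads(gr, p)
    for (nm in names(layer$params)) {
      i <- sample(length(layer$params[[nm]]), 1L)
      bump <- function(delta) {
        n2 <- net
        l2 <- introscan:::.get_layer(n2$layers, p)
        l2$params[[nm]][i] <- l2$params[[nm]][i] + delta
        n2$layers <- introscan:::.set_layer(n2$layers, p, l2)
        loss_at(n2)
      }
      num <- (bump(eps) - bump(-eps)) / (2 * eps)
      ana <- g[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training separates the constructed four-class fixture", {
  store <- make_separable_store(n_per = 40L, seed = 1)
  cfg <- train_config(batch_size = 16L, max_epochs = 5L,
                      steps_per_epoch = 30L, patience = 3L, seed = 2)
  net <- build_network(c(2, 16, 32), "desk", seed = 7)
  fit <- cached("separable_fit", train_discriminator(store, cfg, net = net))
  expect_true(all(diff(fit$history$epoch) == 1))
  # held-out fixture accuracy > 0.9
  set.seed(99)
  tl <- rep(1:4, 10)
  test_t <- array(0, dim = c(2, 16, 32, 40))
  for (i in 1:40) test_t[, , , i] <- store$make_ex(tl[i])
  p <- predict_discriminator(fit$net, test_t)
  expect_gt(mean(max.col(p) == tl), 0.9)
})

test_that("training is reproducible under a fixed seed", {
  store <- make_separable_store(n_per = 12L, seed = 3)
  cfg <- train_config(batch_size = 8L, max_epochs = 2L,
                      steps_per_epoch = 10L, patience = 2L, seed = 11)
  net <- build_network(c(2, 16, 32), "desk", seed = 4)
  f1 <- train_discriminator(store, cfg, net = net)
  f2 <- train_discriminator(store, cfg, net = net)
  expect_identical(f1$history, f2$history)
})

test_that("early stopping follows best-so-far patience semantics", {
  # strictly increasing validation loss from epoch 1 -> stop after
  # exactly 1 + patience epochs
  st <- NULL
  losses <- c(1.0, 1.1, 1.2, 1.3, 1.4)
  stops <- integer()
  for (ep in seq_along(losses)) {
    st <- early_stop_update(st, losses[ep], patience = 3L)
    if (st$stop) {
      stops <- ep
      break
    }
  }
  expect_equal(stops, 4L) # 1 improving epoch + 3 patience
  # non-strict improvement does not reset patience
  st <- NULL
  st <- early_stop_update(st, 1.0, 2L)
  st <- early_stop_update(st, 1.0, 2L) # equal, not an improvement
  expect_false(st$improved)
  st <- early_stop_update(st, 1.0, 2L)
  expect_true(st$stop)
  # a strict improvement resets the counter and records the best
  st <- NULL
  st <- early_stop_update(st, 1.0, 2L)
  st <- early_stop_update(st, 1.2, 2L)
  st <- early_stop_update(st, 0.9, 2L)
  expect_true(st$improved)
  expect_equal(st$best, 0.9)
  expect_equal(st$since_best, 0L)
})

test_that("label-shuffled training stays at four-class chance", {
  store <- make_separable_store(n_per = 30L, seed = 5, shuffle_labels = TRUE)
  cfg <- train_config(batch_size = 16L, max_epochs = 3L,
                      steps_per_epoch = 20L, patience = 3L, seed = 6)
  net <- build_network(c(2, 16, 32), "desk", seed = 8)
  fit <- cached("shuffled_fit", train_discriminator(store, cfg, net = net))
  # validation accuracy indistinguishable from 0.25: binomial 3-sigma band
  n_val <- sum(store$validation)
  acc <- tail(fit$history$val_acc, 1)
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / n_val) + 1e-9)
})

test_that("checkpoints restore bit-identical predictions", {
  store <- make_separable_store(n_per = 10L, seed = 9)
  cfg <- train_config(batch_size = 8L, max_epochs = 1L,
                      steps_per_epoch = 8L, patience = 1L, seed = 12)
  fit <- train_discriminator(store, cfg,
                             net = build_network(c(2, 16, 32), "desk", 13))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$net, path)
  net2 <- load_checkpoint(path)
  x <- store$tensors[, , , 1:7]
  expect_identical(predict_discriminator(fit$net, x),
                   predict_discriminator(net2, x))
})

test_that("degenerate training inputs error out", {
  store <- make_separable_store(n_per = 6L, seed = 10)
  keep <- store$labels != "BiDir" | store$validation
  st2 <- list(tensors = store$tensors[, , , keep, drop = FALSE],
              labels = store$labels[keep],
              validation = store$validation[keep])
  expect_error(train_discriminator(st2, train_config(max_epochs = 1, patience = 1,
                                                     steps_per_epoch = 1)),
               "every scenario class")
})
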