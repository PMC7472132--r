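# Network construction, shape propagation, parameter accounting, the
# training loop, and prediction semantics.

test_that("default architecture has 16 blocks with a bare final convolution", {
  m <- build_rced(rced_config(), seed = 1)
  expect_length(m$blocks, 16)
  expect_true(all(vapply(m$blocks[1:15], `[[`, TRUE, "has_bn")))
  expect_false(m$blocks[[16]]$has_bn)
  expect_equal(m$blocks[[16]]$c_out, 1)

  # forward pass on one random stack: finite 129-vector
  st <- array(rnorm(129 * 8), dim = c(1, 129, 8))
  out <- predict(m, st)
  expect_equal(dim(out), c(1, 129))
  expect_true(all(is.finite(out)))
})

test_that("parameter count matches the closed-form schedule sum", {
  cfg <- rced_config()
  counts <- cfg$filter_counts; widths <- cfg$kernel_widths
  c_in <- 8L; expected <- 0L
  for (i in seq_along(counts)) {
    expected <- expected + c_in * counts[i] * widths[i] + counts[i]
    if (i < length(counts)) expected <- expected + 2L * counts[i]
    c_in <- counts[i]
  }
  expect_identical(n_params(cfg), expected)
  expect_identical(n_params(build_rced(cfg, seed = 2)), expected)
})

test_that("configuration invariants are enforced", {
  expect_error(rced_config(filter_counts = c(4, 2),
                           kernel_widths = c(3, 3)), "1 output channel")
  expect_error(rced_config(filter_counts = c(4, 1), kernel_widths = 3),
               "same length")
  expect_error(rced_config(filter_counts = c(4, 1), kernel_widths = c(4, 3)),
               "odd")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(lr_decay_per_epoch = 0), "lr_decay")
})

test_that("learning-rate schedule decays by 0.95 per epoch", {
  tc <- train_config(lr0 = 0.01)
  expect_equal(rcedecg:::lr_at_epoch(tc, 1), 0.01)
  expect_equal(rcedecg:::lr_at_epoch(tc, 12), 0.01 * 0.95^11)
})

small_cfg <- function() {
  rced_config(filter_counts = c(6, 8, 6, 1), kernel_widths = c(9, 7, 7, 9),
              n_bins = 129, context_k = 8)
}

make_identity_task <- function(n = 240, seed = 5) {
  # targets equal the context's final frame: learnable to near-zero loss
  set.seed(seed)
  stacks <- array(rnorm(n * 129 * 8), dim = c(n, 129, 8))
  list(stacks = stacks, targets = stacks[, , 8])
}

test_that("training learns the identity task and records its history", {
  task <- make_identity_task()
  tc <- train_config(lr0 = 0.1, batch_size = 64, epochs = 12, seed = 3)
  m <- train_rced(build_rced(small_cfg(), seed = 3), task$stacks,
                  task$targets, tc)
  expect_length(m$history, 12)
  expect_lt(m$history[12], 0.05 * m$history[1])
})

test_that("training is deterministic and validates its inputs", {
  task <- make_identity_task(n = 64, seed = 8)
  tc <- train_config(batch_size = 32, epochs = 2, seed = 11)
  m1 <- train_rced(build_rced(small_cfg(), seed = 11), task$stacks,
                   task$targets, tc)
  m2 <- train_rced(build_rced(small_cfg(), seed = 11), task$stacks,
                   task$targets, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$blocks, m2$blocks)

  expect_error(train_rced(build_rced(small_cfg()), task$stacks,
                          task$targets[1:10, ], tc), "not aligned")
  expect_error(train_rced(build_rced(small_cfg()),
                          array(0, dim = c(0, 129, 8)),
                          task$targets[0, , drop = FALSE], tc), "empty")
})

test_that("prediction is deterministic, shape-checked, order-preserving", {
  task <- make_identity_task(n = 32, seed = 2)
  tc <- train_config(batch_size = 32, epochs = 1, seed = 1)
  m <- train_rced(build_rced(small_cfg(), seed = 1), task$stacks,
                  task$targets, tc)
  p1 <- predict(m, task$stacks)
  p2 <- predict(m, task$stacks)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(32, 129))
  # batch prediction equals row-by-row prediction (order preserved)
  p_single <- t(vapply(1:4, function(i) {
    as.numeric(predict(m, task$stacks[i, , , drop = FALSE]))
  }, numeric(129)))
  expect_equal(p1[1:4, ], p_single, tolerance = 1e-12)
})

test_that("gradients agree with finite differences on a tiny network", {
  cfg <- rced_config(filter_counts = c(3, 1), kernel_widths = c(3, 3),
                     n_bins = 7, context_k = 2)
  m <- build_rced(cfg, seed = 6)
  set.seed(6)
  X <- array(rnorm(2 * 7 * 4), dim = c(2, 7, 4))     # (channels, bins, batch)
  Tm <- matrix(rnorm(7 * 4), nrow = 7)
  loss_of <- function(model) {
    fw <- rcedecg:::rced_forward(model, X, training = TRUE)
    Y <- fw$out; dim(Y) <- dim(Tm)
    mean((Y - Tm)^2)
  }
  fw <- rcedecg:::rced_forward(m, X, training = TRUE)
  Y <- fw$out; dim(Y) <- dim(Tm)
  dY <- 2 * (Y - Tm) / length(Tm)
  dim(dY) <- c(1, 7, 4)
  grads <- rcedecg:::rced_backward(m, dY, fw$caches)
  eps <- 1e-6
  for (bi in 1:2) {
    for (pi in seq_len(min(5, length(m$blocks[[bi]]$W)))) {
      mp <- m; mp$blocks[[bi]]$W[pi] <- mp$blocks[[bi]]$W[pi] + eps
      mm <- m; mm$blocks[[bi]]$W[pi] <- mm$blocks[[bi]]$W[pi] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grads[[bi]]$dW[pi], num, tolerance = 1e-4)
    }
  }
})
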