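test_that("dilated causal convolution matches hand and scalar oracles", {
  # identity configuration passes non-negative input through
  x <- matrix(c(0.5, 1, 0, 2), 4, 1)
  out <- dilated_causal_conv(x, w1 = matrix(0), w2 = matrix(1), b = 0)
  expect_equal(out, x, ignore_attr = TRUE)

  # hand evaluation with zero-padded start: [1,2,3] -> [1,3,5]
  out2 <- dilated_causal_conv(matrix(1:3), w1 = matrix(1), w2 = matrix(1), b = 0)
  expect_equal(as.numeric(out2), c(1, 3, 5))

  set.seed(33)
  for (case in 1:100) {
    T_ <- sample(3:7, 1); C <- sample(1:3, 1); Fn <- sample(1:4, 1)
    s <- sample(1:3, 1)
    x <- matrix(rnorm(T_ * C), T_, C)
    w1 <- matrix(rnorm(C * Fn), C, Fn); w2 <- matrix(rnorm(C * Fn), C, Fn)
    b <- rnorm(Fn)
    got <- dilated_causal_conv(x, w1, w2, b, dilation = s)
    expect_equal(got, oracle_dilated_conv(x, w1, w2, b, s), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("convolution and residual block are causal", {
  set.seed(12)
  T_ <- 10; C <- 3
  x <- matrix(rnorm(T_ * C), T_, C)
  w1 <- matrix(rnorm(C * 2), C, 2); w2 <- matrix(rnorm(C * 2), C, 2)
  for (s in 1:3) {
    base <- dilated_causal_conv(x, w1, w2, c(0.1, -0.2), dilation = s,
                                activation = "identity")
    for (t in c(3, 6, 9)) {
      xp <- x
      xp[(t + 1):T_, ] <- xp[(t + 1):T_, ] + rnorm((T_ - t) * C, sd = 5)
      pert <- dilated_causal_conv(xp, w1, w2, c(0.1, -0.2), dilation = s,
                                  activation = "identity")
      expect_identical(base[1:t, ], pert[1:t, ])
      if (t < T_) expect_false(identical(base[t + 1, ], pert[t + 1, ]))
    }
  }
  blk <- tcn_block_params(C, 4)
  base_b <- residual_block(x, blk)
  for (t in c(4, 7)) {
    xp <- x
    xp[(t + 1):T_, ] <- 10 * xp[(t + 1):T_, ] + 1
    expect_identical(residual_block(xp, blk)[1:t, ], base_b[1:t, ])
  }
})

test_that("residual block: pure skip path, channel projection and eval determinism", {
  # zero dilated weights + identity skip reproduce the input
  C <- 3
  blk <- tcn_block_params(C, C, weight_norm = FALSE)
  blk$layers <- lapply(blk$layers, function(l) rapply(l, function(x) x * 0, how = "replace"))
  blk$skip$W <- diag(C); blk$skip$b[] <- 0
  x <- matrix(rnorm(15), 5, C)
  expect_equal(residual_block(x, blk), x, ignore_attr = TRUE)

  # channel adjustment: output width is the filter count, whatever C is
  set.seed(5)
  blk2 <- tcn_block_params(200, 250)
  h <- matrix(rnorm(7 * 200, sd = 0.1), 7, 200)
  out <- residual_block(h, blk2)
  expect_identical(dim(out), c(7L, 250L))

  # evaluation mode is deterministic; training mode draws dropout
  blk3 <- tcn_block_params(3, 4)
  x3 <- matrix(rnorm(21), 7, 3)
  expect_identical(residual_block(x3, blk3), residual_block(x3, blk3))
  set.seed(1); a <- residual_block(x3, blk3, training = TRUE, dropout_rate = 0.5)
  set.seed(2); b <- residual_block(x3, blk3, training = TRUE, dropout_rate = 0.5)
  expect_false(identical(a, b))
})

test_that("one block with kernel 2 and dilation 1 per layer sees exactly 4 steps back", {
  set.seed(9)
  C <- 2; Fn <- 3; T_ <- 12
  blk <- tcn_block_params(C, Fn, weight_norm = FALSE)
  # positive weights + positive input keep every ReLU active, so
  # sensitivity cannot vanish by a dead unit
  blk$layers <- lapply(blk$layers, function(l) {
    l$w1 <- abs(l$w1); l$w2 <- abs(l$w2); l$b <- abs(l$b)
    l
  })
  blk$skip$W[] <- 0  # isolate the convolutional path
  x <- matrix(runif(T_ * C) + 0.5, T_, C)
  base <- residual_block(x, blk)
  t0 <- 8L
  bump <- function(lag) {
    xp <- x
    xp[t0 - lag, ] <- xp[t0 - lag, ] + 1
    residual_block(xp, blk)
  }
  expect_false(isTRUE(all.equal(bump(3)[t0, ], base[t0, ])))
  expect_equal(bump(4)[t0, ], base[t0, ], tolerance = 1e-12)
})

test_that("weight-normalised parameterisation reproduces plain kernels at init", {
  set.seed(77)
  p <- conv_layer_params(3, 4, weight_norm = TRUE)
  eff <- yieldnet:::effective_weights(p)
  # g is initialised to ||v||, so effective weights equal the raw draw
  expect_equal(eff$W1, p$v1, tolerance = 1e-12)
  expect_equal(eff$W2, p$v2, tolerance = 1e-12)
  # rescaling v leaves the effective kernel invariant (direction only)
  p2 <- p; p2$v1 <- p$v1 * 3; p2$v2 <- p$v2 * 3
  eff2 <- yieldnet:::effective_weights(p2)
  expect_equal(eff2$W1, eff$W1, tolerance = 1e-12)
})
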