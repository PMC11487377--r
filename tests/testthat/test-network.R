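test_that("backbone emits the contracted 5-D shape and per-sample independence", {
  set.seed(1)
  withSubstream(1, "bb", bb <- initBackbone("small_cnn", 32L))
  x <- array(rnorm(2 * 8 * 64 * 64), c(2, 8, 64, 64))
  f <- backboneForward(x, bb)
  d <- dim(f)
  expect_equal(d[1:3], c(2, 8, 32))
  expect_true(d[4] > 1 && d[5] > 1)
  expect_equal(d[4], d[5])

  # permuting the batch permutes outputs identically
  xp <- x[c(2, 1), , , , drop = FALSE]
  fp <- backboneForward(xp, bb)
  expect_equal(fp[1, , , , ], f[2, , , , ], tolerance = 1e-12)
  expect_equal(fp[2, , , , ], f[1, , , , ], tolerance = 1e-12)

  # slice-permutation equivariance: the stack is per-slice
  perm <- c(3, 1, 4, 2, 8, 5, 7, 6)
  fl <- backboneForward(x[, perm, , , drop = FALSE], bb)
  expect_equal(fl, f[, perm, , , , drop = FALSE], tolerance = 1e-12)

  expect_error(backboneForward(array(0, c(1, 2, 4, 4)), bb), "receptive")
  expect_error(initBackbone("small_cnn", 4L), ">= 8")
})

test_that("the AlexNet-like backbone reproduces the classic feature geometry", {
  set.seed(2)
  bb <- initBackbone("mrnet_alexnet_like")
  x <- array(rnorm(1 * 2 * 224 * 224), c(1, 2, 224, 224))
  f <- backboneForward(x, bb)
  expect_equal(dim(f), c(1, 2, 256, 6, 6))
})

test_that("the head is a softmax over max-pooled slice descriptors", {
  set.seed(3)
  hd <- initHead(8L)
  f <- array(rnorm(3 * 5 * 8 * 2 * 2), c(3, 5, 8, 2, 2))
  p <- headForward(f, hd)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p > 0))

  # duplicating every slice leaves the max over slices unchanged
  fdup <- f[, rep(1:5, each = 2), , , , drop = FALSE]
  expect_equal(headForward(fdup, hd), p, tolerance = 1e-12)

  hd0 <- initHead(8L)
  hd0$W$value[] <- 0; hd0$b$value[] <- 0
  p0 <- headForward(array(0, c(2, 3, 8, 2, 2)), hd0)
  expect_equal(p0, matrix(0.5, 2, 2))
})

test_that("weighted and focal losses evaluate their defining formulas", {
  lp <- lossParams(alpha = 0.5, gamma = 2)
  expect_equal(weightedLoss(0.5, 1, lp), 0.5 * log(2), tolerance = 1e-12)
  expect_equal(weightedLoss(1, 1, lp), 0, tolerance = 1e-9)
  expect_equal(weightedLoss(0.2, 0, lossParams(alpha = 0.25)),
               0.75 * (-log(0.8)), tolerance = 1e-12)

  expect_equal(focalLoss(0.9, 1, lossParams(alpha = 0.25, gamma = 2)),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-9)
  expect_equal(0.25 * 0.1^2 * (-log(0.9)), 2.634e-4, tolerance = 1e-3)
  expect_equal(focalLoss(1, 1, lossParams()), 0, tolerance = 1e-9)

  # gamma = 0 collapses the focal loss onto the weighted loss
  set.seed(4)
  for (i in 1:100) {
    p <- runif(1); y <- rbinom(1, 1, 0.5); a <- runif(1, 0.05, 0.95)
    lp0 <- lossParams(alpha = a, gamma = 0)
    expect_equal(focalLoss(p, y, lp0), weightedLoss(p, y, lp0),
                 tolerance = 1e-12)
    expect_equal(totalLoss(p, y, lp0), 2 * weightedLoss(p, y, lp0),
                 tolerance = 1e-12)
    lpg <- lossParams(alpha = a, gamma = runif(1, 0, 4))
    expect_equal(totalLoss(p, y, lpg),
                 weightedLoss(p, y, lpg) + focalLoss(p, y, lpg),
                 tolerance = 1e-12)
  }

  # both components are strictly decreasing in p_t on (0, 1)
  pts <- seq(0.02, 0.98, by = 0.02)
  for (lpx in list(lossParams(0.3, 0), lossParams(0.5, 2), lossParams(0.8, 1))) {
    wl <- weightedLoss(pts, rep(1, length(pts)), lpx)
    fl <- focalLoss(pts, rep(1, length(pts)), lpx)
    expect_true(all(diff(wl) < 0))
    expect_true(all(diff(wl + fl) < 0))
  }
})

test_that("one optimizer step on a single-sample batch reduces the total loss", {
  ns <- asNamespace("sgknee")
  set.seed(5)
  model <- initModel("small_cnn", 8L, sgEnabled = TRUE, groupSizes = c(1L, 2L),
                     seed = 3, view = "axial")
  params <- ns$.collect_params(model)
  opt <- ns$.adam_new(params, lr = 1e-3)
  x <- array(rnorm(1 * 4 * 16 * 16), c(1, 4, 16, 16))
  loss_at <- function() {
    ns$.td_loss_total(ns$.td_model_forward(x, model), 1, 0.7, 2)$value
  }
  l0 <- loss_at()
  ns$.td_zero_grads(params)
  node <- ns$.td_loss_total(ns$.td_model_forward(x, model), 1, 0.7, 2)
  ns$.td_backward(node)
  ns$.adam_step(opt)
  expect_lt(loss_at(), l0)
})

test_that("checkpoints restore a model that scores identically", {
  tmp <- withr::local_tempdir()
  set.seed(6)
  model <- initModel("small_cnn", 8L, sgEnabled = FALSE, seed = 2,
                     view = "axial")
  x <- array(rnorm(2 * 4 * 16 * 16), c(2, 4, 16, 16))
  p1 <- predictModel(x, model)
  cfg <- defaultConfig()
  cfg$model$out_channels <- 8L
  cfg$sg$enabled <- FALSE
  saveCheckpoint(model, cfg, normStats(0, 1), file.path(tmp, "ck.rds"))
  ck <- loadCheckpoint(file.path(tmp, "ck.rds"))
  expect_equal(predictModel(x, ck$model), p1, tolerance = 1e-12)
})
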