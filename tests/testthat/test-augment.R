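test_that("random crop shares one window across slices and enforces bounds", {
  set.seed(1)
  vol <- rand_volume(L = 3, H = 256, W = 256)
  out <- randomCrop(vol, 224)
  expect_equal(dim(volumeData(out)), c(3, 224, 224))
  # every slice must be the same contiguous subwindow of its source slice
  x <- volumeData(vol); y <- volumeData(out)
  found <- FALSE
  for (oh in 0:32) {
    hit <- which(sapply(0:32, function(ow)
      identical(y[1, , ], x[1, oh + 1:224, ow + 1:224])))
    if (length(hit) > 0) {
      ow <- hit[1] - 1
      found <- all(sapply(1:3, function(l)
        identical(y[l, , ], x[l, oh + 1:224, ow + 1:224])))
      break
    }
  }
  expect_true(found)

  small <- rand_volume(L = 2, H = 8, W = 8)
  expect_identical(volumeData(randomCrop(small, 8)), volumeData(small))
  expect_error(randomCrop(small, 9), "exceeds")
})

test_that("normalization follows (p - m)/std and its affine equivariance", {
  v <- examVolume(array(c(2, 4), c(1, 1, 2)))
  out <- normalizeVolume(v, normStats(3, 1))
  expect_equal(as.vector(volumeData(out)), c(-1, 1))

  set.seed(2)
  x <- rand_volume(L = 4, H = 10, W = 10)
  st <- computeNormStats(list(x))
  z <- volumeData(normalizeVolume(x, st))
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sd(as.vector(z)), 1, tolerance = 1e-6)

  expect_error(normStats(0, 0))  # zero spread is rejected at construction

  # scaling/shifting the data with matching stats leaves the output unchanged
  a <- 2.5; b <- -1.2
  xs <- examVolume(a * volumeData(x) + b)
  sts <- normStats(a * st@m + b, a * st@std)
  expect_equal(volumeData(normalizeVolume(xs, sts)),
               volumeData(normalizeVolume(x, st)), tolerance = 1e-12)
})

test_that("spatial erasing zeroes exactly the side-convention block per slice", {
  set.seed(3)
  ones <- examVolume(array(1, c(5, 224, 224)))
  out <- volumeData(spatialErase(ones, 0.5))
  for (l in 1:5) expect_equal(sum(out[l, , ] == 0), 112^2)  # 25% of pixels

  expect_identical(volumeData(spatialErase(ones, 0)), volumeData(ones))
  all0 <- volumeData(spatialErase(ones, 1))
  expect_true(all(all0 == 0))

  # area convention: ratio becomes the erased area fraction
  outa <- volumeData(spatialErase(ones, 0.25, blockMode = "area"))
  expect_equal(sum(outa[1, , ] == 0), round(sqrt(0.25) * 224)^2)
})

test_that("erase blocks always lie fully inside bounds over many draws", {
  set.seed(4)
  for (i in 1:1000) {
    r <- runif(1)
    side <- sample(10:30, 1)
    v <- array(1, c(1, side, side))
    out <- spatialErase(v, r)
    s <- sgknee:::.block_side(side, r, "side")
    expect_equal(sum(out == 0), s^2)  # clipping would leave fewer zeros
  }
})

test_that("spatial mixup is the exact lambda-convex combination with an in-view donor", {
  set.seed(5)
  vol <- rand_volume(L = 4, H = 32, W = 32)
  x0 <- volumeData(vol)

  out1 <- spatialMixup(vol, 0.5, lambda = 1)
  expect_equal(volumeData(out1), x0, tolerance = 1e-12)

  out0 <- spatialMixup(vol, 0.5, lambda = 0)
  det <- attr(out0, "mixupDetails")
  for (l in 1:4) {
    d <- det[[l]]
    expect_true(d$donor != l)
    s <- 16
    blk <- volumeData(out0)[l, d$offset[1] + 1:s, d$offset[2] + 1:s]
    donor_blk <- x0[d$donor, d$donorOffset[1] + 1:s, d$donorOffset[2] + 1:s]
    expect_equal(blk, donor_blk, tolerance = 1e-12)
  }

  outl <- spatialMixup(vol, 0.5)
  detl <- attr(outl, "mixupDetails")
  for (l in 1:4) {
    d <- detl[[l]]; s <- 16
    blk_sum <- sum(volumeData(outl)[l, d$offset[1] + 1:s, d$offset[2] + 1:s])
    self_sum <- sum(x0[l, d$offset[1] + 1:s, d$offset[2] + 1:s])
    donor_sum <- sum(x0[d$donor, d$donorOffset[1] + 1:s, d$donorOffset[2] + 1:s])
    expect_equal(blk_sum, d$lambda * self_sum + (1 - d$lambda) * donor_sum,
                 tolerance = 1e-6)
  }

  expect_error(spatialMixup(rand_volume(L = 1), 0.5), "donor")
})

test_that("layer-scale operations touch exactly round(L * ratio) slices", {
  set.seed(6)
  vol <- examVolume(array(1, c(20, 16, 16)))
  out <- volumeData(layerScaleApply(vol, "erase", 0.25))
  zero_layers <- sum(apply(out, 1, function(m) all(m == 0)))
  expect_equal(zero_layers, 5)
  expect_equal(sum(apply(out, 1, function(m) all(m == 1))), 15)

  expect_identical(volumeData(layerScaleApply(vol, "erase", 0)),
                   volumeData(vol))

  donors <- rand_views(L = 8, H = 12, W = 12)
  outm <- layerScaleApply(vol, "mixup", 0.25, donorViews = donors, lambda = 0)
  det <- attr(outm, "layerDetails")
  expect_length(det$selected, 5)
  for (d in det$draws) {
    donor <- volumeData(donors[[d$donorView]])[d$donorLayer, , ]
    resized <- sgknee:::.resize_nn(donor, 16, 16)
    expect_equal(volumeData(outm)[d$layer, , ], resized, tolerance = 1e-12)
  }
  expect_error(layerScaleApply(vol, "mixup", 0.25), "donor views")
})

test_that("the pipeline composes crop/normalize/augment deterministically", {
  views <- rand_views(L = 6, H = 32, W = 32)
  st <- computeNormStats(views)
  off <- augmentConfig(cropSize = 28L, pErase = 0, pMixup = 0)
  a <- augmentPipeline(views, off, st, seed = 9)
  # with both ops off, the pipeline is exactly crop + normalize
  for (v in names(a)) {
    expect_equal(dim(volumeData(a[[v]]))[2:3], c(28, 28))
    expect_equal(sd(as.vector(volumeData(a[[v]]))), 1, tolerance = 0.35)
  }
  b <- augmentPipeline(views, off, st, seed = 9)
  for (v in names(a)) expect_identical(volumeData(a[[v]]), volumeData(b[[v]]))

  on <- augmentConfig(cropSize = 28L, pErase = 1, pMixup = 0, pLayerScale = 0,
                      eraseRatio = 0.5)
  set.seed(8)
  fr <- unlist(replicate(100, {
    out <- augmentPipeline(views, on, st, seed = sample.int(1e6, 1))
    z <- apply(volumeData(out$axial), 1, function(m) mean(m == 0))
    z[z > 0]                                    # zero fraction of touched layers
  }, simplify = FALSE))
  expect_equal(mean(fr), 0.25, tolerance = 0.01)
})
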