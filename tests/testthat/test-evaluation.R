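test_that("confusion metrics satisfy their defining identities", {
  # counts implied by a 54/66 validation split with the reported per-class
  # recalls: 50/54 and 61/66
  y <- c(rep(1, 54), rep(0, 66))
  pred <- c(rep(1, 50), rep(0, 4), rep(0, 61), rep(1, 5))
  m <- confusionMetrics(y, pred)
  expect_equal(m@TP, 50L); expect_equal(m@FN, 4L)
  expect_equal(m@TN, 61L); expect_equal(m@FP, 5L)
  expect_equal(m@sensitivity, 0.9259, tolerance = 1e-4)
  expect_equal(m@specificity, 0.9242, tolerance = 1e-4)
  expect_equal(m@accuracy, 0.9250, tolerance = 1e-12)

  perfect <- confusionMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect@accuracy, perfect@sensitivity, perfect@specificity),
               c(1, 1, 1))

  expect_error(confusionMetrics(c(1, 1), c(1, 0)), "specificity")
  expect_error(confusionMetrics(c(0, 0), c(1, 0)), "sensitivity")

  # accuracy = (sen * P + spe * N) / (P + N) identically
  set.seed(20)
  for (i in 1:20) {
    yy <- c(rep(1, sample(3:10, 1)), rep(0, sample(3:10, 1)))
    pp <- rbinom(length(yy), 1, 0.5)
    mm <- confusionMetrics(yy, pp)
    P <- sum(yy == 1); N <- sum(yy == 0)
    expect_equal(mm@accuracy,
                 (mm@sensitivity * P + mm@specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("rank-based AUC equals the exhaustive pair statistic", {
  expect_equal(aucScore(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(aucScore(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(aucScore(c(1, 1), c(0.5, 0.6)), "single-class")

  set.seed(21)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # plenty of ties
    expect_equal(aucScore(y, s), oracle_auc(y, s), tolerance = 1e-12)
  }
})

test_that("ROC curve points are consistent with the AUC", {
  set.seed(22)
  y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
  s <- runif(40)
  roc <- rocCurve(y, s)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, aucScore(y, s), tolerance = 1e-12)
})

test_that("stratified folds are exact, disjoint, covering and deterministic", {
  labels <- c(rep(1L, 20), rep(0L, 80))
  m <- datasetManifest(data.frame(
    exam_id = sprintf("e%03d", 1:100), label = labels,
    axial = "", coronal = "", sagittal = ""))
  plan <- makeFolds(m, k = 5, seed = 3)
  all_valid <- unlist(lapply(plan, `[[`, "valid"))
  expect_setequal(all_valid, sprintf("e%03d", 1:100))
  expect_equal(anyDuplicated(all_valid), 0)
  lab <- setNames(labels, sprintf("e%03d", 1:100))
  for (f in plan) {
    expect_equal(sum(lab[f$valid]), 4)           # exactly 20/5 positives
    expect_length(intersect(f$valid, c(f$train, f$tune)), 0)
    expect_length(intersect(f$train, f$tune), 0)
    expect_setequal(c(f$valid, f$train, f$tune), sprintf("e%03d", 1:100))
    # tune is a stratified fifth of the non-validation portion
    expect_equal(length(f$tune), 16)
    expect_equal(sum(lab[f$tune]), 3)            # round(0.2 * 16)
  }
  plan2 <- makeFolds(m, k = 5, seed = 3)
  expect_identical(plan, plan2)
  expect_false(identical(plan, makeFolds(m, k = 5, seed = 4)))

  tiny <- datasetManifest(data.frame(
    exam_id = sprintf("t%d", 1:6), label = c(1L, 1L, 1L, 0L, 0L, 0L),
    axial = "", coronal = "", sagittal = ""))
  expect_error(makeFolds(tiny, k = 5), "fewer members")
})

test_that("fold stratification stays within one case of the global fraction", {
  set.seed(23)
  labels <- as.integer(runif(137) < 0.3)
  while (sum(labels) < 5) labels[sample(137, 1)] <- 1L
  m <- datasetManifest(data.frame(
    exam_id = sprintf("x%03d", 1:137), label = labels,
    axial = "", coronal = "", sagittal = ""))
  plan <- makeFolds(m, k = 5, seed = 9)
  lab <- setNames(labels, sprintf("x%03d", 1:137))
  gf <- mean(labels)
  for (f in plan) {
    nf <- length(f$valid)
    expect_lte(abs(sum(lab[f$valid]) - gf * nf), 1)
  }
})

test_that("the ablation grid emits the 10-row module table", {
  tmp <- withr::local_tempdir()
  pp <- phantomParams(spatialSize = 24L, layerRange = c(4L, 6L),
                      posFraction = 0.3, noiseSd = 0.05)
  manifest <- generateDataset(40, pp, tmp, seed = 7)
  cfg <- defaultConfig()
  cfg$augment$crop_size <- 20L
  cfg$model$out_channels <- 8L
  cfg$sg$group_sizes <- c(1L, 2L)
  cfg$optim$epochs <- 1L
  cfg$optim$lr <- 1e-3
  res <- runAblation(manifest, cfg, seed = 7)
  tab <- res$table
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$fusion), 1)
  expect_equal(tab$view[nrow(tab)], "all")
  expect_equal(sort(unique(tab$view[!tab$fusion])),
               c("axial", "coronal", "sagittal"))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
  expect_true(all(c("axial", "coronal", "sagittal", "fused") %in%
                  names(res$roc)))

  # toggle wiring: the Base rows carry dda = sg = FALSE
  base_rows <- tab[!tab$dda & !tab$sg, ]
  expect_equal(nrow(base_rows), 3)

  res2 <- runAblation(manifest, cfg, seed = 7)
  expect_equal(res2$table, tab, tolerance = 1e-12)
})
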