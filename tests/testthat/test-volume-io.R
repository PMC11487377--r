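test_that("volume files round-trip exactly", {
  tmp <- withr::local_tempdir()
  ramp <- array(as.double(seq_len(3 * 4 * 4)), c(3, 4, 4))
  p <- file.path(tmp, "ramp.npy")
  writeVolume(examVolume(ramp, "axial", "r"), p)
  back <- readVolume(p, view = "axial")
  expect_identical(volumeData(back), ramp)
  expect_equal(nLayers(back), 3)

  # integer-valued uint8 payload round-trips bit-exactly
  u8 <- array(as.double(sample(0:255, 2 * 5 * 5, replace = TRUE)), c(2, 5, 5))
  p2 <- file.path(tmp, "u8.npy")
  writeVolume(u8, p2, dtype = "uint8")
  expect_identical(volumeData(readVolume(p2)), u8)

  # float32 round-trips within single precision
  p3 <- file.path(tmp, "f4.npy")
  x <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  writeVolume(x, p3, dtype = "float")
  expect_equal(volumeData(readVolume(p3)), x, tolerance = 1e-6)
})

test_that("npy layout is C-order and interoperable with numpy semantics", {
  # the (l, h, w) element written must be stored with w varying fastest
  tmp <- withr::local_tempfile(fileext = ".npy")
  x <- array(0, c(2, 3, 4)); x[2, 1, 3] <- 7
  writeVolume(x, tmp)
  con <- file(tmp, "rb")
  on.exit(close(con))
  readBin(con, "raw", 8)
  hlen <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  readBin(con, "raw", hlen)
  vals <- readBin(con, "double", 24, endian = "little")
  # C-order flat index of (2,1,3) in shape (2,3,4): (2-1)*12 + (1-1)*4 + (3-1)
  expect_equal(which(vals == 7) - 1, 14)
})

test_that("reader enforces the 3-D contract and dialect shape", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "flat.npy")
  sgknee:::.write_npy(matrix(1:6, 2), p)
  expect_error(readVolume(p), "3-D")
  expect_error(readVolume(file.path(tmp, "missing.npy")), "not found")

  stack <- array(0, c(20, 256, 256))
  p2 <- file.path(tmp, "stack.npy")
  writeVolume(stack, p2, dtype = "uint8")
  v <- readVolume(p2, view = "coronal")
  expect_equal(dim(volumeData(v)), c(20, 256, 256))
  expect_equal(examView(v), "coronal")
})

test_that("manifests parse, validate and preserve order", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "manifest.csv")
  df <- data.frame(exam_id = c("b", "a"), label = c(1L, 0L),
                   axial = "x.npy", coronal = "y.npy", sagittal = "z.npy")
  write.csv(df, p, row.names = FALSE)
  m <- readManifest(p)
  expect_s4_class(m, "DatasetManifest")
  expect_equal(length(m), 2)
  expect_equal(manifestRecords(m)$exam_id, c("b", "a"))  # file order kept

  df_dup <- df; df_dup$exam_id <- c("a", "a")
  write.csv(df_dup, p, row.names = FALSE)
  expect_error(readManifest(p), "duplicate")

  df_bad <- df; df_bad$label <- c(2L, 0L)
  write.csv(df_bad, p, row.names = FALSE)
  expect_error(readManifest(p), "0 or 1")
})

test_that("class prevalence matches the counting definition and is order-invariant", {
  mk <- function(labels) datasetManifest(data.frame(
    exam_id = sprintf("e%d", seq_along(labels)), label = labels,
    axial = "", coronal = "", sagittal = ""))
  m <- mk(c(rep(1L, 208), rep(0L, 922)))
  expect_equal(classPrevalence(m), 208 / 1130)
  expect_equal(round(100 * classPrevalence(m), 1), 18.4)
  expect_equal(classPrevalence(mk(c(rep(1L, 54), rep(0L, 66)))), 0.45)
  expect_equal(classPrevalence(mk(rep(0L, 10))), 0)
  set.seed(7)
  labs <- sample(c(0L, 1L), 50, replace = TRUE, prob = c(0.7, 0.3))
  expect_equal(classPrevalence(mk(labs)), classPrevalence(mk(sample(labs))))
  expect_error(classPrevalence(datasetManifest(data.frame(
    exam_id = character(), label = integer(), axial = character(),
    coronal = character(), sagittal = character()))), "empty")
})
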