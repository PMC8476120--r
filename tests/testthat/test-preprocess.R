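test_that("kymographs round-trip through TIFF and CSV", {
  set.seed(8)
  m <- matrix(runif(400, 0, 600), 20, 20)
  k <- Kymograph(m, sourceId = "roundtrip")
  ftif <- tempfile(fileext = ".tif")
  fcsv <- tempfile(fileext = ".csv")
  writeKymograph(k, ftif)
  writeKymograph(k, fcsv)
  ktif <- readKymograph(ftif)
  kcsv <- readKymograph(fcsv)
  expect_equal(intensityMatrix(ktif), m, tolerance = 1e-6)
  expect_equal(intensityMatrix(kcsv), m, tolerance = 1e-12)
  ## both encodings agree with each other
  expect_equal(intensityMatrix(ktif), intensityMatrix(kcsv),
               tolerance = 1e-6)
  expect_equal(frameInterval(ktif), 0.3)
  expect_equal(pixelSize(ktif), 126.4)
})

test_that("non-2-D input is rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(paste(1:10, collapse = ","), f)   # a single row
  expect_error(readKymograph(f), "2-D")
  expect_error(readKymograph(tempfile(fileext = ".csv")), "no such file")
  expect_error(Kymograph(matrix(1, 5, 3)), "8 pixels")
})

test_that("a constant image is entirely background", {
  k <- Kymograph(matrix(100, 60, 60))
  out <- intensityMatrix(rollingBallSubtract(k, 50))
  expect_true(all(out == 0))
})

test_that("narrow peaks survive subtraction; flat offset is removed", {
  n <- 80
  prof <- 10 + 150 * exp(-((1:n) - 40)^2 / (2 * 2^2))
  k <- Kymograph(matrix(prof, 80, n, byrow = TRUE))
  out <- intensityMatrix(rollingBallSubtract(k, 50))
  expect_gt(max(out), 150 * 0.95)          # peak amplitude within 5%
  expect_lt(max(out[, c(1:25, 55:80)]), 1)  # off-peak residual below 1
  expect_gte(min(out), 0)                   # clipping contract

  ## independent oracle: flat-disc morphological opening (EBImage)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- intensityMatrix(k)
    op <- EBImage::opening(img / max(img),
                           EBImage::makeBrush(51, "disc")) * max(img)
    oracle <- img - as.matrix(op)
    oracle[oracle < 0] <- 0
    expect_lt(max(abs(out - oracle)), 0.05 * 150)
  }
})

test_that("subtraction is idempotent for peaky images", {
  n <- 80
  prof <- 25 + 140 * exp(-((1:n) - 30)^2 / (2 * 1.5^2))
  k <- Kymograph(matrix(prof, 40, n, byrow = TRUE))
  once <- rollingBallSubtract(k, 50)
  twice <- rollingBallSubtract(once, 50)
  expect_lt(max(abs(intensityMatrix(once) - intensityMatrix(twice))),
            0.01 * 140)
})

test_that("oversized radii are rejected", {
  k <- Kymograph(matrix(1, 10, 10))
  expect_error(rollingBallSubtract(k, 100), "dimensions")
})
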