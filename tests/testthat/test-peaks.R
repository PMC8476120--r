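test_that("candidate detection finds isolated maxima and respects spacing", {
  expect_equal(nrow(detectCandidates(rep(5, 50), 50)), 0L)

  prof <- gaussProfile(60, A = 150, x0 = 20, sigma = 2)
  cand <- detectCandidates(prof, 50)
  expect_equal(nrow(cand), 1L)
  expect_lte(abs(cand$positionPx - 20), 1)

  two <- gaussProfile(80, 150, 20, 2) + gaussProfile(80, 120, 50, 2)
  expect_equal(nrow(detectCandidates(two, 50, minSeparationPx = 5)), 2L)

  ## two candidates closer than the separation collapse to the higher one
  close <- gaussProfile(60, 150, 20, 4)
  close[22] <- close[22] + 1   # shoulder bump
  cc <- detectCandidates(close, 50, minSeparationPx = 5)
  expect_equal(nrow(cc), 1L)
})

test_that("a noiseless Gaussian is recovered to numerical precision", {
  prof <- gaussProfile(60, A = 150, x0 = 20, sigma = 2)
  fit <- fitMultiGaussian(prof, detectCandidates(prof, 50), threshold = 50,
                          baseline = FALSE)
  expect_equal(nrow(fit), 1L)
  expect_lt(abs(fit$amplitude - 150), 0.1)
  expect_lt(abs(fit$positionPx - 20), 0.01)
  expect_equal(fit$integral, fit$amplitude * fit$sigmaPx * sqrt(2 * pi))
})

test_that("two well-separated Gaussians are both recovered", {
  prof <- gaussProfile(100, 150, 30, 2) + gaussProfile(100, 90, 50, 2)
  fit <- fitMultiGaussian(prof, detectCandidates(prof, 40), threshold = 40,
                          baseline = FALSE)
  expect_equal(nrow(fit), 2L)
  expect_lt(abs(fit$amplitude[1] - 150) / 150, 0.01)
  expect_lt(abs(fit$amplitude[2] - 90) / 90, 0.01)
  ## sorted by position, and never more peaks than candidates
  expect_true(!is.unsorted(fit$positionPx))
})

test_that("amplitude errors match the linearised error model under noise", {
  ## independent oracle: the asymptotic standard error of the amplitude from
  ## the Jacobian of the model at the true parameters
  n <- 60; A <- 150; x0 <- 20.3; s <- 2; noiseSd <- 5
  x <- seq_len(n)
  J <- cbind(exp(-(x - x0)^2 / (2 * s^2)),
             A * exp(-(x - x0)^2 / (2 * s^2)) * (x - x0) / s^2,
             A * exp(-(x - x0)^2 / (2 * s^2)) * (x - x0)^2 / s^3)
  seA <- noiseSd * sqrt(solve(t(J) %*% J)[1, 1])
  clean <- A * exp(-(x - x0)^2 / (2 * s^2))
  set.seed(42)
  hits <- 0L
  for (r in 1:200) {
    prof <- clean + rnorm(n, sd = noiseSd)
    cand <- detectCandidates(prof, 50)
    if (!nrow(cand)) next
    fit <- suppressWarnings(
      fitMultiGaussian(prof, cand, threshold = 50, baseline = FALSE))
    if (nrow(fit) == 1L && abs(fit$amplitude - A) <= 3 * seA) hits <- hits + 1L
  }
  expect_gte(hits, 0.95 * 200)
})

test_that("peak extraction matches ground truth on a stationary cluster", {
  sp <- SimulationParams(pa = 0, pd = 0, pNuc = 0, nFrames = 30, seed = 2)
  tr <- simulateClusterDynamics(sp, initialSizes = 3)
  k <- renderKymograph(tr, ImagingParams(noiseSd = 0, unitIntensityCv = 0,
                                         backgroundOffset = 0))
  pt <- extractPeaks(k, threshold = 20)
  df <- peaks(pt)
  expect_equal(nrow(df), 30L)                      # one peak per frame
  expect_equal(sort(unique(df$frame)), 1:30)
  expect_true(all(abs(df$integral - 300) / 300 < 0.02))
})

test_that("an empty kymograph yields an empty, well-formed PeakTable", {
  k <- Kymograph(matrix(2, 20, 30))
  pt <- extractPeaks(k, threshold = 30)
  expect_s4_class(pt, "PeakTable")
  expect_equal(nrow(peaks(pt)), 0L)
  expect_equal(nFrames(pt), 20L)
})

test_that("peak tables are sorted and round-trip through CSV", {
  sp <- unitSimParams(nFrames = 60L, seed = 9L)
  d <- generateDataset(sp, cleanImaging(), 1, seed = 9,
                       initialSizes = 2L)[[1]]
  pt <- suppressWarnings(extractPeaks(rollingBallSubtract(d$kymograph)))
  df <- peaks(pt)
  expect_false(is.unsorted(df$frame))
  f <- tempfile(fileext = ".csv")
  writePeakTable(pt, f)
  back <- readPeakTable(f)
  expect_equal(peaks(back)$integral, df$integral, tolerance = 1e-6)
  expect_equal(nFrames(back), nFrames(pt))
  expect_equal(back@threshold, pt@threshold, tolerance = 1e-8)
})
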