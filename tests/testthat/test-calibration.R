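test_that("well-separated intensity classes are recovered within 2 counts", {
  set.seed(1)
  x <- c(rnorm(1000, 100, 8), rnorm(1000, 200, 10))
  fit <- fitIntensityMixture(x, 2)
  expect_lt(abs(fit$means[1] - 100), 2)
  expect_lt(abs(fit$means[2] - 200), 2)
  expect_true(all(fit$weights > 0.4))
})

test_that("single-component data recover the sample mean", {
  set.seed(2)
  x <- rnorm(400, 150, 12)
  fit <- fitIntensityMixture(x, 1)
  expect_lt(abs(fit$means - mean(x)), 2)
})

test_that("unresolvable extra components are flagged, not fatal", {
  set.seed(3)
  x <- c(rnorm(950, 100, 8), rnorm(50, 500, 8))
  fit <- suppressWarnings(fitIntensityMixture(x, 5, lowWeight = 0.05))
  expect_length(fit$means, 5L)
  expect_true(all(is.finite(fit$means)))
  expect_true(any(fit$lowWeight))   # surplus components carry little mass
  expect_error(fitIntensityMixture(rnorm(30, 100, 5), 2), "at least 50")
})

test_that("the calibration line matches closed-form least squares", {
  perfect <- fitCalibrationLine(c(100, 200, 300))
  expect_equal(perfect$slope, 100, tolerance = 1e-10)
  expect_equal(perfect$intercept, 0, tolerance = 1e-9)
  expect_equal(perfect$rSquared, 1, tolerance = 1e-12)

  ## hand oracle for (1,100), (2,210), (3,290): slope = 190/2 = 95,
  ## intercept = 200 - 95*2 = 10; fitted values (105, 200, 295) give
  ## SSE = 25 + 100 + 25 = 150 and SST = 10000 + 100 + 8100 = 18200
  hand <- fitCalibrationLine(c(100, 210, 290))
  expect_equal(hand$slope, 95, tolerance = 1e-10)
  expect_equal(hand$intercept, 10, tolerance = 1e-10)
  expect_equal(hand$rSquared, 1 - 150 / 18200, tolerance = 1e-12)

  expect_error(fitCalibrationLine(100), "at least 2")
  expect_error(fitCalibrationLine(c(100, 100)), "degenerate")
})

test_that("band assignment follows the 2-sd and nearest-mean rules", {
  m <- calibrationModelFromComponents(c(100, 200), c(8, 10))
  ## at a component mean: that count
  expect_equal(assignCount(c(100, 200), m), c(1L, 2L))
  ## midway between non-overlapping bands: unassigned
  expect_true(is.na(assignCount(150, m)))
  ## overlapping bands resolve to the nearest mean
  mo <- calibrationModelFromComponents(c(100, 200), c(30, 30))
  expect_equal(assignCount(c(140, 160), mo), c(1L, 2L))
})

test_that("the published nine-component table assigns intensity 100 to one binder", {
  tab <- referenceIntensityComponents(9)
  m <- calibrationModelFromComponents(tab$mean, tab$sd, tab$weight,
                                      countOffset = 0L)
  expect_equal(assignCount(100, m), 1L)
  expect_equal(assignCount(24.52, m), 0L)
})

test_that("assignment is monotone in intensity for realistic calibrations", {
  ## class widths in real calibrations are well below the class spacing
  ## (a band nested inside a much wider neighbour would break monotonicity,
  ## but such a geometry never survives the calibration guards)
  set.seed(7)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    mu <- sort(runif(k, 50, 800))
    if (min(diff(mu)) < 20) next
    sds <- runif(k, 0.05, 0.45) * min(diff(mu))
    m <- calibrationModelFromComponents(mu, sds)
    counts <- assignCount(seq(0, 900, by = 2.5), m)
    obs <- counts[!is.na(counts)]
    expect_true(all(diff(obs) >= 0))
  }
})

test_that("noise-free synthetic assignment is exact; snr >= 10 stays above 95%", {
  sp <- unitSimParams(nFrames = 300L, seed = 6L)
  d0 <- generateDataset(sp, cleanImaging(), 1, seed = 6,
                        initialSizes = 2L)[[1]]
  cal <- list(nComponents = 6L, countOffset = 1L, minLineR2 = 0.9,
              maxSdFrac = 0.6)
  accuracy <- function(d) {
    pt <- suppressWarnings(extractPeaks(rollingBallSubtract(d$kymograph)))
    model <- collapseKinetics:::.autoCalibration(peaks(pt)$integral, cal, 6L,
                                                 "acc")
    pk <- peaks(pt)
    ot <- occupancyTable(d$trace)
    ot$posPx <- ot$centreNm / 126.4
    truth <- rep(NA_integer_, nrow(pk))
    for (i in seq_len(nrow(pk))) {
      cand <- ot[ot$frame == pk$frame[i], , drop = FALSE]
      if (!nrow(cand)) next
      j <- which.min(abs(cand$posPx - pk$positionPx[i]))
      if (abs(cand$posPx[j] - pk$positionPx[i]) < 3) truth[i] <- cand$count[j]
    }
    got <- assignCount(pk$integral, model)
    ok <- !is.na(truth) & truth <= 6
    mean(got[ok] == truth[ok], na.rm = TRUE)
  }
  expect_equal(accuracy(d0), 1)

  dn <- generateDataset(sp, ImagingParams(noiseSd = 4, unitIntensityCv = 0.1,
                                          seed = 6), 1, seed = 6,
                        initialSizes = 2L)[[1]]
  expect_gte(accuracy(dn), 0.95)
})

test_that("calibration models survive a JSON round trip", {
  m <- calibrationModelFromComponents(c(98, 201, 299), c(9, 12, 15),
                                      extendTo = 5L, sourceId = "json")
  f <- tempfile(fileext = ".json")
  writeCalibration(m, f)
  back <- readCalibration(f)
  expect_equal(componentMeans(back), componentMeans(m), tolerance = 1e-12)
  expect_equal(back@bands, m@bands, tolerance = 1e-12)
  expect_equal(back@extrapolated, m@extrapolated)
  expect_equal(assignCount(c(100, 250, 400), back),
               assignCount(c(100, 250, 400), m))
})
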