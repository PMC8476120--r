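## build a PeakTable by hand for linker unit tests
mkPeaks <- function(df, nFrames = max(df$frame) + 1L, threshold = 10) {
  df$amplitude <- if (is.null(df$amplitude)) df$integral / (1 * sqrt(2 * pi))
    else df$amplitude
  df$sigmaPx <- 1
  df$fitRss <- 0
  df$converged <- TRUE
  df <- df[order(df$frame, df$positionPx),
           c("frame", "positionPx", "amplitude", "sigmaPx", "integral",
             "fitRss", "converged")]
  rownames(df) <- NULL
  new("PeakTable", peaks = df, threshold = threshold, sourceId = "manual",
      nFrames = as.integer(nFrames))
}

test_that("a stationary peak threads into a single full-length track", {
  pk <- mkPeaks(data.frame(frame = 1:10, positionPx = 20.2, integral = 200),
                nFrames = 10L)
  ts <- linkTracks(pk)
  df <- tracks(ts)
  expect_equal(length(unique(df$trackId)), 1L)
  expect_equal(nrow(df), 10L)
})

test_that("distant peaks stay in separate tracks", {
  pk <- mkPeaks(data.frame(frame = rep(1:5, each = 2),
                           positionPx = rep(c(10, 50), 5), integral = 100))
  ts <- linkTracks(pk, maxLinkDistancePx = 10)
  expect_equal(length(unique(tracks(ts)$trackId)), 2L)
})

test_that("a single missing frame is bridged and flagged as a gap", {
  pk <- mkPeaks(data.frame(frame = c(1:4, 6:9), positionPx = 30,
                           integral = 150), nFrames = 9L)
  ts <- linkTracks(pk, maxGapFrames = 2)
  df <- tracks(ts)
  expect_equal(length(unique(df$trackId)), 1L)
  expect_equal(df$frame[df$gap], 5L)
  expect_true(is.na(df$integral[df$gap]))
  ## with a shorter grace the same data split into two tracks
  ts0 <- linkTracks(pk, maxGapFrames = 0)
  expect_equal(length(unique(tracks(ts0)$trackId)), 2L)
})

test_that("no peak is ever assigned to two tracks", {
  sp <- SimulationParams(pa = 0.15, pd = 0.0554, pNuc = 0.06,
                         nFrames = 300, filamentLengthPx = 256, seed = 13)
  d <- generateDataset(sp, cleanImaging(), 1, seed = 13)[[1]]
  pt <- suppressWarnings(extractPeaks(rollingBallSubtract(d$kymograph)))
  ts <- linkTracks(pt)
  df <- tracks(ts)[!tracks(ts)$gap, ]
  ## every observed localisation appears exactly once
  expect_equal(nrow(df), nrow(peaks(pt)))
  expect_false(any(duplicated(df[, c("frame", "positionPx")])))
})

test_that("count series carry terminal zeros and missing values correctly", {
  model <- calibrationModelFromComponents(c(100, 200), c(8, 10))
  ## constant 2-myosin track for 5 frames, gone before the end of recording
  pk <- mkPeaks(data.frame(frame = 1:5, positionPx = 25, integral = 200),
                nFrames = 20L)
  cs <- tracksToCountSeries(linkTracks(pk), model)
  expect_equal(cs[[1L]], c(2L, 2L, 2L, 2L, 2L, 0L))

  ## an unassignable intensity becomes NA, not zero
  pk2 <- mkPeaks(data.frame(frame = 1:3, positionPx = 25,
                            integral = c(200, 150, 200)), nFrames = 3L)
  cs2 <- tracksToCountSeries(linkTracks(pk2), model)
  expect_equal(cs2[[1L]], c(2L, NA_integer_, 2L))   # censored end: no 0

  ## single-frame tracks contribute nothing
  pk3 <- mkPeaks(data.frame(frame = 2, positionPx = 25, integral = 200),
                 nFrames = 10L)
  expect_length(tracksToCountSeries(linkTracks(pk3), model), 0L)
})

test_that("noiseless tracking reproduces the ground-truth count trajectory", {
  sp <- unitSimParams(nFrames = 150L, pNuc = 0, seed = 17L)
  d <- generateDataset(sp, cleanImaging(), 1, seed = 17,
                       initialSizes = 3L)[[1]]
  pt <- suppressWarnings(extractPeaks(rollingBallSubtract(d$kymograph)))
  model <- collapseKinetics:::.autoCalibration(
    peaks(pt)$integral,
    list(nComponents = 6L, countOffset = 1L, minLineR2 = 0.9,
         maxSdFrac = 0.6), 6L, "rt")
  cs <- tracksToCountSeries(linkTracks(pt), model)
  os <- occupancySeries(d$trace)
  expect_length(cs, length(os))
  truth <- os[[1L]]
  got <- cs[[1L]]
  n <- min(length(truth), length(got))
  agree <- mean(truth[seq_len(n)] == got[seq_len(n)], na.rm = TRUE)
  expect_gte(agree, 0.98)
})

test_that("track drift shows no directional bias under symmetric attachment", {
  sp <- SimulationParams(pa = 0.3, pd = 0.25, pNuc = 0.05, nFrames = 500,
                         filamentLengthPx = 256, nMaxSim = 4L, seed = 23)
  tr <- simulateClusterDynamics(sp, initialSizes = c(2L, 2L, 2L))
  ot <- occupancyTable(tr)
  disp <- unlist(lapply(split(ot, ot$regionId), function(g) {
    d <- diff(g$centreNm)
    d[d != 0]
  }))
  expect_gt(length(disp), 50)
  p <- binom.test(sum(disp > 0), length(disp))$p.value
  expect_gt(p, 0.01)
})
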