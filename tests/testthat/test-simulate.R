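test_that("forced detachment empties a cluster in one frame", {
  sp <- SimulationParams(pa = 0, pd = 1, pNuc = 0, nFrames = 5, seed = 1)
  tr <- simulateClusterDynamics(sp, initialSizes = 3)
  ev <- eventLog(tr)
  expect_equal(sum(ev$event == "detach" & ev$frame == 1L), 3L)
  os <- occupancySeries(tr, minFrames = 1)
  expect_equal(os[["1"]], c(3L, 0L))   # occupied at frame 1, empty after
})

test_that("occupancy is non-decreasing without a detachment channel", {
  sp <- SimulationParams(pa = 0.15, pd = 0, pNuc = 0, nFrames = 150, seed = 3)
  tr <- simulateClusterDynamics(sp, initialSizes = 1)
  os <- occupancySeries(tr, minFrames = 1)
  expect_length(os, 1L)
  expect_true(all(diff(os[[1L]]) >= 0))
  expect_gt(max(os[[1L]]), 1)   # the attachment channel is active
})

test_that("probabilities outside [0,1] and infeasible pa are rejected", {
  expect_error(SimulationParams(pa = -0.1), "pa")
  expect_error(SimulationParams(pd = 1.4), "pd")
  expect_error(SimulationParams(pa = 0.9, pd = 0.3), "must not exceed")
})

test_that("identical seeds give bit-identical traces", {
  sp <- unitSimParams(seed = 11L)
  tr1 <- simulateClusterDynamics(sp)
  tr2 <- simulateClusterDynamics(sp)
  expect_identical(tr1@myosins, tr2@myosins)
  expect_identical(eventLog(tr1), eventLog(tr2))
})

test_that("one-frame transition frequencies follow the analytic kernel", {
  ## includes the binomial detachment cells C(i, i-j) pd^(i-j) (1-pd)^j
  ## and the attachment cells at exactly pa
  sp <- SimulationParams(pa = 0.15, pd = 0.056, pNuc = 0.1, nFrames = 4000L,
                         filamentLengthPx = 256, seed = 21L)
  tr <- simulateClusterDynamics(sp)
  ## tabulate one size beyond the tested rows so that the "discard sizes
  ## above nMax" rule cannot censor the boundary row's attachment pairs
  tc <- countTransitions(occupancySeries(tr, minFrames = 1), nMax = 5L)
  m <- probabilities(transitionMatrix(tc, conditional = FALSE))
  kern <- transitionKernel(sp, nMax = 5L)
  ex <- tc@exposures
  expect_gt(sum(ex), 5000)
  for (i in 1:4) {
    for (j in 0:5) {
      if (j == i) next
      p0 <- kern[as.character(i), as.character(j)]
      phat <- m[as.character(i), as.character(j)]
      se <- sqrt(p0 * (1 - p0) / ex[i])
      expect_lte(abs(phat - p0), max(3 * se, 1e-12) + 1e-12,
                 label = sprintf("cell %d->%d", i, j))
    }
  }
})

test_that("a concerted collapse channel raises complete detachment above pd^n", {
  sp <- SimulationParams(pa = 0.15, pd = 0.056, pc = 0.1, pNuc = 0.1,
                         nFrames = 3000L, filamentLengthPx = 256, seed = 4L)
  tr <- simulateClusterDynamics(sp)
  tc <- countTransitions(occupancySeries(tr, minFrames = 1), nMax = 4L)
  m <- probabilities(transitionMatrix(tc, conditional = FALSE))
  for (i in 2:4) {
    expect_gt(m[as.character(i), "0"], 0.056^i)
  }
})

test_that("rendering conserves injected intensity and baseline", {
  ## empty trace: every pixel is the background offset
  spEmpty <- SimulationParams(pa = 0, pd = 0, pNuc = 0, nFrames = 3, seed = 1)
  trEmpty <- simulateClusterDynamics(spEmpty)
  k0 <- renderKymograph(trEmpty, ImagingParams(noiseSd = 0,
                                               backgroundOffset = 25))
  expect_true(all(intensityMatrix(k0) == 25))

  ## one myosin: integrated frame intensity equals the unit intensity
  sp1 <- SimulationParams(pa = 0, pd = 0, pNuc = 0, nFrames = 2, seed = 1)
  tr1 <- simulateClusterDynamics(sp1, initialSizes = 1)
  k1 <- renderKymograph(tr1, ImagingParams(noiseSd = 0, unitIntensityCv = 0,
                                           backgroundOffset = 0))
  expect_equal(rowSums(intensityMatrix(k1)), c(100, 100), tolerance = 0.01)

  ## n co-located myosins: n times the unit intensity
  tr3 <- simulateClusterDynamics(sp1, initialSizes = 3)
  k3 <- renderKymograph(tr3, ImagingParams(noiseSd = 0, unitIntensityCv = 0,
                                           backgroundOffset = 0))
  expect_equal(rowSums(intensityMatrix(k3)), c(300, 300), tolerance = 0.01 * 300)
})

test_that("datasets are reproducible from the master seed and replicates differ", {
  sp <- unitSimParams(nFrames = 60L)
  im <- cleanImaging()
  d1 <- generateDataset(sp, im, nKymographs = 2, seed = 5)
  d2 <- generateDataset(sp, im, nKymographs = 2, seed = 5)
  expect_identical(intensityMatrix(d1[[1]]$kymograph),
                   intensityMatrix(d2[[1]]$kymograph))
  expect_identical(d1[[2]]$trace@myosins, d2[[2]]$trace@myosins)
  expect_false(identical(d1[[1]]$trace@myosins, d1[[2]]$trace@myosins))
})

test_that("paper-scale dataset generation stays fast", {
  sp <- SimulationParams(nFrames = 300L)
  el <- system.time(generateDataset(sp, ImagingParams(), nKymographs = 20,
                                    seed = 2))["elapsed"]
  expect_lt(el, 60)
})
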