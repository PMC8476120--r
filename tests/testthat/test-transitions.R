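test_that("transition tallies follow the counting rules", {
  tc <- countTransitions(list(c(2L, 2L, 1L, 1L, 0L)))
  cnt <- transitionCounts(tc)
  expect_equal(cnt["2", "1"], 1L)
  expect_equal(cnt["1", "0"], 1L)
  expect_equal(sum(cnt), 2L)
  expect_equal(unname(tc@exposures[1:2]), c(2, 2))  # stays count as exposure

  ## complete collapse in one step
  expect_equal(transitionCounts(countTransitions(list(c(3L, 0L))))["3", "0"], 1L)

  ## sizes above nMax are discarded
  tc7 <- countTransitions(list(c(7L, 3L)), nMax = 6)
  expect_equal(sum(transitionCounts(tc7)), 0L)

  ## missing values break pairs
  tcNA <- countTransitions(list(c(2L, NA, 1L)))
  expect_equal(sum(transitionCounts(tcNA)), 0L)
})

test_that("conditional rows are normalised like the published tables", {
  ## row 4 split 20 / 5 / 75 reproduces p[4,3] = 0.20, p[4,5] = 0.05
  series <- c(rep(list(c(4L, 3L)), 20), rep(list(c(4L, 5L)), 5),
              rep(list(c(4L, 0L)), 75))
  m <- transitionMatrix(countTransitions(series))
  p <- probabilities(m)
  expect_equal(p["4", "3"], 0.20)
  expect_equal(p["4", "5"], 0.05)
  expect_equal(p["4", "0"], 0.75)

  ## single observed transition: that row is a point mass
  m1 <- transitionMatrix(countTransitions(list(c(2L, 1L))))
  expect_equal(probabilities(m1)["2", "1"], 1)

  ## every observed row sums to one within 1e-9; the diagonal is zero
  rs <- rowSums(p)
  expect_true(all(abs(rs[m@rowTotals > 0] - 1) < 1e-9))
  expect_true(all(diag(p[, -1]) == 0))
})

test_that("detachment probability and rate match the kinetic closed forms", {
  expect_equal(round(detachmentProbability(1.9, 0.1, 0.30), 4), 0.0554)
  expect_equal(detachmentProbability(frameS = 0), 0)
  expect_equal(detachmentRate(1.9, 0.1), 0.19)
  expect_equal(detachmentProbability(1.9, 0.1, 0.30),
               1 - exp(-0.19 * 0.30), tolerance = 1e-12)
})

test_that("the predicted matrix encodes both detachment laws", {
  pa <- 0.15; pd <- 0.0554
  pComb <- probabilities(predictedMatrix(pa, pd, 6, "combinatorial"))
  pBin <- probabilities(predictedMatrix(pa, pd, 6, "binomial"))

  ## superdiagonal is pa for both
  for (i in 1:5) {
    expect_equal(pComb[i, as.character(i + 1)], pa)
    expect_equal(pBin[i, as.character(i + 1)], pa)
  }
  ## brute-force oracle: the 4 -> 2 coefficient counts 2-subsets of 4
  nWays <- ncol(combn(4, 2))
  expect_equal(pComb["4", "2"], nWays * pd^2, tolerance = 1e-12)
  expect_equal(pBin["4", "2"], nWays * pd^2 * (1 - pd)^2, tolerance = 1e-12)
  ## complete detachment: a single way for all to leave
  for (i in 1:6) {
    expect_equal(pComb[as.character(i), "0"], pd^i, tolerance = 1e-12)
    expect_equal(pBin[as.character(i), "0"], pd^i, tolerance = 1e-12)
  }
  ## row-normalised variant sums to one
  pN <- probabilities(predictedMatrix(pa, pd, 6, normalise = TRUE))
  expect_equal(unname(rowSums(pN)), rep(1, 6), tolerance = 1e-9)
  expect_error(predictedMatrix(0, 0.05), "pa")
})

test_that("Pa estimation averages the first superdiagonal", {
  p <- matrix(0, 2, 3, dimnames = list(start = c("1", "2"),
                                       final = c("0", "1", "2")))
  p["1", "2"] <- 0.1
  sem <- matrix(NA_real_, 2, 3, dimnames = dimnames(p))
  m <- new("TransitionMatrix", probabilities = p, sem = sem,
           rowTotals = c(10, 0), conditional = FALSE, nMax = 2L,
           nSources = 1L)
  expect_equal(estimatePa(m), 0.1)      # single observed row

  ## superdiagonal entries 0.1 and 0.2 average to 0.15
  p3 <- matrix(0, 3, 4, dimnames = list(start = as.character(1:3),
                                        final = as.character(0:3)))
  p3["1", "2"] <- 0.1; p3["2", "3"] <- 0.2
  m3 <- new("TransitionMatrix", probabilities = p3,
            sem = matrix(NA_real_, 3, 4, dimnames = dimnames(p3)),
            rowTotals = c(5, 5, 5), conditional = FALSE, nMax = 3L,
            nSources = 1L)
  expect_equal(estimatePa(m3), 0.15)

  expect_error(estimatePa(countTransitions(list(c(1L, 1L)))), "no transitions")
})

test_that("Pa is recovered from simulated study conditions", {
  sp <- SimulationParams(pa = 0.15, pd = 0.0554, pNuc = 0.08,
                         nFrames = 3000, filamentLengthPx = 256, seed = 31)
  tr <- simulateClusterDynamics(sp)
  tc <- countTransitions(occupancySeries(tr, minFrames = 1), nMax = 6)
  expect_lt(abs(estimatePa(tc) - 0.15), 0.02)
})

test_that("collapse curves extract the first column with uncertainty rules", {
  pred <- predictedMatrix(0.15, 0.0554, 6)
  cc <- collapseCurve(pred)
  expect_equal(cc$probability, 0.0554^(1:6), tolerance = 1e-12)
  ## log-linear in cluster size
  expect_equal(diff(log(cc$probability)), rep(log(0.0554), 5),
               tolerance = 1e-9)

  ## single-kymograph input: sem reported missing
  m1 <- transitionMatrix(countTransitions(list(c(3L, 0L, 0L)[1:2])))
  expect_true(all(is.na(collapseCurve(m1)$sem)))

  ## a collapse channel lifts the measured first column above pd^i
  sp <- SimulationParams(pa = 0.15, pd = 0.0554, pc = 0.15, pNuc = 0.1,
                         nFrames = 2000, filamentLengthPx = 256, seed = 37)
  tr <- simulateClusterDynamics(sp)
  m <- transitionMatrix(countTransitions(occupancySeries(tr, minFrames = 1)),
                        conditional = FALSE)
  cc2 <- collapseCurve(m)
  obs <- cc2$nObs > 20 & cc2$size >= 2
  expect_true(any(obs))
  expect_true(all(cc2$probability[obs] > 0.0554^cc2$size[obs]))
})

test_that("rate inversion is the exact algebraic inverse", {
  ## round trip across sizes and rates
  for (k in c(0.19, 3, 6)) {
    for (i in 1:6) {
      pd <- 1 - exp(-k * 0.3)
      expect_equal(invertCollapseRate(pd^i, i, 0.3), k,
                   tolerance = 1e-9 * k)
    }
  }
  expect_equal(invertCollapseRate(0.0554, 1, 0.3), 0.19, tolerance = 1e-3)
  ## closed-form evaluation: -ln(1 - sqrt(0.35)) / 0.3
  expect_equal(invertCollapseRate(0.35, 2, 0.3),
               -log(1 - sqrt(0.35)) / 0.3, tolerance = 1e-12)
  expect_equal(round(invertCollapseRate(0.35, 2, 0.3), 1), 3.0)
  expect_error(invertCollapseRate(1.2, 2), "inside")
})

test_that("transition tables round-trip through the archived CSV layout", {
  series <- c(rep(list(c(4L, 3L)), 20), rep(list(c(4L, 5L)), 5),
              rep(list(c(4L, 0L)), 75), rep(list(c(2L, 1L)), 10),
              rep(list(c(1L, 2L)), 10), rep(list(c(2L, 3L)), 10))
  m <- transitionMatrix(countTransitions(series))
  f <- tempfile(fileext = ".csv")
  writeTransitionMatrix(m, f)
  back <- readTransitionTable(f)
  expect_equal(probabilities(back), probabilities(m), tolerance = 1e-12)
  expect_true(back@conditional)
})

test_that("across-kymograph SEMs exist only with multiple sources", {
  series <- list(c(2L, 1L, 2L, 1L), c(2L, 1L, 0L), c(2L, 3L, 2L, 1L))
  tc <- countTransitions(series, sourceIds = c("a", "b", "c"))
  m <- transitionMatrix(tc)
  expect_equal(m@nSources, 3L)
  expect_true(is.finite(m@sem["2", "1"]))
})
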