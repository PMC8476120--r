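test_that("the fixed-dimension Gibbs sampler matches a quadrature oracle", {
  ## single component, jumps disabled, beta fixed by its own update; the
  ## oracle integrates the joint posterior of (mu, tau) on a grid after
  ## marginalising beta analytically (gamma-gamma compound)
  set.seed(5)
  y <- rnorm(60, 120, 9)
  hy <- mixtureHyperParams(y, kMax = 3)
  alpha <- hy@alpha; g <- hy@g; h <- hy@h; xi <- hy@xi; kappa <- hy@kappa
  n <- length(y)

  logPost <- function(mu, tau) {
    n / 2 * log(tau) - tau / 2 * sum((y - mu)^2) -
      kappa / 2 * (mu - xi)^2 +
      (alpha - 1) * log(tau) - (alpha + g) * log(h + tau)
  }
  mus <- seq(mean(y) - 6, mean(y) + 6, length.out = 201)
  taus <- exp(seq(log(1e-4), log(0.2), length.out = 301))
  lp <- outer(mus, taus, Vectorize(logPost))
  w <- exp(lp - max(lp))
  ## trapezoid weights on the log-spaced tau grid
  dtau <- c(diff(taus), 0) / 2 + c(0, diff(taus)) / 2
  W <- sweep(w, 2, dtau, "*")
  muMean <- sum(rowSums(W) * mus) / sum(W)
  tauMean <- sum(colSums(W) * taus) / sum(W)

  ch <- runMixtureChain(y, hy, nSweeps = 6000, seed = 2, fixedK = 1)
  keep <- 1001:6000
  muHat <- mean(ch@means[keep, 1])
  tauHat <- mean(1 / ch@sds[keep, 1]^2)
  expect_lt(abs(muHat - muMean) / abs(muMean), 0.02)
  expect_lt(abs(tauHat - tauMean) / tauMean, 0.05)
})

test_that("chains are reproducible from the seed", {
  set.seed(9)
  y <- c(rnorm(100, 100, 8), rnorm(100, 220, 10))
  hy <- mixtureHyperParams(y, kMax = 5)
  c1 <- runMixtureChain(y, hy, nSweeps = 300, seed = 7)
  c2 <- runMixtureChain(y, hy, nSweeps = 300, seed = 7)
  expect_identical(c1@k, c2@k)
  expect_identical(c1@means, c2@means)
  expect_error(runMixtureChain(rep(5, 100), hy), "zero range")
})

test_that("component number is identified in well-separated cases", {
  set.seed(12)
  y1 <- rnorm(500, 100, 5)
  hy1 <- mixtureHyperParams(y1, kMax = 5)
  ch1 <- runMixtureChain(y1, hy1, nSweeps = 2500, seed = 3)
  expect_equal(modalK(ch1), 1L)

  y2 <- c(rnorm(500, 100, 5), rnorm(500, 200, 5))
  hy2 <- mixtureHyperParams(y2, kMax = 5)
  chains <- runMixtureChains(y2, hy2, nSweeps = 2500, nChains = 2, seed = 3)
  expect_equal(modalK(chains), 2L)
  sm <- summarizeChains(chains, 2L)
  expect_lt(abs(sm@components$mean[1] - 100), 3)
  expect_lt(abs(sm@components$mean[2] - 200), 3)
  expect_true(all(abs(sm@components$weight - 0.5) < 0.05))
})

test_that("means stay ordered at every retained sweep", {
  set.seed(31)
  y <- c(rnorm(300, 100, 8), rnorm(300, 180, 8), rnorm(300, 260, 8))
  ch <- runMixtureChain(y, mixtureHyperParams(y, kMax = 6), nSweeps = 1500,
                        seed = 8)
  for (s in seq(10, 1500, by = 10)) {
    mu <- ch@means[s, seq_len(ch@k[s])]
    expect_false(is.unsorted(mu, strictly = TRUE))
  }
})

test_that("summaries average chains and degenerate inputs behave", {
  set.seed(4)
  y <- c(rnorm(200, 90, 6), rnorm(200, 210, 8))
  hy <- mixtureHyperParams(y, kMax = 4)
  chains <- runMixtureChains(y, hy, nSweeps = 800, nChains = 2, seed = 13)
  sm <- summarizeChains(chains, 2L)
  expect_s4_class(sm, "ComponentSummary")
  expect_equal(nrow(sm@components), 2L)
  expect_equal(sm@components$variance, sm@components$sd^2)
  expect_error(summarizeChains(chains, 6L), "no post-burn-in sweeps")

  ## two chains with identical retained states summarise to that state
  smA <- summarizeChains(list(chains[[1]], chains[[1]]), 2L)
  smB <- summarizeChains(chains[[1]], 2L)
  expect_equal(smA@components$mean, smB@components$mean, tolerance = 1e-12)
})

test_that("linearity check regresses means on binder number", {
  lin <- linearityCheck(c(0, 100, 200, 300))
  expect_equal(lin$slope, 100, tolerance = 1e-9)
  expect_equal(lin$rSquared, 1, tolerance = 1e-12)

  tab <- referenceIntensityComponents(9)
  lin9 <- linearityCheck(tab$mean)
  ## descriptive: the published means are close to linear (the top two
  ## classes accelerate slightly)
  expect_gt(lin9$rSquared, 0.9)
  expect_gt(lin9$slope, 0)

  expect_error(linearityCheck(c(0, 100)), "at least 3")
})

test_that("mid-point cut-offs and cut-off assignment follow the published rule", {
  tab <- referenceIntensityComponents(9)
  cuts <- cutoffsFromMeans(tab$mean)
  expect_length(cuts, 8L)
  expect_lt(abs(cuts[1] - 81.55), 0.005)    # background / one-binder
  expect_lt(abs(cuts[2] - 156.22), 0.005)   # one / two binders

  expect_equal(cutoffsFromMeans(c(0, 10)), 5)
  expect_equal(cutoffsFromMeans(c(2, 4, 10)), c(3, 7))
  expect_error(cutoffsFromMeans(5), "at least 2")
  expect_error(cutoffsFromMeans(c(5, 4)), "strictly increasing")

  expect_equal(assignCountsByCutoff(100, cuts), 1L)
  expect_equal(assignCountsByCutoff(10, cuts), 0L)
  expect_equal(assignCountsByCutoff(2000, cuts), 8L)
  expect_equal(assignCountsByCutoff(c(50, 160, 700), cuts), c(0L, 2L, 8L))
})

test_that("the seven-component table is also available", {
  tab7 <- referenceIntensityComponents(7)
  expect_equal(nrow(tab7), 7L)
  expect_equal(tab7$mean[1], 57.17)
  expect_error(referenceIntensityComponents(5), "7 or 9")
})
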