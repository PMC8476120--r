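#' @include AllClasses.R AllGenerics.R
NULL

#' Hyperparameters for the normal-mixture sampler
#'
#' Weakly informative defaults tied to the data range R: the inverse
#' variances have a Gamma(alpha, beta) prior with alpha = 2 and beta itself
#' Gamma(g = 0.2, h = 10/R^2); the means are N(xi, 1/kappa) with xi the
#' data mid-range and kappa = 1/R^2; weights are Dirichlet(delta = 1); the
#' number of components is uniform on 1..kMax.
#'
#' @param data numeric vector the mixture will be fitted to (sets R).
#' @param alpha inverse-variance prior shape (default 2).
#' @param g shape of the beta hyperprior (default 0.2).
#' @param hScale h = hScale / R^2 (default 10).
#' @param kMax maximum number of components (default 9).
#' @param delta Dirichlet parameter (default 1).
#' @param xi mean-prior centre; default mid-range.
#' @param kappa mean-prior precision; default 1/R^2.
#' @return A [MixtureHyperParams-class].
#' @export
mixtureHyperParams <- function(data, alpha = 2, g = 0.2, hScale = 10,
                               kMax = 9L, delta = 1, xi = NULL,
                               kappa = NULL) {
  data <- data[is.finite(data)]
  R <- diff(range(data))
  if (R <= 0) stop("data with zero range cannot be fitted")
  new("MixtureHyperParams", alpha = alpha, g = g, h = hScale / R^2,
      xi = if (is.null(xi)) mean(range(data)) else xi,
      kappa = if (is.null(kappa)) 1 / R^2 else kappa,
      delta = delta, kMax = as.integer(kMax), dataRange = R)
}

## log density of the Beta(a, b) distribution
.ldbeta <- function(x, a, b) dbeta(x, a, b, log = TRUE)

#' Run one reversible-jump mixture chain
#'
#' Samples the posterior of a univariate normal mixture with an unknown
#' number of components. Each sweep performs, in order: a Dirichlet weight
#' update; normal conditional updates of the means, rejected individually
#' if they would break the ordering (the ordering is how the linearity of
#' intensity with binder number is imposed during sampling); gamma
#' conditional updates of the inverse variances; a multinomial reallocation
#' of the observations; a gamma update of the variance-rate hyperparameter;
#' a split-or-combine move; and a birth-or-death move for empty components.
#' The trans-dimensional moves use the standard dimension-matching
#' construction with Beta(2,2), Beta(2,2), Beta(1,1) split variables.
#'
#' @param data numeric vector (>= 50 points).
#' @param hyper a [MixtureHyperParams-class]; default from
#'   [mixtureHyperParams()].
#' @param nSweeps number of sweeps (>= 1).
#' @param seed RNG seed.
#' @param startK initial number of components (default half of kMax).
#' @param fixedK set to an integer to disable the trans-dimensional moves
#'   and run a fixed-dimension Gibbs sampler at that k.
#' @return A [MixtureChain-class].
#' @export
runMixtureChain <- function(data, hyper = mixtureHyperParams(data),
                            nSweeps = 5000L, seed = 1L, startK = NULL,
                            fixedK = NULL) {
  data <- as.numeric(data[is.finite(data)])
  n <- length(data)
  if (n < 50L) stop("need at least 50 data points")
  stopifnot(nSweeps >= 1L)
  if (diff(range(data)) <= 0) stop("data with zero range cannot be fitted")
  set.seed(seed)

  kMax <- hyper@kMax
  alpha <- hyper@alpha; g <- hyper@g; h <- hyper@h
  xi <- hyper@xi; kappa <- hyper@kappa; delta <- hyper@delta
  jumps <- is.null(fixedK)
  k <- if (!jumps) as.integer(fixedK) else
    if (is.null(startK)) max(1L, min(kMax, kMax %/% 2L)) else as.integer(startK)
  stopifnot(k >= 1L, k <= kMax)

  ## initial allocation from sorted k-means (or quantile slicing)
  if (k > 1L) {
    km <- suppressWarnings(try(kmeans(data, k, nstart = 3), silent = TRUE))
    if (!inherits(km, "try-error") && length(unique(km$centers)) == k) {
      ord <- order(km$centers)
      z <- match(km$cluster, ord)
      mu <- sort(as.numeric(km$centers))
    } else {
      qs <- quantile(data, (seq_len(k) - 0.5) / k, names = FALSE)
      mu <- as.numeric(qs)
      z <- findInterval(data, c(-Inf, (mu[-1] + mu[-k]) / 2, Inf))
    }
  } else {
    z <- rep(1L, n)
    mu <- mean(data)
  }
  sig2 <- vapply(seq_len(k), function(j) {
    v <- var(data[z == j])
    if (!is.finite(v) || v <= 0) var(data) / k^2 else v
  }, numeric(1))
  w <- pmax(tabulate(z, k), 1) / sum(pmax(tabulate(z, k), 1))
  beta <- g / h

  kOut <- integer(nSweeps)
  muOut <- matrix(NA_real_, nSweeps, kMax)
  sdOut <- matrix(NA_real_, nSweeps, kMax)
  wOut <- matrix(NA_real_, nSweeps, kMax)
  betaOut <- numeric(nSweeps)
  att <- c(split = 0, combine = 0, birth = 0, death = 0)
  acc <- c(split = 0, combine = 0, birth = 0, death = 0)

  logphi <- function(y, m, s2) -0.5 * log(2 * pi * s2) - (y - m)^2 / (2 * s2)

  for (sweep in seq_len(nSweeps)) {
    nj <- tabulate(z, k)

    ## (a) weights | allocations
    w <- rgamma(k, delta + nj, 1)
    w <- w / sum(w)

    ## (b) means: full conditionals with individual order-rejection
    for (j in sample.int(k)) {
      prec <- kappa + nj[j] / sig2[j]
      m <- (kappa * xi + sum(data[z == j]) / sig2[j]) / prec
      cand <- rnorm(1, m, sqrt(1 / prec))
      loOk <- j == 1L || cand > mu[j - 1L]
      hiOk <- j == k || cand < mu[j + 1L]
      if (loOk && hiOk) mu[j] <- cand
    }

    ## (c) variances
    for (j in seq_len(k)) {
      ss <- if (nj[j]) sum((data[z == j] - mu[j])^2) else 0
      sig2[j] <- 1 / rgamma(1, alpha + nj[j] / 2, beta + ss / 2)
    }

    ## (d) allocations (Gumbel-max over log posterior class probabilities)
    if (k > 1L) {
      lp <- matrix(0, n, k)
      for (j in seq_len(k)) {
        lp[, j] <- log(w[j]) + logphi(data, mu[j], sig2[j])
      }
      z <- max.col(lp - log(-log(matrix(runif(n * k), n, k))))
    } else z <- rep(1L, n)

    ## (e) hyperparameter beta
    beta <- rgamma(1, g + k * alpha, h + sum(1 / sig2))

    if (jumps) {
      ## (f) split / combine
      doSplit <- if (k == 1L) TRUE else if (k == kMax) FALSE else
        runif(1) < 0.5
      bk <- function(kk) if (kk < kMax) (if (kk == 1L) 1 else 0.5) else 0
      dk <- function(kk) if (kk > 1L) (if (kk == kMax) 1 else 0.5) else 0
      nj <- tabulate(z, k)
      if (doSplit && k < kMax) {
        att["split"] <- att["split"] + 1
        j <- sample.int(k, 1L)
        u1 <- rbeta(1, 2, 2); u2 <- rbeta(1, 2, 2); u3 <- rbeta(1, 1, 1)
        wS <- w[j]; muS <- mu[j]; s2S <- sig2[j]
        w1 <- wS * u1; w2 <- wS * (1 - u1)
        mu1 <- muS - u2 * sqrt(s2S) * sqrt(w2 / w1)
        mu2 <- muS + u2 * sqrt(s2S) * sqrt(w1 / w2)
        s21 <- u3 * (1 - u2^2) * s2S * wS / w1
        s22 <- (1 - u3) * (1 - u2^2) * s2S * wS / w2
        ## adjacency: the two new means must fall between the neighbours
        loOk <- j == 1L || mu1 > mu[j - 1L]
        hiOk <- j == k || mu2 < mu[j + 1L]
        if (loOk && hiOk) {
          members <- which(z == j)
          lp1 <- log(w1) + logphi(data[members], mu1, s21)
          lp2 <- log(w2) + logphi(data[members], mu2, s22)
          mx <- pmax(lp1, lp2)
          p1 <- exp(lp1 - mx) / (exp(lp1 - mx) + exp(lp2 - mx))
          toFirst <- runif(length(members)) < p1
          l1 <- sum(toFirst); l2 <- length(members) - l1
          logPalloc <- sum(log(ifelse(toFirst, p1, 1 - p1)))
          logLikRatio <-
            sum(logphi(data[members][toFirst], mu1, s21)) +
            sum(logphi(data[members][!toFirst], mu2, s22)) -
            sum(logphi(data[members], muS, s2S))
          logA <- logLikRatio +
            ## p(k+1)/p(k) = 1 (uniform), ordered-prior factor (k+1)
            log(k + 1) +
            (delta - 1 + l1) * log(w1) + (delta - 1 + l2) * log(w2) -
            (delta - 1 + l1 + l2) * log(wS) - lbeta(delta, k * delta) +
            0.5 * log(kappa / (2 * pi)) -
            kappa / 2 * ((mu1 - xi)^2 + (mu2 - xi)^2 - (muS - xi)^2) +
            alpha * log(beta) - lgamma(alpha) -
            (alpha + 1) * (log(s21) + log(s22) - log(s2S)) -
            beta * (1 / s21 + 1 / s22 - 1 / s2S) +
            log(dk(k + 1L)) - log(bk(k)) - logPalloc +
            log(wS) + log(abs(mu1 - mu2)) + log(s21) + log(s22) -
            log(s2S) -
            log(u2) - log(1 - u2^2) - log(u3) - log(1 - u3) -
            .ldbeta(u1, 2, 2) - .ldbeta(u2, 2, 2) - .ldbeta(u3, 1, 1)
          if (is.finite(logA) && log(runif(1)) < logA) {
            acc["split"] <- acc["split"] + 1
            wNew <- append(w[-j], c(w1, w2), after = j - 1L)
            muNew <- append(mu[-j], c(mu1, mu2), after = j - 1L)
            s2New <- append(sig2[-j], c(s21, s22), after = j - 1L)
            zNew <- z
            zNew[z > j] <- zNew[z > j] + 1L
            zNew[members] <- j + ifelse(toFirst, 0L, 1L)
            w <- wNew; mu <- muNew; sig2 <- s2New; z <- zNew
            k <- k + 1L
          }
        }
      } else if (!doSplit && k > 1L) {
        att["combine"] <- att["combine"] + 1
        j1 <- sample.int(k - 1L, 1L); j2 <- j1 + 1L
        wS <- w[j1] + w[j2]
        muS <- (w[j1] * mu[j1] + w[j2] * mu[j2]) / wS
        s2S <- (w[j1] * (mu[j1]^2 + sig2[j1]) +
                  w[j2] * (mu[j2]^2 + sig2[j2])) / wS - muS^2
        u1 <- w[j1] / wS
        u2 <- (muS - mu[j1]) / (sqrt(s2S) * sqrt(w[j2] / w[j1]))
        u3 <- sig2[j1] * w[j1] / ((1 - u2^2) * s2S * wS)
        okU <- s2S > 0 && u2 > 0 && u2 < 1 && u3 > 0 && u3 < 1
        if (okU) {
          members <- which(z == j1 | z == j2)
          inFirst <- z[members] == j1
          l1 <- sum(inFirst); l2 <- length(members) - l1
          lp1 <- log(w[j1]) + logphi(data[members], mu[j1], sig2[j1])
          lp2 <- log(w[j2]) + logphi(data[members], mu[j2], sig2[j2])
          mx <- pmax(lp1, lp2)
          p1 <- exp(lp1 - mx) / (exp(lp1 - mx) + exp(lp2 - mx))
          logPalloc <- sum(log(ifelse(inFirst, p1, 1 - p1)))
          logLikRatio <-
            sum(logphi(data[members][inFirst], mu[j1], sig2[j1])) +
            sum(logphi(data[members][!inFirst], mu[j2], sig2[j2])) -
            sum(logphi(data[members], muS, s2S))
          ## log acceptance of the reverse split; combine accepts at -logA
          logA <- logLikRatio +
            log(k) +
            (delta - 1 + l1) * log(w[j1]) + (delta - 1 + l2) * log(w[j2]) -
            (delta - 1 + l1 + l2) * log(wS) -
            lbeta(delta, (k - 1L) * delta) +
            0.5 * log(kappa / (2 * pi)) -
            kappa / 2 * ((mu[j1] - xi)^2 + (mu[j2] - xi)^2 - (muS - xi)^2) +
            alpha * log(beta) - lgamma(alpha) -
            (alpha + 1) * (log(sig2[j1]) + log(sig2[j2]) - log(s2S)) -
            beta * (1 / sig2[j1] + 1 / sig2[j2] - 1 / s2S) +
            log(dk(k)) - log(bk(k - 1L)) - logPalloc +
            log(wS) + log(abs(mu[j1] - mu[j2])) + log(sig2[j1]) +
            log(sig2[j2]) - log(s2S) -
            log(u2) - log(1 - u2^2) - log(u3) - log(1 - u3) -
            .ldbeta(u1, 2, 2) - .ldbeta(u2, 2, 2) - .ldbeta(u3, 1, 1)
          if (is.finite(logA) && log(runif(1)) < -logA) {
            acc["combine"] <- acc["combine"] + 1
            w <- append(w[-c(j1, j2)], wS, after = j1 - 1L)
            mu <- append(mu[-c(j1, j2)], muS, after = j1 - 1L)
            sig2 <- append(sig2[-c(j1, j2)], s2S, after = j1 - 1L)
            zNew <- z
            zNew[z >= j2] <- zNew[z >= j2] - 1L
            z <- zNew
            k <- k - 1L
          }
        }
      }

      ## (g) birth / death of empty components
      nj <- tabulate(z, k)
      doBirth <- if (k == 1L) TRUE else if (k == kMax) FALSE else
        runif(1) < 0.5
      bk <- function(kk) if (kk < kMax) (if (kk == 1L) 1 else 0.5) else 0
      dk <- function(kk) if (kk > 1L) (if (kk == kMax) 1 else 0.5) else 0
      if (doBirth && k < kMax) {
        att["birth"] <- att["birth"] + 1
        wStar <- rbeta(1, 1, k)
        muStar <- rnorm(1, xi, sqrt(1 / kappa))
        s2Star <- 1 / rgamma(1, alpha, beta)
        k0 <- sum(nj == 0L)
        logA <- -lbeta(k * delta, delta) +
          (delta - 1) * log(wStar) + (n + k * delta - k) * log(1 - wStar) +
          log(k + 1) +
          log(dk(k + 1L)) - log(k0 + 1) - log(bk(k)) -
          .ldbeta(wStar, 1, k) +
          (k - 1) * log(1 - wStar)
        if (is.finite(logA) && log(runif(1)) < logA) {
          acc["birth"] <- acc["birth"] + 1
          pos <- findInterval(muStar, mu) + 1L
          w <- append(w * (1 - wStar), wStar, after = pos - 1L)
          mu <- append(mu, muStar, after = pos - 1L)
          sig2 <- append(sig2, s2Star, after = pos - 1L)
          zNew <- z
          zNew[z >= pos] <- zNew[z >= pos] + 1L
          z <- zNew
          k <- k + 1L
        }
      } else if (!doBirth && k > 1L) {
        empty <- which(nj == 0L)
        if (length(empty)) {
          att["death"] <- att["death"] + 1
          j <- if (length(empty) == 1L) empty else sample(empty, 1L)
          wStar <- w[j]
          k0 <- length(empty)
          ## reverse of a birth into the (k-1)-component state
          logA <- -lbeta((k - 1L) * delta, delta) +
            (delta - 1) * log(wStar) +
            (n + (k - 1L) * delta - (k - 1L)) * log(1 - wStar) +
            log(k) +
            log(dk(k)) - log(k0) - log(bk(k - 1L)) -
            .ldbeta(wStar, 1, k - 1L) +
            (k - 2L) * log(1 - wStar)
          if (is.finite(logA) && log(runif(1)) < -logA) {
            acc["death"] <- acc["death"] + 1
            w <- w[-j] / (1 - wStar)
            mu <- mu[-j]
            sig2 <- sig2[-j]
            zNew <- z
            zNew[z > j] <- zNew[z > j] - 1L
            z <- zNew
            k <- k - 1L
          }
        }
      }
    }

    kOut[sweep] <- k
    muOut[sweep, seq_len(k)] <- mu
    sdOut[sweep, seq_len(k)] <- sqrt(sig2)
    wOut[sweep, seq_len(k)] <- w
    betaOut[sweep] <- beta
  }

  rates <- ifelse(att > 0, acc / att, NA_real_)
  names(rates) <- names(att)
  new("MixtureChain", k = kOut, means = muOut, sds = sdOut, weights = wOut,
      beta = betaOut, hyper = hyper, seed = as.integer(seed),
      moveRates = rates)
}

#' Run several independent chains
#'
#' @inheritParams runMixtureChain
#' @param nChains number of chains (default 4); chain c uses seed
#'   `seed + c - 1`.
#' @return list of [MixtureChain-class].
#' @export
runMixtureChains <- function(data, hyper = mixtureHyperParams(data),
                             nSweeps = 5000L, nChains = 4L, seed = 1L,
                             startK = NULL, fixedK = NULL) {
  lapply(seq_len(nChains), function(cc) {
    runMixtureChain(data, hyper, nSweeps = nSweeps,
                    seed = as.integer(seed + cc - 1L), startK = startK,
                    fixedK = fixedK)
  })
}

#' Modal number of components after burn-in
#'
#' @param chains list of [MixtureChain-class] (or a single chain).
#' @param burnIn fraction of sweeps discarded (default 0.5).
#' @return integer, the most visited k.
#' @export
modalK <- function(chains, burnIn = 0.5) {
  if (is(chains, "MixtureChain")) chains <- list(chains)
  ks <- unlist(lapply(chains, function(ch) {
    ch@k[-seq_len(floor(length(ch@k) * burnIn))]
  }))
  tk <- table(ks)
  as.integer(names(tk)[which.max(tk)])
}

#' Summarise chains conditional on a component count
#'
#' Pools post-burn-in sweeps with exactly `kCondition` components and
#' reports, per component, the posterior mean of the mean, sd, variance and
#' weight, averaged across chains. Also reports the occupancy fraction of
#' `kCondition` and a between/within-chain convergence ratio (the largest
#' potential-scale-reduction factor over the component means).
#'
#' @param chains list of [MixtureChain-class] (or one chain).
#' @param kCondition conditioning number of components.
#' @param burnIn burn-in fraction (default 0.5).
#' @return A [ComponentSummary-class].
#' @export
summarizeChains <- function(chains, kCondition, burnIn = 0.5) {
  if (is(chains, "MixtureChain")) chains <- list(chains)
  kCondition <- as.integer(kCondition)
  if (kCondition > ncol(chains[[1L]]@means)) {
    stop("no post-burn-in sweeps with k = ", kCondition)
  }
  perChain <- lapply(chains, function(ch) {
    keep <- seq_along(ch@k) > floor(length(ch@k) * burnIn)
    sel <- keep & ch@k == kCondition
    list(n = sum(sel), nKept = sum(keep),
         mu = ch@means[sel, seq_len(kCondition), drop = FALSE],
         sd = ch@sds[sel, seq_len(kCondition), drop = FALSE],
         w = ch@weights[sel, seq_len(kCondition), drop = FALSE])
  })
  ns <- vapply(perChain, `[[`, numeric(1), "n")
  if (sum(ns) == 0L) {
    stop("no post-burn-in sweeps with k = ", kCondition)
  }
  use <- perChain[ns > 0L]
  chMu <- vapply(use, function(pc) colMeans(pc$mu), numeric(kCondition))
  chSd <- vapply(use, function(pc) colMeans(pc$sd), numeric(kCondition))
  chW <- vapply(use, function(pc) colMeans(pc$w), numeric(kCondition))
  chMu <- matrix(chMu, kCondition); chSd <- matrix(chSd, kCondition)
  chW <- matrix(chW, kCondition)
  nsUse <- ns[ns > 0L]
  wts <- nsUse / sum(nsUse)
  comp <- data.frame(
    component = seq_len(kCondition),
    mean = as.numeric(chMu %*% wts),
    sd = as.numeric(chSd %*% wts),
    weight = as.numeric(chW %*% wts))
  comp$variance <- comp$sd^2

  ## potential scale reduction over the component means
  conv <- NA_real_
  if (length(use) > 1L && all(nsUse > 10L)) {
    rhat <- vapply(seq_len(kCondition), function(j) {
      m <- vapply(use, function(pc) mean(pc$mu[, j]), numeric(1))
      v <- vapply(use, function(pc) var(pc$mu[, j]), numeric(1))
      W <- mean(v)
      B <- var(m)
      nbar <- mean(nsUse)
      if (W <= 0) return(1)
      sqrt(((nbar - 1) / nbar * W + B) / W)
    }, numeric(1))
    conv <- max(rhat)
  }
  occ <- sum(ns) / sum(vapply(perChain, `[[`, numeric(1), "nKept"))
  new("ComponentSummary",
      components = comp[, c("component", "mean", "sd", "variance", "weight")],
      kCondition = kCondition, occupancy = occ, convergence = conv,
      nChains = length(chains))
}

#' Linearity of component means in the number of binders
#'
#' Fluorescence intensity is linear in the number of bound fluorophores, so
#' the conditional posterior means should fall on a straight line against
#' the binder number. Regresses the means, excluding the background
#' component, on the binder index and reports slope and r-squared
#' (descriptive check; the sampling itself only enforces mean ordering).
#'
#' @param x a [ComponentSummary-class] or a numeric vector of ordered means
#'   whose first entry is the background component.
#' @return list with slope, intercept, rSquared.
#' @examples
#' linearityCheck(c(0, 100, 200, 300))   # slope 100, r^2 = 1
#' @export
linearityCheck <- function(x) {
  means <- if (is(x, "ComponentSummary")) x@components$mean else as.numeric(x)
  if (length(means) < 3L) {
    stop("need at least 3 components (background plus two binder classes)")
  }
  idx <- seq_along(means)[-1L] - 1L    # binder numbers 1, 2, ...
  fitCalibrationLine(means[-1L], idx)
}

#' Mid-point cut-offs between successive component means
#'
#' @param means strictly increasing numeric vector (>= 2 values).
#' @return numeric vector of boundaries, length `length(means) - 1`.
#' @examples
#' cutoffsFromMeans(c(24.52, 138.57))   # 81.545
#' @export
cutoffsFromMeans <- function(means) {
  if (length(means) < 2L) stop("need at least 2 means")
  if (any(diff(means) <= 0)) stop("means must be strictly increasing")
  (means[-length(means)] + means[-1L]) / 2
}

#' Assign intensities to binder counts by cut-off
#'
#' The count is the number of boundaries lying below the intensity;
#' component 0 (below the first boundary) is the background, i.e. zero
#' bound myosins.
#'
#' @param intensities numeric vector.
#' @param boundaries sorted cut-off values.
#' @return integer vector of counts in 0..length(boundaries).
#' @export
assignCountsByCutoff <- function(intensities, boundaries) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be sorted increasing")
  }
  findInterval(intensities, boundaries)
}
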