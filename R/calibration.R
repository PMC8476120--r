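#' @include AllClasses.R AllGenerics.R
NULL

#' Fit an intensity histogram to a sum of Gaussians
#'
#' The fitted peak intensities of a kymograph cluster into roughly
#' equally spaced populations, one per number of bound myosins. This fits a
#' histogram of the intensities (Freedman-Diaconis bin width by default) to
#' a sum of `nComponents` Gaussians by nonlinear least squares, seeded from
#' k-means centres, and returns the components ordered by increasing mean.
#' Components whose weight falls below `lowWeight` are flagged rather than
#' dropped, so asking for more components than the data resolve degrades
#' gracefully.
#'
#' @param intensities numeric vector (>= 50 values).
#' @param nComponents number of Gaussian components (>= 1).
#' @param binWidth histogram bin width; default Freedman-Diaconis.
#' @param lowWeight weight below which a component is flagged (default 0.01).
#' @return list with elements means, sds, weights (each length
#'   nComponents, ordered by mean), lowWeight (logical flags), converged,
#'   rss, binWidth.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(1000, 100, 8), rnorm(1000, 200, 10))
#' fitIntensityMixture(x, 2)$means
#' @export
fitIntensityMixture <- function(intensities, nComponents, binWidth = NULL,
                                lowWeight = 0.01) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 50L) {
    stop("need at least 50 intensity values to calibrate")
  }
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L) stop("nComponents must be >= 1")
  if (length(intensities) < 3L * nComponents + 10L) {
    stop("fewer samples than needed for ", nComponents, " components")
  }

  if (is.null(binWidth)) {
    binWidth <- 2 * diff(quantile(intensities, c(0.25, 0.75), names = FALSE)) /
      length(intensities)^(1 / 3)
    ## Freedman-Diaconis under-bins strongly multimodal data; keep enough
    ## bins to leave the least-squares problem over-determined
    maxBw <- diff(range(intensities)) / max(30, 6 * nComponents)
    binWidth <- min(binWidth, maxBw)
    if (binWidth <= 0) binWidth <- diff(range(intensities)) / 30
  }
  breaks <- seq(min(intensities) - binWidth, max(intensities) + binWidth,
                by = binWidth)
  h <- graphics::hist(intensities, breaks = breaks, plot = FALSE)
  xs <- h$mids
  ys <- h$counts

  ## the fit is seeded twice -- from k-means clusters and from a linear
  ## grid anchored at the lowest intensity class (photometric linearity
  ## makes the class means near-multiples of the unit intensity) -- and the
  ## lower-RSS solution wins; k-means runs under a fixed internal seed so
  ## that the fit is a pure function of the data
  seeds <- list()
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(1711L)
  km <- try(suppressWarnings(
    kmeans(intensities, centers = nComponents, nstart = 5,
           iter.max = 50)), silent = TRUE)
  if (is.null(oldSeed)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", oldSeed, envir = globalenv())
  if (!inherits(km, "try-error") && length(unique(km$centers)) == nComponents) {
    ord <- order(km$centers)
    mu0 <- as.numeric(km$centers[ord])
    sd0 <- vapply(seq_len(nComponents), function(j) {
      v <- intensities[km$cluster == ord[j]]
      s <- sd(v)
      if (!is.finite(s) || s <= 0) binWidth else s
    }, numeric(1))
    n0 <- tabulate(match(km$cluster, ord), nComponents)
    seeds$kmeans <- list(mu = mu0, sd = sd0, n = n0)
  }
  m1 <- quantile(intensities, 0.1, names = FALSE)
  seeds$grid <- list(mu = m1 * seq_len(nComponents),
                     sd = rep(max(0.12 * m1, binWidth), nComponents),
                     n = rep(length(intensities) / nComponents, nComponents))
  qs <- quantile(intensities, (seq_len(nComponents) - 0.5) / nComponents,
                 names = FALSE)
  if (!any(duplicated(qs))) {
    seeds$quantile <- list(mu = qs,
                           sd = rep(diff(range(intensities)) /
                                      (4 * nComponents), nComponents),
                           n = rep(length(intensities) / nComponents,
                                   nComponents))
  }

  rng <- range(intensities)
  lower <- as.numeric(rbind(rep(0, nComponents),
                            rep(rng[1] - binWidth, nComponents),
                            rep(binWidth / 4, nComponents)))
  upper <- as.numeric(rbind(rep(2 * max(ys) + 10, nComponents),
                            rep(rng[2] + binWidth, nComponents),
                            rep(diff(rng) + binWidth, nComponents)))
  par <- NULL; rss <- Inf; converged <- FALSE
  for (sd_ in seeds) {
    A0 <- sd_$n * binWidth / (sd_$sd * sqrt(2 * pi))
    par0 <- pmin(pmax(as.numeric(rbind(A0, sd_$mu,
                                       pmax(sd_$sd, binWidth / 2))),
                      lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = par0,
      fn = function(p) ys - .multiGaussEval(p, xs),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    r <- sum(fit$fvec^2)
    if (r < rss) {
      rss <- r
      par <- fit$par
      converged <- fit$info %in% 1:4
    }
  }
  if (is.null(par)) {
    stop("mixture fit failed from every seeding")
  }

  k <- nComponents
  A <- par[3 * seq_len(k) - 2]
  mu <- par[3 * seq_len(k) - 1]
  s <- par[3 * seq_len(k)]
  ord <- order(mu)
  A <- A[ord]; mu <- mu[ord]; s <- s[ord]
  mass <- A * s * sqrt(2 * pi) / binWidth
  w <- mass / sum(mass)
  list(means = mu, sds = s, weights = w, lowWeight = w < lowWeight,
       converged = converged, rss = rss, binWidth = binWidth,
       nBins = length(xs))
}

#' Straight-line fit of component means against myosin count
#'
#' Ordinary least squares of mean intensity on the count index 1, 2, ...
#' Photometric linearity of the fluorophores makes this line straight; its
#' slope is the intensity of one myosin.
#'
#' @param means numeric vector of component mean intensities (>= 2).
#' @param counts count indices (default `seq_along(means)`).
#' @return list with slope, intercept, rSquared.
#' @examples
#' fitCalibrationLine(c(100, 200, 300))   # slope 100, intercept 0, r^2 = 1
#' @export
fitCalibrationLine <- function(means, counts = seq_along(means)) {
  if (length(means) < 2L) stop("need at least 2 component means")
  if (length(unique(means)) == 1L) stop("degenerate (identical) means")
  fit <- lm(means ~ counts)
  ss <- sum((means - mean(means))^2)
  r2 <- if (ss > 0) 1 - sum(fit$residuals^2) / ss else NA_real_
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       rSquared = r2)
}

#' Build a photometric calibration model
#'
#' Fits the intensity mixture, the calibration line, and constructs the
#' mean +/- 2 sd assignment bands. When `extendTo` exceeds the number of
#' fitted components, bands for higher counts are extrapolated from the
#' line fit (means) and from a straight-line trend of sd against count
#' (spreads); such bands are flagged.
#'
#' @param intensities numeric vector of fitted peak intensities.
#' @param nComponents Gaussian components to fit.
#' @param countOffset count of the first component: 1 (default) when peak
#'   intensities exclude background, 0 when the first component is the
#'   background population.
#' @param extendTo optional largest count to cover via extrapolated bands.
#' @param sourceId label.
#' @param ... passed to [fitIntensityMixture()].
#' @return A [CalibrationModel-class].
#' @export
calibrationModel <- function(intensities, nComponents, countOffset = 1L,
                             extendTo = NULL, sourceId = "calibration", ...) {
  mix <- fitIntensityMixture(intensities, nComponents, ...)
  calibrationModelFromComponents(mix$means, mix$sds, mix$weights,
                                 countOffset = countOffset,
                                 extendTo = extendTo, sourceId = sourceId)
}

#' Build a calibration model from explicit mixture components
#'
#' @param means,sds,weights ordered component parameters (weights optional).
#' @inheritParams calibrationModel
#' @return A [CalibrationModel-class].
#' @export
calibrationModelFromComponents <- function(means, sds,
                                           weights = rep(1 / length(means),
                                                         length(means)),
                                           countOffset = 1L, extendTo = NULL,
                                           sourceId = "calibration") {
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  k <- length(means)
  counts <- countOffset + seq_len(k) - 1L
  ## the background class (count 0) carries no photometric information for
  ## the line, which regresses intensity on the number of fluorophores >= 1
  lineIdx <- counts >= 1L
  if (sum(lineIdx) >= 2L) {
    ln <- fitCalibrationLine(means[lineIdx], counts[lineIdx])
  } else {
    ln <- list(slope = NA_real_, intercept = NA_real_, rSquared = NA_real_)
  }
  extrapolated <- rep(FALSE, k)
  if (!is.null(extendTo) && extendTo > max(counts)) {
    if (!is.finite(ln$slope)) stop("cannot extrapolate without a line fit")
    extra <- (max(counts) + 1L):as.integer(extendTo)
    exMeans <- ln$intercept + ln$slope * extra
    ## spread grows with count; extrapolate sd linearly in count
    if (sum(lineIdx) >= 2L && length(unique(sds[lineIdx])) > 1L) {
      sdfit <- lm(sds[lineIdx] ~ counts[lineIdx])
      exSds <- pmax(unname(coef(sdfit)[1L] + coef(sdfit)[2L] * extra),
                    min(sds))
    } else {
      exSds <- rep(sds[k], length(extra))
    }
    means <- c(means, exMeans)
    sds <- c(sds, exSds)
    weights <- c(weights, rep(0, length(extra)))
    extrapolated <- c(extrapolated, rep(TRUE, length(extra)))
    counts <- c(counts, extra)
  }
  bands <- cbind(means - 2 * sds, means + 2 * sds)
  colnames(bands) <- c("lo", "hi")
  new("CalibrationModel", componentMeans = means, componentSds = sds,
      componentWeights = weights, lineSlope = ln$slope,
      lineIntercept = ln$intercept,
      rSquared = if (is.na(ln$rSquared)) NA_real_ else
        max(0, min(1, ln$rSquared)),
      bands = bands, extrapolated = extrapolated,
      countOffset = as.integer(countOffset), sourceId = sourceId)
}

#' Assign an intensity to an integer myosin count
#'
#' An intensity inside exactly one mean +/- 2 sd band takes that band's
#' count; where bands overlap, the class with the nearest mean wins; an
#' intensity outside all bands is unassigned (NA), to be treated as missing
#' (not zero) downstream.
#'
#' @param intensity numeric vector.
#' @param model a [CalibrationModel-class].
#' @return integer vector, NA for unassigned intensities.
#' @examples
#' m <- calibrationModelFromComponents(c(100, 200), c(8, 10))
#' assignCount(c(100, 150, 205), m)   # 1, NA, 2
#' @export
assignCount <- function(intensity, model) {
  stopifnot(is(model, "CalibrationModel"))
  lo <- model@bands[, 1L]; hi <- model@bands[, 2L]
  mu <- model@componentMeans
  counts <- model@countOffset + seq_along(mu) - 1L
  vapply(intensity, function(v) {
    if (!is.finite(v)) return(NA_integer_)
    inBand <- which(v >= lo & v <= hi)
    if (length(inBand) == 1L) return(counts[inBand])
    if (length(inBand) > 1L) {
      return(counts[inBand[which.min(abs(mu[inBand] - v))]])
    }
    NA_integer_
  }, integer(1))
}

#' Serialise / restore a calibration model as JSON
#'
#' @param model a [CalibrationModel-class].
#' @param path JSON file path.
#' @return `path` (write) or a [CalibrationModel-class] (read).
#' @export
writeCalibration <- function(model, path) {
  stopifnot(is(model, "CalibrationModel"))
  jsonlite::write_json(list(
    componentMeans = model@componentMeans,
    componentSds = model@componentSds,
    componentWeights = model@componentWeights,
    lineSlope = model@lineSlope, lineIntercept = model@lineIntercept,
    rSquared = model@rSquared, extrapolated = model@extrapolated,
    countOffset = model@countOffset, sourceId = model@sourceId
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- calibrationModelFromComponents(
    x$componentMeans, x$componentSds, x$componentWeights,
    countOffset = x$countOffset, sourceId = x$sourceId)
  m@extrapolated <- as.logical(x$extrapolated)
  m
}
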