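#' @import methods
#' @importFrom stats coef dnorm dbeta dbinom lm mad median pnorm qnorm
#'   quantile rbeta rbinom rgamma rnorm runif sd setNames var kmeans
#'   binom.test pchisq
#' @importFrom utils head read.csv tail write.csv
#' @importFrom graphics hist
NULL

## ---------------------------------------------------------------------------
## Kymograph
## ---------------------------------------------------------------------------

#' Kymograph container
#'
#' A kymograph is a 2-D fluorescence intensity array with time (frames) as
#' rows and position along the filament (pixels) as columns, together with
#' its physical sampling: the frame interval in seconds and the pixel size
#' in nanometres.
#'
#' @slot intensity numeric matrix, frames x pixels.
#' @slot frameInterval numeric(1), seconds per frame.
#' @slot pixelNm numeric(1), nanometres per pixel.
#' @slot sourceId character(1), provenance label.
#'
#' @seealso [Kymograph()], [readKymograph()], [rollingBallSubtract()]
#' @exportClass Kymograph
setClass("Kymograph",
  representation(
    intensity = "matrix",
    frameInterval = "numeric",
    pixelNm = "numeric",
    sourceId = "character"
  )
)

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!is.numeric(object@intensity)) {
    msg <- c(msg, "intensity must be a numeric matrix")
  }
  if (nrow(object@intensity) < 2L) {
    msg <- c(msg, "a kymograph needs at least 2 frames (rows)")
  }
  if (ncol(object@intensity) < 8L) {
    msg <- c(msg, "a kymograph needs at least 8 pixels (columns)")
  }
  if (!all(is.finite(object@intensity))) {
    msg <- c(msg, "intensity values must all be finite")
  }
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0) {
    msg <- c(msg, "frameInterval must be a single positive number")
  }
  if (length(object@pixelNm) != 1L || object@pixelNm <= 0) {
    msg <- c(msg, "pixelNm must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' Create a Kymograph
#'
#' @param intensity numeric matrix (frames x pixels).
#' @param frameInterval seconds per frame (default 0.3).
#' @param pixelNm nanometres per pixel (default 126.4).
#' @param sourceId provenance string.
#' @return A [Kymograph-class] object.
#' @examples
#' k <- Kymograph(matrix(rnorm(200, 100, 5), 20, 10))
#' nFrames(k)
#' @export
Kymograph <- function(intensity, frameInterval = 0.3, pixelNm = 126.4,
                      sourceId = "kymograph") {
  new("Kymograph", intensity = intensity,
      frameInterval = as.numeric(frameInterval),
      pixelNm = as.numeric(pixelNm), sourceId = as.character(sourceId))
}

## ---------------------------------------------------------------------------
## Simulation parameters
## ---------------------------------------------------------------------------

#' Parameters of the cluster-dynamics simulator
#'
#' Governs the discrete-time stochastic model of myosin cluster occupancy on
#' a one-dimensional filament: single-myosin attachment at cluster edges,
#' independent per-myosin detachment set by ATP binding, an optional
#' concerted whole-cluster collapse channel, and nucleation of new
#' single-myosin regions.
#'
#' @slot pa per-region per-frame probability that one myosin attaches.
#' @slot pd per-frame per-myosin independent detachment probability.
#' @slot pc numeric vector; pc[n] is the per-frame probability of concerted
#'   collapse of a cluster of size n.
#' @slot pNuc per-frame probability of nucleating a new 1-myosin region.
#' @slot nucMinSepPx minimum separation (pixels) between a nucleation site
#'   and existing regions; closer attempts are rejected, since a new spot
#'   inside an existing diffraction-limited region is indistinguishable from
#'   an attachment, which the pa channel already models.
#' @slot nMaxSim hard cap on simulated cluster size.
#' @slot filamentLengthPx filament extent in pixels.
#' @slot siteSpacingNm centre-to-centre spacing of adjacent bound myosins
#'   (nm); default 38.5 nm, one actin pseudo-repeat.
#' @slot nFrames number of simulated frames.
#' @slot frameInterval seconds per frame.
#' @slot seed RNG seed.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    pa = "numeric", pd = "numeric", pc = "numeric", pNuc = "numeric",
    nucMinSepPx = "numeric",
    nMaxSim = "integer", filamentLengthPx = "numeric",
    siteSpacingNm = "numeric", nFrames = "integer",
    frameInterval = "numeric", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  prob1 <- function(p) length(p) == 1L && is.finite(p) && p >= 0 && p <= 1
  if (!prob1(object@pa)) msg <- c(msg, "pa must be a probability in [0,1]")
  if (!prob1(object@pd)) msg <- c(msg, "pd must be a probability in [0,1]")
  if (!prob1(object@pNuc)) msg <- c(msg, "pNuc must be a probability in [0,1]")
  if (length(object@pc) != object@nMaxSim ||
      any(!is.finite(object@pc) | object@pc < 0 | object@pc > 1)) {
    msg <- c(msg, "pc must be probabilities in [0,1], one per cluster size")
  }
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@siteSpacingNm <= 0) msg <- c(msg, "siteSpacingNm must be > 0")
  if (object@filamentLengthPx < 8) {
    msg <- c(msg, "filamentLengthPx must be >= 8")
  }
  ## the per-frame law allocates the attachment channel within the
  ## no-detachment mass, so pa may not exceed the smallest survival
  ## probability over admissible cluster sizes
  if (prob1(object@pa) && prob1(object@pd) && object@pd < 1) {
    surv <- (1 - object@pd)^object@nMaxSim
    if (object@pa > surv + 1e-12) {
      msg <- c(msg, sprintf(
        "pa (%.3g) must not exceed (1-pd)^nMaxSim = %.3g; lower pa, pd or nMaxSim",
        object@pa, surv))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Defaults correspond to the metastable study conditions: attachment
#' probability 0.15 per frame, detachment probability per myosin per frame
#' given by ATP binding at 0.1 uM ATP over a 0.3 s frame
#' (\code{1 - exp(-1.9 * 0.1 * 0.3) = 0.0554}), and no concerted collapse.
#'
#' @param pa per-region per-frame attachment probability.
#' @param pd per-myosin per-frame detachment probability.
#' @param pc collapse probability: a single number (applied to all cluster
#'   sizes >= 2), a numeric vector indexed by cluster size, or a function of
#'   cluster size. Default 0 (no concerted channel).
#' @param pNuc per-frame nucleation probability of a new 1-myosin region.
#' @param nucMinSepPx nucleation exclusion distance around existing regions
#'   in pixels (default 8).
#' @param nMaxSim hard cap on cluster size (default 12).
#' @param filamentLengthPx filament extent in pixels (default 128).
#' @param siteSpacingNm spacing of adjacent bound myosins (default 38.5 nm).
#' @param nFrames number of frames (default 300).
#' @param frameInterval seconds per frame (default 0.3).
#' @param seed RNG seed.
#' @return A [SimulationParams-class] object.
#' @examples
#' sp <- SimulationParams(pa = 0.15, pd = 0.0554, nFrames = 100, seed = 1)
#' @export
SimulationParams <- function(pa = 0.15,
                             pd = detachmentProbability(),
                             pc = 0,
                             pNuc = 0.02,
                             nucMinSepPx = 8,
                             nMaxSim = 12L,
                             filamentLengthPx = 128,
                             siteSpacingNm = 38.5,
                             nFrames = 300L,
                             frameInterval = 0.3,
                             seed = 1L) {
  nMaxSim <- as.integer(nMaxSim)
  if (is.function(pc)) {
    pcv <- vapply(seq_len(nMaxSim), pc, numeric(1))
  } else if (length(pc) == 1L) {
    ## a scalar collapse probability applies to clusters of two or more;
    ## a single myosin leaving is ordinary detachment, not a collapse
    pcv <- c(0, rep(pc, nMaxSim - 1L))
  } else {
    pcv <- rep_len(as.numeric(pc), nMaxSim)
  }
  new("SimulationParams", pa = as.numeric(pa), pd = as.numeric(pd),
      pc = pcv, pNuc = as.numeric(pNuc),
      nucMinSepPx = as.numeric(nucMinSepPx), nMaxSim = nMaxSim,
      filamentLengthPx = as.numeric(filamentLengthPx),
      siteSpacingNm = as.numeric(siteSpacingNm),
      nFrames = as.integer(nFrames),
      frameInterval = as.numeric(frameInterval), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Ground-truth trace
## ---------------------------------------------------------------------------

#' Ground-truth cluster-dynamics trace
#'
#' The full record of a simulation: one row per myosin (its region, lattice
#' site, attachment frame and detachment frame) plus an event log. Per-frame
#' occupancies and region centres are derived views ([occupancySeries()]).
#'
#' @slot myosins data.frame with columns myosinId, regionId, site,
#'   attachFrame, detachFrame (NA while still bound at the last frame).
#' @slot events data.frame with columns frame, event
#'   (nucleate/attach/detach/collapse), regionId, myosinId, site.
#' @slot nFrames integer(1).
#' @slot params the [SimulationParams-class] used.
#' @exportClass GroundTruthTrace
setClass("GroundTruthTrace",
  representation(
    myosins = "data.frame",
    events = "data.frame",
    nFrames = "integer",
    params = "SimulationParams"
  )
)

setValidity("GroundTruthTrace", function(object) {
  msg <- character()
  need <- c("myosinId", "regionId", "site", "attachFrame", "detachFrame")
  if (!all(need %in% names(object@myosins))) {
    msg <- c(msg, "myosins must have myosinId, regionId, site, attachFrame, detachFrame")
  } else if (nrow(object@myosins)) {
    ok <- is.na(object@myosins$detachFrame) |
      object@myosins$detachFrame > object@myosins$attachFrame
    if (!all(ok)) msg <- c(msg, "detachFrame must exceed attachFrame")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Imaging parameters
## ---------------------------------------------------------------------------

#' Parameters of the kymograph renderer
#'
#' @slot pixelNm nanometres per pixel (126.4 as imaged after 2x2 binning).
#' @slot psfSigmaNm Gaussian point-spread sigma in nm.
#' @slot unitIntensity mean integrated counts contributed by one myosin.
#' @slot unitIntensityCv coefficient of variation of per-myosin intensity;
#'   each myosin's brightness is drawn once, at attachment.
#' @slot backgroundOffset constant background counts.
#' @slot noiseSd additive Gaussian noise sd (counts).
#' @slot seed RNG seed for brightness draws and noise.
#' @exportClass ImagingParams
setClass("ImagingParams",
  representation(
    pixelNm = "numeric", psfSigmaNm = "numeric", unitIntensity = "numeric",
    unitIntensityCv = "numeric", backgroundOffset = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("ImagingParams", function(object) {
  msg <- character()
  if (object@pixelNm <= 0) msg <- c(msg, "pixelNm must be > 0")
  if (object@psfSigmaNm <= 0) msg <- c(msg, "psfSigmaNm must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@unitIntensity <= 0) msg <- c(msg, "unitIntensity must be > 0")
  if (object@unitIntensityCv < 0) msg <- c(msg, "unitIntensityCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct imaging parameters
#'
#' @param pixelNm nm per pixel, default 126.4.
#' @param psfSigmaNm effective Gaussian PSF sigma (nm), default 100.
#' @param unitIntensity integrated counts per myosin, default 100.
#' @param unitIntensityCv brightness coefficient of variation, default 0.1.
#' @param backgroundOffset background counts, default 10.
#' @param noiseSd additive Gaussian noise sd, default 5.
#' @param seed RNG seed.
#' @return An [ImagingParams-class] object.
#' @export
ImagingParams <- function(pixelNm = 126.4, psfSigmaNm = 100,
                          unitIntensity = 100, unitIntensityCv = 0.1,
                          backgroundOffset = 10, noiseSd = 5, seed = 1L) {
  new("ImagingParams", pixelNm = as.numeric(pixelNm),
      psfSigmaNm = as.numeric(psfSigmaNm),
      unitIntensity = as.numeric(unitIntensity),
      unitIntensityCv = as.numeric(unitIntensityCv),
      backgroundOffset = as.numeric(backgroundOffset),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Peak table
## ---------------------------------------------------------------------------

#' Table of fitted fluorescence peaks
#'
#' One row per fitted Gaussian peak per frame. `integral` is the photometric
#' quantity carried through the pipeline (amplitude * sigma * sqrt(2*pi)),
#' since clusters broaden slightly as they spread along the filament.
#'
#' @slot peaks data.frame with columns frame, positionPx, amplitude,
#'   sigmaPx, integral, fitRss, converged.
#' @slot threshold detection threshold used (counts).
#' @slot sourceId source kymograph id.
#' @slot nFrames total frames in the source kymograph (needed to decide
#'   whether a disappearing track ends inside the recording).
#' @exportClass PeakTable
setClass("PeakTable",
  representation(
    peaks = "data.frame",
    threshold = "numeric",
    sourceId = "character",
    nFrames = "integer"
  )
)

setValidity("PeakTable", function(object) {
  msg <- character()
  need <- c("frame", "positionPx", "amplitude", "sigmaPx", "integral",
            "fitRss", "converged")
  if (!all(need %in% names(object@peaks))) {
    msg <- c(msg, paste("peaks must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(object@peaks) > 1L) {
    o <- order(object@peaks$frame, object@peaks$positionPx)
    if (!identical(o, seq_len(nrow(object@peaks)))) {
      msg <- c(msg, "peaks must be sorted by (frame, positionPx)")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Calibration model
## ---------------------------------------------------------------------------

#' Photometric calibration from intensity to myosin count
#'
#' Per-kymograph mapping from fluorescence intensity to an integer number of
#' bound myosins. Component k of the underlying Gaussian mixture corresponds
#' to count `countOffset + k - 1`; its assignment band is mean +/- 2 sd.
#' A straight-line fit of mean intensity against count summarises photometric
#' linearity and, optionally, extends bands to counts beyond those directly
#' resolved in the histogram (such bands are flagged `extrapolated`).
#'
#' @slot componentMeans increasing intensity means, one per count class.
#' @slot componentSds per-class sds.
#' @slot componentWeights mixture weights (may contain flagged low weights).
#' @slot lineSlope,lineIntercept,rSquared straight-line fit of mean vs count.
#' @slot bands k x 2 matrix of assignment intervals (mean -/+ 2 sd).
#' @slot extrapolated logical per class; TRUE when the band comes from the
#'   line fit rather than a fitted mixture component.
#' @slot countOffset integer count of the first component (0 when the first
#'   component is background, 1 when it is a single myosin).
#' @slot sourceId character label.
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(
    componentMeans = "numeric",
    componentSds = "numeric",
    componentWeights = "numeric",
    lineSlope = "numeric",
    lineIntercept = "numeric",
    rSquared = "numeric",
    bands = "matrix",
    extrapolated = "logical",
    countOffset = "integer",
    sourceId = "character"
  )
)

setValidity("CalibrationModel", function(object) {
  msg <- character()
  m <- object@componentMeans
  if (length(m) && any(diff(m) <= 0)) {
    msg <- c(msg, "componentMeans must be strictly increasing")
  }
  if (length(object@componentSds) != length(m)) {
    msg <- c(msg, "componentSds must match componentMeans in length")
  }
  if (nrow(object@bands) != length(m) || ncol(object@bands) != 2L) {
    msg <- c(msg, "bands must be a k x 2 matrix")
  } else if (nrow(object@bands) && any(object@bands[, 2] < object@bands[, 1])) {
    msg <- c(msg, "each band must be an ordered interval")
  }
  if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1)) {
    msg <- c(msg, "rSquared must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Region tracks
## ---------------------------------------------------------------------------

#' Linked active-region tracks
#'
#' @slot tracks data.frame with columns trackId, frame, positionPx,
#'   integral, count, gap (TRUE for interpolated gap frames).
#' @slot maxLinkDistancePx linking radius used.
#' @slot maxGapFrames maximum bridged gap used.
#' @slot sourceId source kymograph id.
#' @slot nFrames total frames in the source kymograph.
#' @exportClass RegionTrackSet
setClass("RegionTrackSet",
  representation(
    tracks = "data.frame",
    maxLinkDistancePx = "numeric",
    maxGapFrames = "integer",
    sourceId = "character",
    nFrames = "integer"
  )
)

setValidity("RegionTrackSet", function(object) {
  msg <- character()
  need <- c("trackId", "frame", "positionPx", "integral", "gap")
  if (!all(need %in% names(object@tracks))) {
    msg <- c(msg, paste("tracks must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(object@tracks)) {
    byTrack <- split(object@tracks$frame, object@tracks$trackId)
    if (any(!vapply(byTrack, function(f) all(diff(f) > 0), logical(1)))) {
      msg <- c(msg, "frames must be strictly increasing within a track")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Transition counts and matrix
## ---------------------------------------------------------------------------

#' Tallied one-frame cluster-size transitions
#'
#' `counts[i, j+1]` is the number of observed transitions from cluster size i
#' (rows, 1..nMax) to size j (columns, 0..nMax) between consecutive observed
#' frames, i != j. `exposures[i]` counts all observed consecutive-frame pairs
#' starting at size i, including i -> i stays, so that per-frame
#' (unconditional) probabilities can be formed as counts / exposures.
#' Pairs containing a missing count or a size above nMax are discarded.
#'
#' @slot counts integer matrix nMax x (nMax + 1), dimnames sizes.
#' @slot exposures numeric vector of length nMax.
#' @slot nMax largest analysed cluster size.
#' @slot perSource named list of per-kymograph (counts, exposures) pairs,
#'   kept so that across-kymograph SEMs can be formed.
#' @exportClass TransitionCounts
setClass("TransitionCounts",
  representation(
    counts = "matrix",
    exposures = "numeric",
    nMax = "integer",
    perSource = "list"
  )
)

setValidity("TransitionCounts", function(object) {
  msg <- character()
  n <- object@nMax
  if (nrow(object@counts) != n || ncol(object@counts) != n + 1L) {
    msg <- c(msg, "counts must be nMax x (nMax+1)")
  } else {
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(diag(object@counts[, -1, drop = FALSE]) != 0)) {
      msg <- c(msg, "diagonal (i -> i) entries must be zero")
    }
  }
  if (length(object@exposures) != n) {
    msg <- c(msg, "exposures must have length nMax")
  }
  if (length(msg)) msg else TRUE
})

#' Cluster-size transition probability matrix
#'
#' Rows are the starting cluster size (1..nMax), columns the final size
#' (0..nMax). When `conditional` is TRUE the entries are probabilities of
#' moving to size j given that the size changed (the display convention:
#' zero diagonal, observed rows sum to 1); when FALSE they are per-frame
#' probabilities (counts / exposures), whose diagonal is also zero but whose
#' rows sum to the per-frame probability of any change.
#'
#' @slot probabilities numeric matrix nMax x (nMax+1).
#' @slot sem across-kymograph standard errors (NA when a single source).
#' @slot rowTotals observation counts per row (changes for conditional,
#'   exposures for per-frame).
#' @slot conditional logical flag.
#' @slot nMax integer.
#' @slot nSources number of kymographs contributing.
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
  representation(
    probabilities = "matrix",
    sem = "matrix",
    rowTotals = "numeric",
    conditional = "logical",
    nMax = "integer",
    nSources = "integer"
  )
)

setValidity("TransitionMatrix", function(object) {
  msg <- character()
  p <- object@probabilities
  if (any(p < -1e-12 | p > 1 + 1e-12)) {
    msg <- c(msg, "probabilities must lie in [0,1]")
  }
  if (any(abs(diag(p[, -1, drop = FALSE])) > 1e-12)) {
    msg <- c(msg, "the central diagonal must be zero")
  }
  if (isTRUE(object@conditional)) {
    rs <- rowSums(p)
    bad <- object@rowTotals > 0 & abs(rs - 1) > 1e-9
    if (any(bad)) msg <- c(msg, "observed rows of a conditional matrix must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RJMCMC containers
## ---------------------------------------------------------------------------

#' Hyperparameters of the normal-mixture hierarchical model
#'
#' Weakly informative hierarchy for univariate normal mixtures with an
#' unknown number of components: means are a priori N(xi, 1/kappa),
#' inverse variances Gamma(alpha, beta) with beta itself Gamma(g, h),
#' weights Dirichlet(delta), and the component count uniform on 1..kMax.
#'
#' @slot alpha shape of the inverse-variance prior (2).
#' @slot g shape of the beta hyperprior (0.2).
#' @slot h rate of the beta hyperprior (10 / R^2 with R the data range).
#' @slot xi mean-prior centre (data mid-range).
#' @slot kappa mean-prior precision (1 / R^2).
#' @slot delta Dirichlet weight parameter (1).
#' @slot kMax maximum number of components.
#' @slot dataRange numeric(1), R.
#' @exportClass MixtureHyperParams
setClass("MixtureHyperParams",
  representation(
    alpha = "numeric", g = "numeric", h = "numeric", xi = "numeric",
    kappa = "numeric", delta = "numeric", kMax = "integer",
    dataRange = "numeric"
  )
)

setValidity("MixtureHyperParams", function(object) {
  msg <- character()
  pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
  for (s in c("alpha", "g", "h", "kappa", "delta")) {
    if (!pos(slot(object, s))) msg <- c(msg, paste(s, "must be > 0"))
  }
  if (object@kMax < 1L) msg <- c(msg, "kMax must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A reversible-jump mixture chain
#'
#' Stores the per-sweep component count and the ordered component
#' parameters, NA-padded to kMax columns. Allocations are not retained.
#'
#' @slot k integer vector, components per sweep.
#' @slot means,sds,weights nSweeps x kMax matrices, NA beyond k.
#' @slot beta numeric vector of the variance-rate hyperparameter per sweep.
#' @slot hyper the [MixtureHyperParams-class] used.
#' @slot seed RNG seed.
#' @slot moveRates named numeric vector of acceptance rates.
#' @exportClass MixtureChain
setClass("MixtureChain",
  representation(
    k = "integer", means = "matrix", sds = "matrix", weights = "matrix",
    beta = "numeric", hyper = "MixtureHyperParams", seed = "integer",
    moveRates = "numeric"
  )
)

#' Posterior component summary conditional on a component count
#'
#' @slot components data.frame with columns component, mean, sd, variance,
#'   weight (posterior means conditional on k = kCondition, averaged across
#'   chains).
#' @slot kCondition the conditioning component count.
#' @slot occupancy fraction of retained sweeps with k = kCondition.
#' @slot convergence between/within-chain ratio (max over components).
#' @slot nChains chains averaged.
#' @exportClass ComponentSummary
setClass("ComponentSummary",
  representation(
    components = "data.frame",
    kCondition = "integer",
    occupancy = "numeric",
    convergence = "numeric",
    nChains = "integer"
  )
)
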