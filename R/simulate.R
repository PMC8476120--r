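#' @include AllClasses.R AllGenerics.R
NULL

## nominal camera pixel (nm) used to express filament length in pixels on the
## myosin lattice; the renderer may use a different pixel size
.NOMINAL_PIXEL_NM <- 126.4

## simple growable record set: preallocated columns with capacity doubling
.newRecorder <- function(cols, init = 256L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$cap <- init
  for (cl in names(cols)) env[[cl]] <- vector(cols[[cl]], init)
  env$cols <- names(cols)
  env
}

.recAdd <- function(env, ...) {
  vals <- list(...)
  i <- env$n + 1L
  if (i > env$cap) {
    env$cap <- env$cap * 2L
    for (cl in env$cols) {
      v <- env[[cl]]
      length(v) <- env$cap
      env[[cl]] <- v
    }
  }
  for (cl in names(vals)) env[[cl]][i] <- vals[[cl]]
  env$n <- i
  invisible(env)
}

.recDf <- function(env) {
  out <- lapply(env$cols, function(cl) env[[cl]][seq_len(env$n)])
  names(out) <- env$cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Analytic one-frame transition law of the simulator
#'
#' Returns the exact per-frame transition kernel of the cluster-occupancy
#' model: within one frame a region either collapses (probability
#' \code{pc(n)}), gains one myosin (probability \code{pa}), loses \code{d}
#' myosins (binomial, \code{choose(n, d) pd^d (1-pd)^(n-d)}), or is
#' unchanged. Attachment and detachment are frame-exclusive channels; the
#' attachment channel is carved out of the no-detachment mass so the marginal
#' detachment law stays exactly binomial.
#'
#' @param params a [SimulationParams-class].
#' @param nMax number of starting sizes to tabulate (rows 1..nMax); defaults
#'   to \code{nMaxSim - 1} so the attachment column stays in range.
#' @return numeric matrix with rows starting size 1..nMax and columns final
#'   size 0..(nMax+1), each row summing to 1.
#' @examples
#' k <- transitionKernel(SimulationParams(pa = 0.15, pd = 0.0554))
#' rowSums(k)
#' @export
transitionKernel <- function(params, nMax = params@nMaxSim - 1L) {
  stopifnot(is(params, "SimulationParams"), nMax >= 1L,
            nMax < params@nMaxSim)
  pa <- params@pa; pd <- params@pd
  out <- matrix(0, nMax, nMax + 2L,
                dimnames = list(start = as.character(seq_len(nMax)),
                                final = as.character(0:(nMax + 1L))))
  for (i in seq_len(nMax)) {
    pc <- params@pc[i]
    detach <- dbinom(0:i, i, pd)            # d = 0..i
    out[i, as.character(i - (1:i))] <- (1 - pc) * detach[2:(i + 1L)]
    out[i, "0"] <- pc + (1 - pc) * detach[i + 1L]
    out[i, as.character(i + 1L)] <- (1 - pc) * pa
    out[i, as.character(i)] <- (1 - pc) * (detach[1L] - pa)
  }
  out
}

#' Simulate cluster occupancy dynamics on a filament
#'
#' Discrete-time Markov simulation of myosin clusters. Frames 1..nFrames are
#' occupancy snapshots; events drawn at frame f are stamped f and take
#' effect at frame f + 1. Per region and frame, one of four frame-exclusive
#' outcomes occurs: concerted collapse with probability \code{pc(n)};
#' detachment of \code{d >= 1} myosins (binomial per-myosin law, detached
#' myosins chosen uniformly); attachment of one myosin at the left or right
#' cluster edge with equal probability (marginal probability \code{pa});
#' or no change. New 1-myosin regions nucleate with probability \code{pNuc}
#' per frame at a uniform random lattice position away from the filament
#' ends. Regions reaching zero occupancy are closed.
#'
#' @param params a [SimulationParams-class].
#' @param initialSizes optional integer vector of cluster sizes present at
#'   frame 1, placed evenly along the filament.
#' @return A [GroundTruthTrace-class].
#' @examples
#' tr <- simulateClusterDynamics(SimulationParams(nFrames = 50, seed = 7),
#'                               initialSizes = 3)
#' head(eventLog(tr))
#' @export
simulateClusterDynamics <- function(params, initialSizes = integer()) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  set.seed(params@seed)

  spacing <- params@siteSpacingNm
  nSites <- max(16L, floor(params@filamentLengthPx * .NOMINAL_PIXEL_NM / spacing))
  margin <- ceiling(500 / spacing)   # keep clusters clear of the image edge
  loSite <- margin + 1L
  hiSite <- nSites - margin

  myo <- .newRecorder(list(myosinId = "integer", regionId = "integer",
                           site = "integer", attachFrame = "integer",
                           detachFrame = "integer"))
  ev <- .newRecorder(list(frame = "integer", event = "character",
                          regionId = "integer", myosinId = "integer",
                          site = "integer"))

  nextMyosin <- 1L
  nextRegion <- 1L
  ## active regions: list of list(id, sites (int), myo (int)) kept in id order
  regions <- list()

  addMyosin <- function(rid, site, frame, event) {
    id <- nextMyosin
    nextMyosin <<- nextMyosin + 1L
    .recAdd(myo, myosinId = id, regionId = rid, site = site,
            attachFrame = frame, detachFrame = NA_integer_)
    .recAdd(ev, frame = frame, event = event, regionId = rid,
            myosinId = id, site = site)
    id
  }

  ## initial regions appear at frame 1 (logged as nucleation/attachment at
  ## frame 0 would be outside the record; stamp them frame 1 with effect
  ## already present at frame 1)
  if (length(initialSizes)) {
    pos <- round(seq(loSite, hiSite,
                     length.out = length(initialSizes) + 2L))[-c(1L, length(initialSizes) + 2L)]
    for (r in seq_along(initialSizes)) {
      rid <- nextRegion; nextRegion <- nextRegion + 1L
      n0 <- as.integer(initialSizes[r])
      sites <- pos[r] + seq_len(n0) - 1L
      ids <- integer(n0)
      for (s in seq_len(n0)) {
        id <- nextMyosin; nextMyosin <- nextMyosin + 1L
        .recAdd(myo, myosinId = id, regionId = rid, site = sites[s],
                attachFrame = 1L, detachFrame = NA_integer_)
        ids[s] <- id
      }
      regions[[length(regions) + 1L]] <- list(id = rid, sites = sites, myo = ids)
    }
  }

  pa <- params@pa; pd <- params@pd
  survival <- (1 - pd)^(1:params@nMaxSim)

  closeMyosins <- function(ids, frame) {
    ## detachFrame is the first frame the myosin is absent
    idx <- match(ids, myo$myosinId[seq_len(myo$n)])
    myo$detachFrame[idx] <- frame + 1L
  }

  for (f in seq_len(params@nFrames - 1L)) {
    keep <- logical(length(regions))
    for (r in seq_along(regions)) {
      reg <- regions[[r]]
      n <- length(reg$sites)
      if (runif(1) < params@pc[n]) {
        closeMyosins(reg$myo, f)
        .recAdd(ev, frame = f, event = "collapse", regionId = reg$id,
                myosinId = NA_integer_, site = NA_integer_)
        keep[r] <- FALSE
        next
      }
      d <- rbinom(1L, n, pd)
      if (d == 0L) {
        if (n < params@nMaxSim && runif(1) < pa / survival[n]) {
          site <- if (runif(1) < 0.5) min(reg$sites) - 1L else max(reg$sites) + 1L
          id <- addMyosin(reg$id, site, f, "attach")
          ## attachment takes effect at the next frame; adjust attachFrame
          myo$attachFrame[myo$n] <- f + 1L
          reg$sites <- c(reg$sites, site)
          reg$myo <- c(reg$myo, id)
        }
        regions[[r]] <- reg
        keep[r] <- TRUE
      } else {
        gone <- if (d == n) seq_len(n) else sample.int(n, d)
        closeMyosins(reg$myo[gone], f)
        for (g in gone) {
          .recAdd(ev, frame = f, event = "detach", regionId = reg$id,
                  myosinId = reg$myo[g], site = reg$sites[g])
        }
        if (d == n) {
          keep[r] <- FALSE
        } else {
          reg$sites <- reg$sites[-gone]
          reg$myo <- reg$myo[-gone]
          regions[[r]] <- reg
          keep[r] <- TRUE
        }
      }
    }
    regions <- regions[keep]
    if (runif(1) < params@pNuc) {
      site <- loSite + sample.int(hiSite - loSite + 1L, 1L) - 1L
      ## a nucleation landing within the diffraction-limited footprint of an
      ## existing region is not a resolvable new region; reject the attempt
      minSepSites <- params@nucMinSepPx * .NOMINAL_PIXEL_NM / spacing
      clear <- !length(regions) ||
        all(vapply(regions, function(rg) {
          min(abs(rg$sites - site)) >= minSepSites
        }, logical(1)))
      if (clear) {
        rid <- nextRegion; nextRegion <- nextRegion + 1L
        id <- addMyosin(rid, site, f, "nucleate")
        myo$attachFrame[myo$n] <- f + 1L
        regions[[length(regions) + 1L]] <- list(id = rid, sites = site,
                                                myo = id)
      }
    }
  }

  new("GroundTruthTrace", myosins = .recDf(myo), events = .recDf(ev),
      nFrames = params@nFrames, params = params)
}

#' Per-region occupancy time series
#'
#' Derives, for each region, the integer myosin count at every frame of its
#' lifetime. If a region dies before the end of the recording, a terminal 0
#' is appended (the complete-detachment transition is observable); a region
#' still alive at the last frame is right-censored. Regions observed for
#' fewer than \code{minFrames} frames are dropped, mirroring the conditioning
#' applied to image-derived tracks.
#'
#' @param trace a [GroundTruthTrace-class].
#' @param minFrames minimum observed frames for a region to contribute
#'   (default 2).
#' @return named list of integer vectors, one per region.
#' @export
occupancySeries <- function(trace, minFrames = 2L) {
  stopifnot(is(trace, "GroundTruthTrace"))
  m <- trace@myosins
  if (!nrow(m)) return(list())
  nF <- trace@nFrames
  out <- list()
  for (rid in unique(m$regionId)) {
    mr <- m[m$regionId == rid, , drop = FALSE]
    first <- min(mr$attachFrame)
    if (first > nF) next
    lastBound <- max(ifelse(is.na(mr$detachFrame), nF, mr$detachFrame - 1L))
    lastBound <- min(lastBound, nF)
    frames <- first:lastBound
    cnt <- vapply(frames, function(f) {
      sum(mr$attachFrame <= f &
            (is.na(mr$detachFrame) | mr$detachFrame > f))
    }, integer(1))
    if (lastBound < nF) cnt <- c(cnt, 0L)   # terminal complete detachment
    ## a region occupied for fewer than minFrames frames contributes nothing,
    ## matching the conditioning applied to image-derived tracks
    if (length(frames) >= minFrames) out[[as.character(rid)]] <- cnt
  }
  out
}

#' Per-frame region table
#'
#' Long-format view of a trace: one row per region per frame with its
#' occupancy and intensity-weighted centre position in nanometres.
#'
#' @param trace a [GroundTruthTrace-class].
#' @return data.frame with columns frame, regionId, count, centreNm.
#' @export
occupancyTable <- function(trace) {
  stopifnot(is(trace, "GroundTruthTrace"))
  m <- trace@myosins
  if (!nrow(m)) {
    return(data.frame(frame = integer(), regionId = integer(),
                      count = integer(), centreNm = numeric()))
  }
  spacing <- trace@params@siteSpacingNm
  rows <- list()
  for (f in seq_len(trace@nFrames)) {
    live <- m$attachFrame <= f & (is.na(m$detachFrame) | m$detachFrame > f)
    if (!any(live)) next
    mf <- m[live, , drop = FALSE]
    agg <- tapply(mf$site, mf$regionId, function(s) c(length(s), mean(s)))
    rid <- as.integer(names(agg))
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f, regionId = rid,
      count = vapply(agg, `[`, numeric(1), 1L),
      centreNm = vapply(agg, `[`, numeric(1), 2L) * spacing)
  }
  out <- do.call(rbind, rows)
  out$count <- as.integer(out$count)
  rownames(out) <- NULL
  out
}

#' Render a ground-truth trace as a noisy kymograph
#'
#' Each frame is the sum over bound myosins of one-dimensional Gaussian
#' point-spread profiles integrated over pixel boundaries (so total flux is
#' conserved), plus a constant background offset and i.i.d. additive
#' Gaussian noise; the result is clipped at zero. Each myosin's integrated
#' brightness is drawn once, at attachment, from a normal distribution with
#' mean \code{unitIntensity} and coefficient of variation
#' \code{unitIntensityCv}, modelling a fixed fluorophore brightness.
#'
#' @param trace a [GroundTruthTrace-class].
#' @param imaging an [ImagingParams-class].
#' @param sourceId provenance label for the kymograph.
#' @return A [Kymograph-class] with frames as rows.
#' @export
renderKymograph <- function(trace, imaging = ImagingParams(),
                            sourceId = "synthetic") {
  stopifnot(is(trace, "GroundTruthTrace"), is(imaging, "ImagingParams"))
  validObject(imaging)
  set.seed(imaging@seed)
  nF <- trace@nFrames
  W <- max(8L, as.integer(ceiling(trace@params@filamentLengthPx)))
  img <- matrix(0, nF, W)

  m <- trace@myosins
  if (nrow(m)) {
    bright <- imaging@unitIntensity *
      pmax(0, 1 + imaging@unitIntensityCv * rnorm(nrow(m)))
    spacing <- trace@params@siteSpacingNm
    sigmaPx <- imaging@psfSigmaNm / imaging@pixelNm
    edges <- 0:W   # pixel p covers (p-1, p] in pixel units
    for (i in seq_len(nrow(m))) {
      f1 <- m$attachFrame[i]
      f2 <- if (is.na(m$detachFrame[i])) nF else m$detachFrame[i] - 1L
      if (f1 > nF || f2 < f1) next
      f2 <- min(f2, nF)
      muPx <- m$site[i] * spacing / imaging@pixelNm
      prof <- bright[i] * diff(pnorm(edges, mean = muPx, sd = sigmaPx))
      img[f1:f2, ] <- img[f1:f2, ] + rep(prof, each = f2 - f1 + 1L)
    }
  }

  img <- img + imaging@backgroundOffset
  if (imaging@noiseSd > 0) {
    img <- img + matrix(rnorm(length(img), sd = imaging@noiseSd), nF, W)
  }
  img[img < 0] <- 0
  Kymograph(img, frameInterval = trace@params@frameInterval,
            pixelNm = imaging@pixelNm, sourceId = sourceId)
}

#' Generate a reproducible synthetic dataset
#'
#' Independent replicate simulations rendered as kymographs, with
#' per-replicate seeds derived deterministically from a master seed.
#'
#' @param params a [SimulationParams-class] (its seed is overridden per
#'   replicate).
#' @param imaging an [ImagingParams-class] (seed likewise overridden).
#' @param nKymographs number of replicates.
#' @param seed master seed.
#' @param initialSizes optional initial cluster sizes passed to each
#'   replicate.
#' @return list of length nKymographs; each element is a list with elements
#'   `kymograph` and `trace`.
#' @export
generateDataset <- function(params, imaging = ImagingParams(),
                            nKymographs = 1L, seed = 1L,
                            initialSizes = integer()) {
  stopifnot(nKymographs >= 1L)
  lapply(seq_len(nKymographs), function(r) {
    simSeed <- as.integer((seed + r * 7919) %% .Machine$integer.max)
    imgSeed <- as.integer((seed + r * 104729 + 1) %% .Machine$integer.max)
    p <- params; p@seed <- simSeed
    im <- imaging; im@seed <- imgSeed
    tr <- simulateClusterDynamics(p, initialSizes = initialSizes)
    list(kymograph = renderKymograph(tr, im,
                                     sourceId = sprintf("sim%02d", r)),
         trace = tr)
  })
}
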