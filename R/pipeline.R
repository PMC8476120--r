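#' @include AllClasses.R AllGenerics.R
NULL

.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Build a pipeline configuration
#'
#' All defaults equal the study's stated values where one exists: rolling
#' ball radius 50 px, frame interval 0.3 s, pixel 126.4 nm, largest
#' analysed cluster size 6, ATP-binding rate constant 1.9 per uM per s at
#' 0.1 uM ATP, attachment probability 0.15. Any subset can be overridden
#' through `...` (named nested lists, merged over the defaults).
#'
#' @param ... named overrides, e.g.
#'   `simulate = list(nKymographs = 5), imaging = list(noiseSd = 0)`.
#' @param seed master seed governing every stochastic stage.
#' @return nested list understood by [runPipeline()].
#' @export
pipelineConfig <- function(..., seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    simulate = list(
      enabled = TRUE, nKymographs = 4L, pa = 0.15, pd = NULL, pc = 0,
      pNuc = 0.02, nucMinSepPx = 8, nFrames = 400L, filamentLengthPx = 128,
      nMaxSim = 12L, initialSizes = c(2L)),
    input = list(paths = character(), frameInterval = 0.3, pixelNm = 126.4),
    imaging = list(pixelNm = 126.4, psfSigmaNm = 100, unitIntensity = 100,
                   unitIntensityCv = 0.1, backgroundOffset = 10,
                   noiseSd = 5),
    preprocess = list(radiusPx = 50),
    peaks = list(threshold = NULL, minSeparationPx = 3,
                 sigmaBounds = c(0.5, 4)),
    calibration = list(nComponents = 6L, countOffset = 1L,
                       minLineR2 = 0.9, maxSdFrac = 0.6),
    tracking = list(maxLinkDistancePx = 4, maxGapFrames = 1L),
    transitions = list(nMax = 6L, kT = 1.9, atpuM = 0.1, frameS = 0.3),
    rjmcmc = list(enabled = FALSE, kMax = 7L, nChains = 4L,
                  nSweeps = 2000L))
  cfg <- .mergeConfig(defaults, list(...))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config configuration list (write).
#' @return configuration list (read) or `path` (write).
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(pipelineConfig, c(user[setdiff(names(user), "seed")],
                            list(seed = if (is.null(user$seed)) 1L else
                              user$seed)))
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## fit the largest supportable calibration for one kymograph: try the
## configured component count, backing off while the mixture cannot be
## resolved into strictly increasing, photometrically linear classes.
## Under-fitting (fewer components than populated count classes) shows up as
## merged classes: component widths comparable to the class spacing and an
## intercept far from zero; both are rejected.
.autoCalibration <- function(integrals, cfg, nMax, sourceId) {
  maxSdFrac <- if (is.null(cfg$maxSdFrac)) 0.6 else cfg$maxSdFrac
  best <- NULL
  bestBic <- Inf
  for (k in seq(2L, cfg$nComponents)) {
    mix <- try(suppressWarnings(fitIntensityMixture(integrals, k)),
               silent = TRUE)
    if (inherits(mix, "try-error")) next
    mu <- mix$means; sds <- mix$sds; w <- mix$weights
    ## clusters larger than the highest fitted class form a sparse
    ## high-intensity tail that the last component absorbs as a very wide
    ## Gaussian; such trailing components carry no class information and
    ## are dropped (their counts are covered by line-extrapolated bands)
    while (length(mu) > 2L &&
           sds[length(sds)] > maxSdFrac * min(diff(mu))) {
      mu <- mu[-length(mu)]; sds <- sds[-length(sds)]; w <- w[-length(w)]
    }
    model <- try(calibrationModelFromComponents(
      mu, sds, w, countOffset = cfg$countOffset,
      extendTo = nMax, sourceId = sourceId), silent = TRUE)
    if (inherits(model, "try-error")) next
    if (length(mu) >= 3L && (!is.finite(model@rSquared) ||
                             model@rSquared < cfg$minLineR2)) next
    if (max(sds) > maxSdFrac * min(diff(mu))) next
    if (is.finite(model@lineSlope) &&
        abs(model@lineIntercept) > 0.4 * abs(model@lineSlope)) next
    bic <- mix$nBins * log(max(mix$rss, 1e-12) / mix$nBins) +
      3 * k * log(mix$nBins)
    if (bic < bestBic) {
      bestBic <- bic
      best <- model
    }
  }
  if (is.null(best)) {
    stop("calibration failed for ", sourceId,
         ": intensity histogram could not be resolved into count classes")
  }
  best
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> rolling-ball subtraction -> per-frame
#' multi-Gaussian peak fitting -> per-kymograph intensity calibration ->
#' track linking -> count series -> transition matrices -> collapse curve
#' and rate inversion, writing every intermediate artifact to `outDir`
#' (background-subtracted kymographs, peak tables, calibration JSON, track
#' CSVs, measured and predicted matrices, collapse curve, inverted rates,
#' and a machine-readable JSON report). Each hand-off between stages is an
#' explicit file, so any stage can be rerun or replaced in isolation.
#'
#' @param config from [pipelineConfig()] or [readPipelineConfig()].
#' @param outDir output directory (created if needed); `NULL` skips all
#'   file output and just returns the report.
#' @return the report, an invisible list with elements paEstimate, pd,
#'   detachmentRate, nTransitions, collapse (data.frame), rates
#'   (data.frame), excessCollapse, matrices, and provenance fields.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  t0 <- Sys.time()
  writeOut <- !is.null(outDir)
  if (writeOut && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  configHash <- {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    unname(tools::md5sum(tmp))
  }
  if (writeOut) writePipelineConfig(config, file.path(outDir, "config.yaml"))

  trn <- config$transitions
  pd <- if (is.null(config$simulate$pd)) {
    detachmentProbability(trn$kT, trn$atpuM, trn$frameS)
  } else config$simulate$pd

  ## ---- stage 1: acquire kymographs --------------------------------------
  traces <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sim <- config$simulate
    sp <- SimulationParams(pa = sim$pa, pd = pd, pc = sim$pc,
                           pNuc = sim$pNuc, nucMinSepPx = sim$nucMinSepPx,
                           nMaxSim = sim$nMaxSim,
                           filamentLengthPx = sim$filamentLengthPx,
                           nFrames = sim$nFrames,
                           frameInterval = trn$frameS, seed = config$seed)
    im <- config$imaging
    ip <- ImagingParams(pixelNm = im$pixelNm, psfSigmaNm = im$psfSigmaNm,
                        unitIntensity = im$unitIntensity,
                        unitIntensityCv = im$unitIntensityCv,
                        backgroundOffset = im$backgroundOffset,
                        noiseSd = im$noiseSd, seed = config$seed)
    ds <- generateDataset(sp, ip, nKymographs = sim$nKymographs,
                          seed = config$seed,
                          initialSizes = as.integer(sim$initialSizes))
    kymos <- lapply(ds, `[[`, "kymograph")
    traces <- lapply(ds, `[[`, "trace")
  } else {
    if (!length(config$input$paths)) stop("no input kymographs configured")
    kymos <- lapply(config$input$paths, readKymograph,
                    frameInterval = config$input$frameInterval,
                    pixelNm = config$input$pixelNm)
  }

  ## ---- stage 2-3: preprocess and fit peaks ------------------------------
  peakTables <- list()
  for (i in seq_along(kymos)) {
    k <- kymos[[i]]
    src <- sourceId(k)
    bg <- rollingBallSubtract(k, config$preprocess$radiusPx)
    if (writeOut) {
      writeKymograph(bg, file.path(outDir, paste0(src, "_bgsub.tif")))
    }
    pt <- extractPeaks(bg, threshold = config$peaks$threshold,
                       minSeparationPx = config$peaks$minSeparationPx,
                       sigmaBounds = config$peaks$sigmaBounds)
    if (writeOut) {
      writePeakTable(pt, file.path(outDir, paste0(src, "_peaks.csv")))
    }
    peakTables[[src]] <- pt
  }
  allIntegrals <- unlist(lapply(peakTables, function(pt) pt@peaks$integral),
                         use.names = FALSE)

  ## ---- stage 4: calibration ---------------------------------------------
  ## per kymograph (illumination varies between tightropes); a kymograph
  ## with too few peaks to resolve its own count classes falls back to the
  ## calibration pooled over the whole dataset
  pooled <- NULL
  calModels <- list()
  for (src in names(peakTables)) {
    ints <- peakTables[[src]]@peaks$integral
    model <- if (length(ints) >= 50L) {
      try(.autoCalibration(ints, config$calibration, trn$nMax, src),
          silent = TRUE)
    } else structure("too few peaks", class = "try-error")
    if (inherits(model, "try-error")) {
      if (is.null(pooled)) {
        pooled <- .autoCalibration(allIntegrals, config$calibration,
                                   trn$nMax, "pooled")
      }
      warning(src, ": per-kymograph calibration unresolvable, ",
              "using the pooled calibration")
      model <- pooled
      model@sourceId <- paste0(src, " (pooled)")
    }
    calModels[[src]] <- model
    if (writeOut) {
      writeCalibration(model,
                       file.path(outDir, paste0(src, "_calibration.json")))
    }
  }

  ## ---- stage 5: tracking and count series -------------------------------
  seriesList <- list()
  seriesSources <- character()
  for (src in names(peakTables)) {
    pt <- peakTables[[src]]
    if (!nrow(pt@peaks)) next
    ts <- linkTracks(pt, config$tracking$maxLinkDistancePx,
                     config$tracking$maxGapFrames)
    if (writeOut) {
      write.csv(tracks(ts), file.path(outDir, paste0(src, "_tracks.csv")),
                row.names = FALSE)
    }
    cs <- tracksToCountSeries(ts, calModels[[src]])
    seriesList <- c(seriesList, cs)
    seriesSources <- c(seriesSources, rep(src, length(cs)))
  }
  if (!length(seriesList)) stop("pipeline produced no usable count series")

  ## ---- stage 6: transitions ---------------------------------------------
  tc <- countTransitions(seriesList, nMax = trn$nMax,
                         sourceIds = seriesSources)
  mCond <- transitionMatrix(tc, conditional = TRUE)
  mFrame <- transitionMatrix(tc, conditional = FALSE)
  paHat <- estimatePa(tc)
  predComb <- predictedMatrix(paHat, pd, trn$nMax, "combinatorial")
  predBin <- predictedMatrix(paHat, pd, trn$nMax, "binomial")
  curve <- collapseCurve(mFrame)
  binom0 <- pd^curve$size
  curve$predicted <- binom0
  obs2 <- curve$size >= 2 & curve$nObs > 0
  excess <- all(curve$probability[obs2] > binom0[obs2]) && any(obs2)

  okRate <- curve$probability > 0 & curve$probability < 1
  rates <- data.frame(
    size = curve$size[okRate],
    pCollapse = curve$probability[okRate],
    ratePerS = invertCollapseRate(curve$probability[okRate],
                                  curve$size[okRate], trn$frameS))

  if (writeOut) {
    writeTransitionMatrix(mCond, file.path(outDir, "matrix_measured_conditional.csv"))
    writeTransitionMatrix(mFrame, file.path(outDir, "matrix_measured_perframe.csv"))
    writeTransitionMatrix(predComb, file.path(outDir, "matrix_predicted_combinatorial.csv"))
    writeTransitionMatrix(predBin, file.path(outDir, "matrix_predicted_binomial.csv"))
    write.csv(curve, file.path(outDir, "collapse_curve.csv"), row.names = FALSE)
    write.csv(rates, file.path(outDir, "collapse_rates.csv"), row.names = FALSE)
  }

  ## ---- optional RJMCMC route --------------------------------------------
  rj <- NULL
  if (isTRUE(config$rjmcmc$enabled)) {
    hy <- mixtureHyperParams(allIntegrals, kMax = config$rjmcmc$kMax)
    chains <- runMixtureChains(allIntegrals, hy,
                               nSweeps = config$rjmcmc$nSweeps,
                               nChains = config$rjmcmc$nChains,
                               seed = config$seed + 17L)
    km <- modalK(chains)
    sm <- summarizeChains(chains, km)
    rj <- list(modalK = km,
               components = sm@components,
               occupancy = sm@occupancy,
               convergence = sm@convergence)
    if (writeOut) {
      write.csv(sm@components, file.path(outDir, "rjmcmc_components.csv"),
                row.names = FALSE)
    }
  }

  report <- list(
    configHash = configHash,
    seed = config$seed,
    nKymographs = length(kymos),
    nSeries = length(seriesList),
    nTransitions = sum(transitionCounts(tc)),
    pd = pd,
    detachmentRate = detachmentRate(trn$kT, trn$atpuM),
    paEstimate = paHat,
    collapse = curve,
    rates = rates,
    excessCollapse = excess,
    calibrationR2 = vapply(calModels, function(m) m@rSquared, numeric(1)),
    rjmcmc = rj,
    elapsedS = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (writeOut) {
    rep2 <- report
    rep2$elapsedS <- NULL   # keep the written report bit-reproducible
    jsonlite::write_json(rep2, file.path(outDir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}
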