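# Shared fixtures, all generated in code.

# a clean single-Gaussian line profile
gaussProfile <- function(n = 60, A = 150, x0 = 20, sigma = 2, offset = 0) {
  offset + A * exp(-((seq_len(n)) - x0)^2 / (2 * sigma^2))
}

# quiet, sparse study-condition simulation scaled for unit tests
unitSimParams <- function(...) {
  args <- list(pa = 0.15, pd = 0.0554, pNuc = 0.02, nFrames = 200L,
               seed = 1L)
  user <- list(...)
  args[names(user)] <- user
  do.call(SimulationParams, args)
}

# noise-free imaging with a little brightness variability so intensity
# classes have width but assignment stays exact
cleanImaging <- function(...) {
  ImagingParams(noiseSd = 0, unitIntensityCv = 0.05, backgroundOffset = 0,
                seed = 1L, ...)
}

# pool occupancy series from a list of (kymograph, trace) replicates
truthSeries <- function(dataset, minFrames = 2L) {
  out <- list(); src <- character()
  for (d in dataset) {
    os <- occupancySeries(d$trace, minFrames = minFrames)
    out <- c(out, os)
    src <- c(src, rep(sourceId(d$kymograph), length(os)))
  }
  list(series = out, sources = src)
}

# image-route count series for the same replicates
imageSeries <- function(dataset, nMax = 6L) {
  cal <- list(nComponents = 6L, countOffset = 1L, minLineR2 = 0.9,
              maxSdFrac = 0.6)
  out <- list(); src <- character()
  for (d in dataset) {
    pt <- suppressWarnings(extractPeaks(rollingBallSubtract(d$kymograph)))
    model <- collapseKinetics:::.autoCalibration(peaks(pt)$integral, cal,
                                                 nMax, sourceId(d$kymograph))
    cs <- tracksToCountSeries(linkTracks(pt), model)
    out <- c(out, cs)
    src <- c(src, rep(sourceId(d$kymograph), length(cs)))
  }
  list(series = out, sources = src)
}
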