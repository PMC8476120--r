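#' @include AllClasses.R
NULL

#' Intensity matrix of a kymograph
#' @param object a [Kymograph-class].
#' @return numeric matrix, frames x pixels.
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' Frame interval in seconds
#' @param object an object with a time base.
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' Pixel size in nanometres
#' @param object an object with a spatial calibration.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' Number of frames
#' @param object a kymograph, trace, peak table or track set.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' Provenance label
#' @param object any pipeline object carrying a source id.
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' Peaks as a data.frame
#' @param object a [PeakTable-class].
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' Tracks as a data.frame
#' @param object a [RegionTrackSet-class].
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))

#' Event log of a simulation
#' @param object a [GroundTruthTrace-class].
#' @export
setGeneric("eventLog", function(object) standardGeneric("eventLog"))

#' Transition counts matrix
#' @param object a [TransitionCounts-class].
#' @export
setGeneric("transitionCounts", function(object) standardGeneric("transitionCounts"))

#' Probability entries of a transition matrix
#' @param object a [TransitionMatrix-class].
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))

#' Component means
#' @param object a [CalibrationModel-class] or [ComponentSummary-class].
#' @export
setGeneric("componentMeans", function(object) standardGeneric("componentMeans"))

## -------------------------------------------------------------------------
## accessors
## -------------------------------------------------------------------------

#' @describeIn intensityMatrix kymograph method
setMethod("intensityMatrix", "Kymograph", function(object) object@intensity)

#' @describeIn frameInterval kymograph method
setMethod("frameInterval", "Kymograph", function(object) object@frameInterval)

#' @describeIn pixelSize kymograph method
setMethod("pixelSize", "Kymograph", function(object) object@pixelNm)

#' @describeIn nFrames kymograph method
setMethod("nFrames", "Kymograph", function(object) nrow(object@intensity))

#' @describeIn nFrames ground-truth trace method
setMethod("nFrames", "GroundTruthTrace", function(object) object@nFrames)

#' @describeIn nFrames peak table method
setMethod("nFrames", "PeakTable", function(object) object@nFrames)

#' @describeIn nFrames track set method
setMethod("nFrames", "RegionTrackSet", function(object) object@nFrames)

#' @describeIn sourceId kymograph method
setMethod("sourceId", "Kymograph", function(object) object@sourceId)

#' @describeIn sourceId peak table method
setMethod("sourceId", "PeakTable", function(object) object@sourceId)

#' @describeIn sourceId track set method
setMethod("sourceId", "RegionTrackSet", function(object) object@sourceId)

#' @describeIn peaks peak table method
setMethod("peaks", "PeakTable", function(object) object@peaks)

#' @describeIn tracks track set method
setMethod("tracks", "RegionTrackSet", function(object) object@tracks)

#' @describeIn eventLog trace method
setMethod("eventLog", "GroundTruthTrace", function(object) object@events)

#' @describeIn transitionCounts counts method
setMethod("transitionCounts", "TransitionCounts", function(object) object@counts)

#' @describeIn probabilities matrix method
setMethod("probabilities", "TransitionMatrix", function(object) object@probabilities)

#' @describeIn componentMeans calibration method
setMethod("componentMeans", "CalibrationModel", function(object) object@componentMeans)

#' @describeIn componentMeans mixture summary method
setMethod("componentMeans", "ComponentSummary",
          function(object) object@components$mean)

## -------------------------------------------------------------------------
## show methods
## -------------------------------------------------------------------------

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph '%s': %d frames x %d px (%.3g s/frame, %.4g nm/px)\n",
              object@sourceId, nrow(object@intensity), ncol(object@intensity),
              object@frameInterval, object@pixelNm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@intensity), max(object@intensity)))
})

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams\n")
  cat(sprintf("  pa = %.4g, pd = %.4g, pNuc = %.4g, nMaxSim = %d\n",
              object@pa, object@pd, object@pNuc, object@nMaxSim))
  cat(sprintf("  collapse pc: %s\n",
              if (all(object@pc == 0)) "none" else
                paste(sprintf("%d:%.3g", seq_along(object@pc), object@pc)[object@pc > 0],
                      collapse = " ")))
  cat(sprintf("  %d frames x %.3g s, filament %.5g px, site spacing %.4g nm, seed %d\n",
              object@nFrames, object@frameInterval, object@filamentLengthPx,
              object@siteSpacingNm, object@seed))
})

setMethod("show", "GroundTruthTrace", function(object) {
  cat(sprintf("GroundTruthTrace: %d myosins, %d events over %d frames\n",
              nrow(object@myosins), nrow(object@events), object@nFrames))
})

setMethod("show", "ImagingParams", function(object) {
  cat(sprintf(
    "ImagingParams: %.4g nm/px, PSF sigma %.4g nm, unit intensity %.4g (cv %.3g)\n",
    object@pixelNm, object@psfSigmaNm, object@unitIntensity,
    object@unitIntensityCv))
  cat(sprintf("  background %.4g, noise sd %.4g, seed %d\n",
              object@backgroundOffset, object@noiseSd, object@seed))
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable '%s': %d peaks in %d frames (threshold %.4g)\n",
              object@sourceId, nrow(object@peaks),
              length(unique(object@peaks$frame)), object@threshold))
})

setMethod("show", "CalibrationModel", function(object) {
  k <- length(object@componentMeans)
  cat(sprintf("CalibrationModel '%s': %d count classes (counts %d..%d)\n",
              object@sourceId, k, object@countOffset,
              object@countOffset + k - 1L))
  cat(sprintf("  line: intensity = %.4g + %.4g * count (r^2 = %.4g)\n",
              object@lineIntercept, object@lineSlope, object@rSquared))
  if (any(object@extrapolated)) {
    cat(sprintf("  %d band(s) extrapolated from the line fit\n",
                sum(object@extrapolated)))
  }
})

setMethod("show", "RegionTrackSet", function(object) {
  cat(sprintf("RegionTrackSet '%s': %d tracks, %d localisations\n",
              object@sourceId, length(unique(object@tracks$trackId)),
              sum(!object@tracks$gap)))
})

setMethod("show", "TransitionCounts", function(object) {
  cat(sprintf("TransitionCounts (nMax = %d): %d transitions, %d sources\n",
              object@nMax, sum(object@counts), length(object@perSource)))
  print(object@counts)
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix (nMax = %d, %s, %d source%s)\n",
              object@nMax,
              if (object@conditional) "conditional on a change" else "per frame",
              object@nSources, if (object@nSources == 1L) "" else "s"))
  print(round(object@probabilities, 4))
})

setMethod("show", "MixtureHyperParams", function(object) {
  cat(sprintf(
    "MixtureHyperParams: alpha=%.3g g=%.3g h=%.4g xi=%.4g kappa=%.4g delta=%.3g kMax=%d\n",
    object@alpha, object@g, object@h, object@xi, object@kappa, object@delta,
    object@kMax))
})

setMethod("show", "MixtureChain", function(object) {
  tk <- table(object@k)
  cat(sprintf("MixtureChain: %d sweeps, k range %d..%d, modal k = %d\n",
              length(object@k), min(object@k), max(object@k),
              as.integer(names(tk)[which.max(tk)])))
  cat("  move acceptance: ",
      paste(sprintf("%s %.3f", names(object@moveRates), object@moveRates),
            collapse = ", "), "\n")
})

setMethod("show", "ComponentSummary", function(object) {
  cat(sprintf(
    "ComponentSummary conditional on k = %d (occupancy %.3f, %d chains, convergence %.3f)\n",
    object@kCondition, object@occupancy, object@nChains, object@convergence))
  print(object@components, digits = 5)
})
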