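#' @include AllClasses.R AllGenerics.R
NULL

#' Link per-frame peaks into active-region tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate links
#' between open tracks and current-frame peaks within
#' `maxLinkDistancePx` are taken in order of increasing distance (ties
#' broken towards the leftmost peak); unmatched peaks start new tracks;
#' a track is closed once unmatched for more than `maxGapFrames` frames.
#' Bridged gap frames are inserted with linearly interpolated positions,
#' no intensity, and `gap = TRUE`. Active regions on a tightrope are sparse
#' (microns apart), so a full assignment-problem linker is unnecessary.
#'
#' @param pt a [PeakTable-class].
#' @param maxLinkDistancePx linking radius in pixels (default 4).
#' @param maxGapFrames maximum bridged gap in frames (default 1).
#' @return A [RegionTrackSet-class].
#' @export
linkTracks <- function(pt, maxLinkDistancePx = 4, maxGapFrames = 1L) {
  stopifnot(is(pt, "PeakTable"))
  pk <- pt@peaks
  pk <- pk[pk$converged & is.finite(pk$positionPx), , drop = FALSE]
  if (!nrow(pk)) stop("no fitted peaks to link")

  nextId <- 1L
  open <- list()    # each: id, lastFrame, lastPos
  rows <- .newRecorder(list(trackId = "integer", frame = "integer",
                            positionPx = "double", integral = "double",
                            gap = "logical"))

  addRow <- function(id, frame, pos, integral, gap) {
    .recAdd(rows, trackId = id, frame = frame, positionPx = pos,
            integral = integral, gap = gap)
  }

  for (f in sort(unique(pk$frame))) {
    cur <- pk[pk$frame == f, , drop = FALSE]
    ## close tracks that have been unmatched for too long
    if (length(open)) {
      stale <- vapply(open, function(tr) f - tr$lastFrame > maxGapFrames + 1L,
                      logical(1))
      open <- open[!stale]
    }
    assignedPeak <- rep(FALSE, nrow(cur))
    assignedTrack <- rep(FALSE, length(open))
    if (length(open) && nrow(cur)) {
      d <- abs(outer(vapply(open, `[[`, numeric(1), "lastPos"),
                     cur$positionPx, "-"))
      cand <- which(d <= maxLinkDistancePx, arr.ind = TRUE)
      if (nrow(cand)) {
        ## increasing distance, ties to the leftmost peak
        ord <- order(d[cand], cur$positionPx[cand[, 2L]])
        for (ci in ord) {
          ti <- cand[ci, 1L]; pi <- cand[ci, 2L]
          if (assignedTrack[ti] || assignedPeak[pi]) next
          assignedTrack[ti] <- TRUE
          assignedPeak[pi] <- TRUE
          tr <- open[[ti]]
          nGap <- f - tr$lastFrame - 1L
          if (nGap > 0L) {
            for (g in seq_len(nGap)) {
              w <- g / (nGap + 1L)
              addRow(tr$id, tr$lastFrame + g,
                     (1 - w) * tr$lastPos + w * cur$positionPx[pi],
                     NA_real_, TRUE)
            }
          }
          addRow(tr$id, f, cur$positionPx[pi], cur$integral[pi], FALSE)
          open[[ti]]$lastFrame <- f
          open[[ti]]$lastPos <- cur$positionPx[pi]
        }
      }
    }
    for (pi in which(!assignedPeak)) {
      id <- nextId; nextId <- nextId + 1L
      addRow(id, f, cur$positionPx[pi], cur$integral[pi], FALSE)
      open[[length(open) + 1L]] <- list(id = id, lastFrame = f,
                                        lastPos = cur$positionPx[pi])
    }
  }

  df <- .recDf(rows)
  df <- df[order(df$trackId, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  new("RegionTrackSet", tracks = df,
      maxLinkDistancePx = as.numeric(maxLinkDistancePx),
      maxGapFrames = as.integer(maxGapFrames), sourceId = pt@sourceId,
      nFrames = pt@nFrames)
}

#' Convert tracks to per-region myosin-count time series
#'
#' Maps each tracked intensity integral to an integer count through
#' [assignCount()]. Gap frames and unassigned intensities become missing
#' values (excluded from transition counting, never treated as zero). A
#' track that ends before the last frame of the recording contributes a
#' terminal transition to count 0 at its first peak-free frame; tracks with
#' fewer than `minFrames` observed frames contribute nothing.
#'
#' @param trackSet a [RegionTrackSet-class].
#' @param model a [CalibrationModel-class].
#' @param minFrames minimum observed (non-gap) frames (default 2).
#' @return named list of integer vectors (NA = missing), one per track.
#' @export
tracksToCountSeries <- function(trackSet, model, minFrames = 2L) {
  stopifnot(is(trackSet, "RegionTrackSet"), is(model, "CalibrationModel"))
  df <- trackSet@tracks
  out <- list()
  for (id in unique(df$trackId)) {
    tr <- df[df$trackId == id, , drop = FALSE]
    nObs <- sum(!tr$gap)
    if (nObs < minFrames) next
    cnt <- rep(NA_integer_, nrow(tr))
    obs <- !tr$gap & is.finite(tr$integral)
    cnt[obs] <- assignCount(tr$integral[obs], model)
    if (max(tr$frame) < trackSet@nFrames) cnt <- c(cnt, 0L)
    out[[as.character(id)]] <- cnt
  }
  out
}
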