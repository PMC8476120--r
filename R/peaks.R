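#' @include AllClasses.R AllGenerics.R
NULL

#' Robust detection threshold for a background-subtracted kymograph
#'
#' Threshold = `nSigma` x the robust noise sd, estimated as the median
#' absolute deviation of the image (x 1.4826). On a background-subtracted
#' image most pixels are noise around zero, so the MAD tracks the noise
#' level even with peaks present. The default of 5 sd keeps the expected
#' number of spurious local maxima over a whole kymograph (tens of
#' thousands of pixels) well below one, while a single myosin sits an
#' order of magnitude above the noise floor in this assay.
#'
#' @param k a [Kymograph-class] (background subtracted).
#' @param nSigma multiple of the robust sd (default 5).
#' @return numeric(1) threshold in counts.
#' @export
peakThreshold <- function(k, nSigma = 5) {
  stopifnot(is(k, "Kymograph"))
  m <- k@intensity
  s <- mad(m, center = median(m))
  if (s <= 0) {
    ## clipped noise-free images: fall back to a small fraction of the range
    s <- max(diff(range(m)) / 100, .Machine$double.eps)
  }
  nSigma * s
}

#' Detect candidate peak positions in a line profile
#'
#' Local maxima above a threshold, thinned so that retained candidates are
#' at least `minSeparationPx` apart (higher peaks win).
#'
#' @param profile numeric vector, one time-slice of a kymograph.
#' @param threshold minimum height in counts (>= 0).
#' @param minSeparationPx minimum spacing between candidates (default 3).
#' @return data.frame with columns positionPx (integer pixel index) and
#'   height; zero rows when nothing exceeds the threshold.
#' @examples
#' x <- 150 * exp(-((1:40) - 20)^2 / 8)
#' detectCandidates(x, 50)
#' @export
detectCandidates <- function(profile, threshold, minSeparationPx = 3) {
  stopifnot(is.numeric(profile), threshold >= 0)
  n <- length(profile)
  if (n < 3L) return(data.frame(positionPx = integer(), height = numeric()))
  left <- c(-Inf, profile[-n])
  right <- c(profile[-1L], -Inf)
  isMax <- profile > threshold & profile >= left & profile > right
  pos <- which(isMax)
  if (!length(pos)) return(data.frame(positionPx = integer(), height = numeric()))
  h <- profile[pos]
  keep <- logical(length(pos))
  taken <- numeric(0)
  for (i in order(h, decreasing = TRUE)) {
    if (!length(taken) || min(abs(taken - pos[i])) >= minSeparationPx) {
      keep[i] <- TRUE
      taken <- c(taken, pos[i])
    }
  }
  out <- data.frame(positionPx = pos[keep], height = h[keep])
  out[order(out$positionPx), , drop = FALSE]
}

## model for a sum of Gaussians, par = (A1, x1, s1, A2, ...); a trailing
## extra element, when present, is a constant baseline
.multiGaussEval <- function(par, x) {
  k <- length(par) %/% 3L
  y <- if (length(par) %% 3L) rep(par[length(par)], length(x)) else
    numeric(length(x))
  for (j in seq_len(k)) {
    A <- par[3 * j - 2]; mu <- par[3 * j - 1]; s <- par[3 * j]
    y <- y + A * exp(-(x - mu)^2 / (2 * s^2))
  }
  y
}

.fitGaussians <- function(profile, x, starts, lower, upper) {
  fit <- try(minpack.lm::nls.lm(
    par = starts,
    fn = function(p) profile - .multiGaussEval(p, x),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(par = fit$par, rss = sum(fit$fvec^2), info = fit$info)
}

#' Fit a line profile to a sum of Gaussians
#'
#' Nonlinear least squares of \eqn{\sum_k A_k \exp(-(x - x_k)^2 / 2\sigma_k^2)}
#' seeded from detected candidates. After fitting, peaks whose amplitude
#' falls below the threshold or whose width pins to the sigma bounds are
#' dropped and the model refitted; the model order is then reduced greedily
#' while the Bayesian information criterion improves, giving an autonomously
#' determined number of Gaussians. If the optimiser fails to converge the
#' candidates are returned flagged as unfitted rather than silently dropped.
#'
#' @param profile numeric vector (one time-slice).
#' @param candidates data.frame from [detectCandidates()], or a numeric
#'   vector of candidate positions.
#' @param threshold amplitude threshold for retaining a fitted peak.
#' @param sigmaBounds admissible Gaussian sigma range in pixels
#'   (default c(0.5, 4)).
#' @param baseline also fit a constant offset (default TRUE). Background
#'   subtraction leaves a small positive residual floor (the ball rides the
#'   lower envelope of the noise); without the constant term that floor
#'   leaks into the fitted integrals.
#' @return data.frame with columns positionPx (sub-pixel), amplitude,
#'   sigmaPx, integral, fitRss, converged.
#' @export
fitMultiGaussian <- function(profile, candidates, threshold = 0,
                             sigmaBounds = c(0.5, 4), baseline = TRUE) {
  if (is.numeric(candidates)) {
    candidates <- data.frame(positionPx = candidates,
                             height = profile[pmax(1L, round(candidates))])
  }
  stopifnot(nrow(candidates) >= 1L)
  x <- seq_along(profile)
  n <- length(profile)
  s0 <- min(max(1, sigmaBounds[1] * 2), sigmaBounds[2])  # typical PSF width

  empty <- data.frame(positionPx = numeric(), amplitude = numeric(),
                      sigmaPx = numeric(), integral = numeric(),
                      fitRss = numeric(), converged = logical())
  unfitted <- data.frame(positionPx = candidates$positionPx,
                         amplitude = candidates$height,
                         sigmaPx = NA_real_, integral = NA_real_,
                         fitRss = NA_real_, converged = FALSE)

  buildBounds <- function(k, cand) {
    b <- list(starts = as.numeric(rbind(cand$height, cand$positionPx,
                                        rep(max(s0, sigmaBounds[1] * 1.5), k))),
              lower = as.numeric(rbind(rep(0, k), cand$positionPx - 4,
                                       rep(sigmaBounds[1], k))),
              upper = as.numeric(rbind(rep(2 * max(profile), k),
                                       cand$positionPx + 4,
                                       rep(sigmaBounds[2], k))))
    if (baseline) {
      b$starts <- c(b$starts, median(profile))
      b$lower <- c(b$lower, -max(abs(profile)))
      b$upper <- c(b$upper, max(abs(profile)))
    }
    b
  }

  fitSet <- function(cand) {
    k <- nrow(cand)
    b <- buildBounds(k, cand)
    .fitGaussians(profile, x, b$starts, b$lower, b$upper)
  }

  cand <- candidates
  fit <- fitSet(cand)
  if (is.null(fit)) return(unfitted)

  ## drop sub-threshold or bound-pinned peaks, refit
  repeat {
    k <- length(fit$par) %/% 3L
    A <- fit$par[3 * seq_len(k) - 2]
    s <- fit$par[3 * seq_len(k)]
    bad <- A < threshold | s >= sigmaBounds[2] - 1e-6
    if (!any(bad) || all(bad)) break
    cand <- cand[!bad, , drop = FALSE]
    fit2 <- fitSet(cand)
    if (is.null(fit2)) break
    fit <- fit2
  }
  if (all(fit$par[3 * seq_len(length(fit$par) %/% 3L) - 2] < threshold)) {
    return(empty)
  }

  nPar <- function(k) 3 * k + as.integer(baseline)
  bic <- function(rss, k) n * log(max(rss, 1e-12) / n) + nPar(k) * log(n)

  ## greedy order reduction while BIC improves
  repeat {
    k <- length(fit$par) %/% 3L
    if (k <= 1L) break
    cur <- bic(fit$rss, k)
    A <- fit$par[3 * seq_len(k) - 2]
    drop <- which.min(A)
    cand2 <- data.frame(positionPx = fit$par[3 * seq_len(k) - 1][-drop],
                        height = A[-drop])
    fit2 <- fitSet(cand2)
    if (is.null(fit2) || bic(fit2$rss, k - 1L) >= cur) break
    fit <- fit2
  }

  k <- length(fit$par) %/% 3L
  A <- fit$par[3 * seq_len(k) - 2]
  mu <- fit$par[3 * seq_len(k) - 1]
  s <- fit$par[3 * seq_len(k)]
  keep <- A >= threshold & mu >= 1 & mu <= n
  if (!any(keep)) return(empty)
  out <- data.frame(positionPx = mu[keep], amplitude = A[keep],
                    sigmaPx = s[keep],
                    integral = A[keep] * s[keep] * sqrt(2 * pi),
                    fitRss = rep(fit$rss, sum(keep)), converged = TRUE)
  out[order(out$positionPx), , drop = FALSE]
}

#' Extract fitted peaks from every frame of a kymograph
#'
#' Runs candidate detection and multi-Gaussian fitting on each time-slice
#' and aggregates the results into a [PeakTable-class]. The kymograph should
#' be background subtracted first.
#'
#' @param k a [Kymograph-class].
#' @param threshold detection threshold in counts; default 3 x robust noise
#'   sd via [peakThreshold()].
#' @param minSeparationPx candidate spacing (default 3 px).
#' @param sigmaBounds Gaussian width bounds in pixels (default c(0.5, 4)).
#' @param baseline fit a per-frame constant offset (default TRUE).
#' @return A [PeakTable-class], sorted by (frame, position).
#' @export
extractPeaks <- function(k, threshold = NULL, minSeparationPx = 3,
                         sigmaBounds = c(0.5, 4), baseline = TRUE) {
  stopifnot(is(k, "Kymograph"))
  if (is.null(threshold)) threshold <- peakThreshold(k)
  m <- k@intensity
  rows <- vector("list", nrow(m))
  for (f in seq_len(nrow(m))) {
    cand <- detectCandidates(m[f, ], threshold, minSeparationPx)
    if (!nrow(cand)) next
    pk <- suppressWarnings(
      fitMultiGaussian(m[f, ], cand, threshold = threshold,
                       sigmaBounds = sigmaBounds, baseline = baseline))
    if (nrow(pk)) {
      pk$frame <- f
      rows[[f]] <- pk
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- df[order(df$frame, df$positionPx),
             c("frame", "positionPx", "amplitude", "sigmaPx", "integral",
               "fitRss", "converged")]
    rownames(df) <- NULL
  } else {
    df <- data.frame(frame = integer(), positionPx = numeric(),
                     amplitude = numeric(), sigmaPx = numeric(),
                     integral = numeric(), fitRss = numeric(),
                     converged = logical())
  }
  new("PeakTable", peaks = df, threshold = threshold,
      sourceId = k@sourceId, nFrames = nrow(m))
}

#' Write / read a peak table as CSV
#'
#' @param pt a [PeakTable-class].
#' @param path CSV path.
#' @return `path` (write) or a [PeakTable-class] (read).
#' @export
writePeakTable <- function(pt, path) {
  stopifnot(is(pt, "PeakTable"))
  df <- pt@peaks
  attr <- sprintf("# threshold=%.10g sourceId=%s nFrames=%d",
                  pt@threshold, pt@sourceId, pt@nFrames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "# threshold=([0-9.eE+-]+) sourceId=(.*) nFrames=([0-9]+)", hdr))[[1L]]
  df <- read.csv(path, skip = 1L)
  df$converged <- as.logical(df$converged)
  new("PeakTable", peaks = df, threshold = as.numeric(m[2L]),
      sourceId = m[3L], nFrames = as.integer(m[4L]))
}
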