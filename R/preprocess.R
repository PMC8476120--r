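#' @include AllClasses.R AllGenerics.R
#' @useDynLib collapseKinetics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## fixed power-of-two intensity scale for 32-bit float TIFF storage: the
## tiff package stores samples in [0,1], and division by a power of two is
## exact in floating point
.TIFF_SCALE <- 65536

#' Read a kymograph from TIFF or CSV
#'
#' CSV files hold the bare intensity grid (no header), frames as rows.
#' TIFF files written by [writeKymograph()] are 32-bit float with
#' intensities divided by a fixed 2^16 scale, which this reader undoes;
#' integer TIFFs from other software can be read with `scale = 1` and
#' `asIs = TRUE`.
#'
#' @param path file path; format chosen by extension (.tif/.tiff vs .csv).
#' @param frameInterval seconds per frame (default 0.3).
#' @param pixelNm nanometres per pixel (default 126.4).
#' @param transpose set TRUE when the file stores position as rows.
#' @param scale intensity scale undone on read (TIFF only).
#' @param asIs read TIFF samples without [0,1] normalisation (integer TIFFs).
#' @return A [Kymograph-class].
#' @export
readKymograph <- function(path, frameInterval = 0.3, pixelNm = 126.4,
                          transpose = FALSE, scale = .TIFF_SCALE,
                          asIs = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = asIs)
    if (is.array(m) && length(dim(m)) == 3L) m <- m[, , 1L]
    m <- m * scale
  } else if (ext == "csv") {
    m <- as.matrix(read.csv(path, header = FALSE))
    dimnames(m) <- NULL
  } else {
    stop("unsupported kymograph format: .", ext)
  }
  if (is.null(dim(m)) || length(dim(m)) != 2L) {
    stop("kymograph input must be a 2-D intensity array")
  }
  if (min(dim(m)) < 2L) stop("kymograph input must be a 2-D intensity array")
  if (transpose) m <- t(m)
  storage.mode(m) <- "double"
  Kymograph(m, frameInterval = frameInterval, pixelNm = pixelNm,
            sourceId = basename(path))
}

#' Write a kymograph to TIFF or CSV
#'
#' @param k a [Kymograph-class].
#' @param path output path; `.tif`/`.tiff` writes single-page 32-bit float
#'   (intensity / 2^16), `.csv` a bare full-precision grid.
#' @param scale intensity scale applied before TIFF storage.
#' @return `path`, invisibly.
#' @export
writeKymograph <- function(k, path, scale = .TIFF_SCALE) {
  stopifnot(is(k, "Kymograph"))
  ext <- tolower(tools::file_ext(path))
  m <- k@intensity
  if (ext %in% c("tif", "tiff")) {
    if (min(m) < 0 || max(m) > scale) {
      stop("intensities outside [0, scale]; raise `scale`")
    }
    tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  } else if (ext == "csv") {
    txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(txt, path)
  } else {
    stop("unsupported kymograph format: .", ext)
  }
  invisible(path)
}

## bilinear enlargement of a coarse background grid back to full resolution;
## coarse cell (i,j) is centred at full-resolution coordinate (i-0.5)*f + 0.5
.bilinearEnlarge <- function(small, nr, nc, factor) {
  snr <- nrow(small); snc <- ncol(small)
  yc <- pmin(pmax(((seq_len(nr) - 0.5) / factor) + 0.5, 1), snr)
  xc <- pmin(pmax(((seq_len(nc) - 0.5) / factor) + 0.5, 1), snc)
  y0 <- pmin(floor(yc), snr - 1L); y1 <- y0 + 1L; wy <- yc - y0
  if (snr == 1L) { y0 <- y1 <- rep(1L, nr); wy <- rep(0, nr) }
  x0 <- pmin(floor(xc), snc - 1L); x1 <- x0 + 1L; wx <- xc - x0
  if (snc == 1L) { x0 <- x1 <- rep(1L, nc); wx <- rep(0, nc) }
  a <- small[y0, x0, drop = FALSE]; b <- small[y0, x1, drop = FALSE]
  c_ <- small[y1, x0, drop = FALSE]; d <- small[y1, x1, drop = FALSE]
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + c_ * WY * (1 - WX) +
    d * WY * WX
}

#' Rolling-ball background estimate
#'
#' Grey-scale morphological opening with a ball-shaped structuring element
#' (the surface traced by a ball of the given radius rolled beneath the
#' intensity surface). For radii above 10 px the image is first shrunk by
#' min-pooling (factor 2, 4 or 8 depending on the radius), the ball rolled on
#' the coarse grid, and the background enlarged bilinearly, as in the classic
#' implementation.
#'
#' @param k a [Kymograph-class].
#' @param radiusPx ball radius in pixels (default 50).
#' @return numeric matrix, the estimated background.
#' @export
rollingBallBackground <- function(k, radiusPx = 50) {
  stopifnot(is(k, "Kymograph"), radiusPx >= 1)
  m <- k@intensity
  if (radiusPx > nrow(m) && radiusPx > ncol(m)) {
    stop("radiusPx exceeds both image dimensions")
  }
  factor <- if (radiusPx <= 10) 1L else if (radiusPx <= 30) 2L else
    if (radiusPx <= 100) 4L else 8L
  if (factor == 1L) {
    return(.cppBallBackground(m, radiusPx))
  }
  small <- .cppBlockMin(m, factor)
  bgSmall <- .cppBallBackground(small, radiusPx / factor)
  bg <- .bilinearEnlarge(bgSmall, nrow(m), ncol(m), factor)
  pmin(bg, m)   # a background estimate never exceeds the data
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background with [rollingBallBackground()] and
#' subtracts it, clipping negative residuals at zero. Narrow peaks (much
#' smaller than the ball) are preserved; structure broader than the ball is
#' removed. The default radius of 50 px matches the standard kymograph
#' preprocessing for this assay.
#'
#' @param k a [Kymograph-class].
#' @param radiusPx ball radius in pixels (default 50).
#' @return a background-subtracted [Kymograph-class] of the same shape.
#' @examples
#' k <- Kymograph(matrix(100, 20, 40))
#' range(intensityMatrix(rollingBallSubtract(k)))   # all zero
#' @export
rollingBallSubtract <- function(k, radiusPx = 50) {
  bg <- rollingBallBackground(k, radiusPx)
  out <- k@intensity - bg
  out[out < 0] <- 0
  Kymograph(out, frameInterval = k@frameInterval, pixelNm = k@pixelNm,
            sourceId = k@sourceId)
}
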