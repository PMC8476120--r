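#' @include AllClasses.R AllGenerics.R
NULL

#' Per-frame detachment probability from ATP-binding kinetics
#'
#' At low ATP, myosin release is rate-limited by ATP binding, so the
#' per-frame probability that an attached head detaches is
#' \deqn{P_d = 1 - e^{-k_T [ATP] t}}
#' with \eqn{k_T} the second-order ATP-binding rate constant, \eqn{[ATP]}
#' the ATP concentration and \eqn{t} the frame duration.
#'
#' @param kT second-order ATP-binding rate constant (per uM per s),
#'   default 1.9.
#' @param atpuM ATP concentration in uM, default 0.1.
#' @param frameS frame duration in seconds, default 0.3.
#' @return probability in [0,1].
#' @examples
#' detachmentProbability()            # 0.0554
#' detachmentRate()                   # 0.19 s^-1
#' @export
detachmentProbability <- function(kT = 1.9, atpuM = 0.1, frameS = 0.3) {
  stopifnot(kT >= 0, atpuM >= 0, frameS >= 0)
  1 - exp(-kT * atpuM * frameS)
}

#' @rdname detachmentProbability
#' @return `detachmentRate`: the first-order detachment rate constant
#'   \eqn{k_T [ATP]} in s^-1.
#' @export
detachmentRate <- function(kT = 1.9, atpuM = 0.1) {
  stopifnot(kT >= 0, atpuM >= 0)
  kT * atpuM
}

#' Tally one-frame cluster-size transitions
#'
#' Counts i -> j over consecutive observed frames of each count series,
#' for starting sizes 1..nMax and final sizes 0..nMax. Pairs containing a
#' missing value or a size above nMax are skipped (the few larger clusters
#' are discarded from analysis); i -> i pairs are not tallied as
#' transitions but do accumulate in the per-row exposures, so per-frame
#' probabilities remain recoverable.
#'
#' @param seriesList list of integer count vectors (NA = missing), e.g.
#'   from [tracksToCountSeries()] or [occupancySeries()].
#' @param nMax largest analysed cluster size (default 6).
#' @param sourceIds optional character vector, one per series, naming the
#'   kymograph each series came from (enables across-kymograph SEMs).
#' @return A [TransitionCounts-class].
#' @examples
#' tc <- countTransitions(list(c(2, 2, 1, 1, 0)))
#' transitionCounts(tc)["2", "1"]   # one 2 -> 1 transition
#' @export
countTransitions <- function(seriesList, nMax = 6L, sourceIds = NULL) {
  nMax <- as.integer(nMax)
  if (is.numeric(seriesList)) seriesList <- list(seriesList)
  if (is.null(sourceIds)) sourceIds <- rep("pooled", length(seriesList))
  stopifnot(length(sourceIds) == length(seriesList))

  emptyCounts <- function() {
    matrix(0L, nMax, nMax + 1L,
           dimnames = list(start = as.character(seq_len(nMax)),
                           final = as.character(0:nMax)))
  }
  perSource <- list()
  for (src in unique(sourceIds)) {
    perSource[[src]] <- list(counts = emptyCounts(),
                             exposures = setNames(numeric(nMax),
                                                  as.character(seq_len(nMax))))
  }
  for (s in seq_along(seriesList)) {
    v <- as.integer(seriesList[[s]])
    if (length(v) < 2L) next
    src <- sourceIds[s]
    i <- v[-length(v)]
    j <- v[-1L]
    ok <- !is.na(i) & !is.na(j) & i >= 1L & i <= nMax & j >= 0L & j <= nMax
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]
    ex <- tabulate(i, nMax)
    perSource[[src]]$exposures <- perSource[[src]]$exposures + ex
    move <- i != j
    if (any(move)) {
      t2 <- table(factor(i[move], levels = seq_len(nMax)),
                  factor(j[move], levels = 0:nMax))
      perSource[[src]]$counts <- perSource[[src]]$counts +
        matrix(as.integer(t2), nMax, nMax + 1L)
    }
  }
  total <- emptyCounts()
  exposures <- setNames(numeric(nMax), as.character(seq_len(nMax)))
  for (src in names(perSource)) {
    total <- total + perSource[[src]]$counts
    exposures <- exposures + perSource[[src]]$exposures
  }
  new("TransitionCounts", counts = total, exposures = exposures,
      nMax = nMax, perSource = perSource)
}

## shared helper: probabilities from one (counts, exposures) pair
.countsToProb <- function(counts, exposures, conditional) {
  denom <- if (conditional) rowSums(counts) else exposures
  p <- counts / ifelse(denom > 0, denom, NA_real_)
  p[!is.finite(p)] <- 0
  list(p = p, denom = denom)
}

#' Form a transition probability matrix from tallied counts
#'
#' With `conditional = TRUE` (the display convention) entries are
#' probabilities of reaching size j given that the size changed: the
#' central diagonal is zero and each observed row sums to one. With
#' `conditional = FALSE` entries are per-frame probabilities
#' (counts / exposures); the diagonal is still zero but rows sum to the
#' per-frame probability of any change, which is the correct scale on which
#' to read off the model parameters Pa and Pd. Across-kymograph standard
#' errors are attached when the counts carry more than one source.
#'
#' @param x a [TransitionCounts-class].
#' @param conditional logical (default TRUE).
#' @return A [TransitionMatrix-class].
#' @export
transitionMatrix <- function(x, conditional = TRUE) {
  stopifnot(is(x, "TransitionCounts"))
  if (sum(x@counts) == 0L) stop("no transitions tallied")
  pooled <- .countsToProb(x@counts, x@exposures, conditional)
  nSrc <- length(x@perSource)
  sem <- matrix(NA_real_, x@nMax, x@nMax + 1L, dimnames = dimnames(x@counts))
  if (nSrc > 1L) {
    perP <- lapply(x@perSource, function(ps) {
      pr <- .countsToProb(ps$counts, ps$exposures, conditional)
      ## rows never observed in this kymograph carry no estimate
      pr$p[pr$denom == 0, ] <- NA_real_
      pr$p
    })
    arr <- simplify2array(perP)                 # nMax x (nMax+1) x nSrc
    nObs <- apply(!is.na(arr), c(1, 2), sum)
    sdv <- apply(arr, c(1, 2), sd, na.rm = TRUE)
    sem <- ifelse(nObs > 1L, sdv / sqrt(nObs), NA_real_)
  }
  new("TransitionMatrix", probabilities = pooled$p, sem = sem,
      rowTotals = as.numeric(pooled$denom), conditional = conditional,
      nMax = x@nMax, nSources = as.integer(nSrc))
}

#' Model-predicted transition matrix
#'
#' Builds the stochastic-model twin of the measured matrix from the
#' attachment probability `pa` and per-myosin detachment probability `pd`.
#' Entries right of the diagonal are \eqn{P_a^{(j-i)}}; entries left of the
#' diagonal, with \eqn{n = i - j} myosins leaving, follow one of two laws:
#' \describe{
#'   \item{`"combinatorial"`}{\eqn{P_d^n \, i! / (j!\, n!)} — the detachment
#'     probability raised to the number leaving, scaled by the number of
#'     ways of choosing them. This is the verbatim model law; note it
#'     carries no survival factor for the j myosins that stay.}
#'   \item{`"binomial"`}{\eqn{\binom{i}{n} P_d^n (1 - P_d)^j} — the full
#'     binomial law including the survival factor, which is also the exact
#'     detachment law of the simulator.}
#' }
#' The diagonal is zero. With `normalise = TRUE` rows are scaled to sum to
#' one for like-for-like comparison with a conditional measured matrix;
#' the flag is recorded in the result.
#'
#' @param pa attachment probability per frame, in (0,1).
#' @param pd per-myosin detachment probability per frame, in (0,1).
#' @param nMax largest cluster size (default 6).
#' @param detachLaw `"combinatorial"` (default) or `"binomial"`.
#' @param normalise row-normalise (default FALSE: per-frame scale).
#' @return A [TransitionMatrix-class] (sem all NA).
#' @examples
#' p <- probabilities(predictedMatrix(0.15, 0.0554))
#' p["4", "2"] / 0.0554^2    # 6 ways of choosing 2 of 4
#' @export
predictedMatrix <- function(pa, pd, nMax = 6L,
                            detachLaw = c("combinatorial", "binomial"),
                            normalise = FALSE) {
  stopifnot(pa > 0, pa < 1, pd > 0, pd < 1, nMax >= 1L)
  detachLaw <- match.arg(detachLaw)
  nMax <- as.integer(nMax)
  p <- matrix(0, nMax, nMax + 1L,
              dimnames = list(start = as.character(seq_len(nMax)),
                              final = as.character(0:nMax)))
  for (i in seq_len(nMax)) {
    for (j in 0:nMax) {
      if (j == i) next
      if (j > i) {
        p[i, j + 1L] <- pa^(j - i)
      } else {
        n <- i - j
        p[i, j + 1L] <- if (detachLaw == "combinatorial") {
          pd^n * factorial(i) / (factorial(j) * factorial(n))
        } else {
          choose(i, n) * pd^n * (1 - pd)^j
        }
      }
    }
  }
  if (normalise) p <- p / rowSums(p)
  new("TransitionMatrix", probabilities = p,
      sem = matrix(NA_real_, nMax, nMax + 1L, dimnames = dimnames(p)),
      rowTotals = rep(NA_real_, nMax), conditional = normalise,
      nMax = nMax, nSources = 0L)
}

#' Estimate the attachment probability Pa
#'
#' The unweighted mean of the first superdiagonal (one myosin joining an
#' existing region) over rows with observations. Given a
#' [TransitionCounts-class], the per-frame (unconditional) probabilities are
#' used, since Pa is a per-frame quantity; given a ready-made
#' [TransitionMatrix-class], its entries are averaged as they stand.
#'
#' @param x a [TransitionCounts-class] or [TransitionMatrix-class].
#' @return numeric(1), the Pa estimate.
#' @examples
#' ## superdiagonal values 0.1 and 0.2 average to 0.15
#' @export
estimatePa <- function(x) {
  if (is(x, "TransitionCounts")) {
    if (sum(x@counts) == 0L) stop("no transitions tallied")
    m <- transitionMatrix(x, conditional = FALSE)
  } else if (is(x, "TransitionMatrix")) {
    m <- x
  } else stop("x must be TransitionCounts or TransitionMatrix")
  p <- m@probabilities
  nMax <- m@nMax
  rows <- seq_len(nMax - 1L)
  vals <- p[cbind(rows, rows + 2L)]   # column j = i+1 is at index i+2
  obs <- if (all(is.na(m@rowTotals))) rep(TRUE, length(rows)) else
    m@rowTotals[rows] > 0
  if (!any(obs)) stop("no observed attachment transitions")
  mean(vals[obs])
}

#' Complete-collapse probability curve
#'
#' Extracts the first column of a transition matrix: the probability that a
#' cluster of size i loses all of its myosins in a single frame, with its
#' across-kymograph SEM (missing for a single kymograph).
#'
#' @param m a [TransitionMatrix-class].
#' @return data.frame with columns size, probability, sem, nObs.
#' @export
collapseCurve <- function(m) {
  stopifnot(is(m, "TransitionMatrix"))
  data.frame(size = seq_len(m@nMax),
             probability = m@probabilities[, "0"],
             sem = m@sem[, "0"],
             nObs = m@rowTotals,
             row.names = NULL)
}

#' Invert a complete-collapse probability to a detachment rate constant
#'
#' Reverses the stochastic construction \eqn{P(i \to 0) = P_d^i} with
#' \eqn{P_d = 1 - e^{-k t}}: given the probability that all i myosins leave
#' within one frame, returns the effective single-molecule detachment rate
#' constant \deqn{k = -\ln(1 - P^{1/i}) / t .}
#' Applied to measured collapse probabilities, this expresses how much
#' faster clusters empty than independent ATP-driven release predicts.
#'
#' @param pCollapse probability in (0,1) (vectorised).
#' @param size cluster size i >= 1 (vectorised with pCollapse).
#' @param frameS frame duration in seconds (default 0.3).
#' @return rate constant(s) in s^-1.
#' @examples
#' invertCollapseRate(0.0554, 1)        # 0.19 s^-1
#' invertCollapseRate(0.35, 2)          # ~3 s^-1
#' @export
invertCollapseRate <- function(pCollapse, size, frameS = 0.3) {
  if (any(!is.finite(pCollapse) | pCollapse <= 0 | pCollapse >= 1)) {
    stop("pCollapse must lie strictly inside (0, 1)")
  }
  stopifnot(all(size >= 1), frameS > 0)
  -log(1 - pCollapse^(1 / size)) / frameS
}

#' Read an archived transition table
#'
#' Reads a transition table laid out as in the archived source data: rows
#' are the starting cluster size (1..nMax), columns the final size
#' (0..nMax), entries conditional probabilities with a zero diagonal. CSV
#' is read directly; `.xlsx` requires the readxl package.
#'
#' @param path CSV or XLSX file.
#' @param sheet sheet index for XLSX (default 1).
#' @return A [TransitionMatrix-class] (conditional, sem NA).
#' @export
readTransitionTable <- function(path, sheet = 1L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path, row.names = 1L, check.names = FALSE)
  } else if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading Excel requires the readxl package")
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
    rownames(df) <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  } else stop("unsupported transition-table format: .", ext)
  p <- as.matrix(df)
  storage.mode(p) <- "double"
  nMax <- nrow(p)
  if (ncol(p) != nMax + 1L) {
    stop("expected nMax rows and nMax+1 columns (final sizes 0..nMax)")
  }
  dimnames(p) <- list(start = as.character(seq_len(nMax)),
                      final = as.character(0:nMax))
  ## renormalise away rounding in archived tables
  rs <- rowSums(p)
  p[rs > 0, ] <- p[rs > 0, ] / rs[rs > 0]
  new("TransitionMatrix", probabilities = p,
      sem = matrix(NA_real_, nMax, nMax + 1L, dimnames = dimnames(p)),
      rowTotals = as.numeric(rs > 0), conditional = TRUE, nMax = nMax,
      nSources = 1L)
}

#' Write a transition matrix in the source-data layout
#'
#' @param m a [TransitionMatrix-class].
#' @param path CSV path.
#' @export
writeTransitionMatrix <- function(m, path) {
  stopifnot(is(m, "TransitionMatrix"))
  write.csv(as.data.frame(m@probabilities), path)
  invisible(path)
}
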