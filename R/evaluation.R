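#' @include occurrence-models.R
NULL

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen presence scores above a randomly
#' chosen absence, with ties counted half:
#' (\#\{p > a\} + 0.5 \#\{p = a\}) / (n_p n_a), computed from rank sums.
#'
#' @param presenceScores,absenceScores non-empty numeric score vectors
#' @return AUC in [0, 1]
#' @export
rocAuc <- function(presenceScores, absenceScores) {
  np <- length(presenceScores); na_ <- length(absenceScores)
  if (np == 0 || na_ == 0) stop("both score lists must be non-empty")
  r <- rank(c(presenceScores, absenceScores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na_)
}

#' Maximum true skill statistic over thresholds
#'
#' Scans candidate thresholds (the midpoints between consecutive sorted
#' unique scores, plus one threshold below and one above the score range,
#' so the trivial all-present/all-absent classifiers are candidates); at
#' each, a cell is predicted present when its score is at least the
#' threshold, and TSS(t) = sensitivity + specificity - 1.
#' Returns the maximum and the threshold attaining it (lowest threshold on
#' ties). Degenerate score sets (fewer than two distinct values) have
#' TSS 0. The statistic's algebraic range is [-1, 1].
#'
#' @param scores numeric scores
#' @param labels logical (or 0/1) presence labels, both classes present
#' @return list with \code{tss} and \code{threshold}
#' @export
maxTss <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2)
    return(list(tss = 0, threshold = u[1]))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  p <- scores[labels]; a <- scores[!labels]
  tssAt <- vapply(cand, function(t)
    mean(p >= t) + mean(a < t) - 1, 0)
  best <- which(tssAt == max(tssAt))[1]   # ties -> lowest threshold
  list(tss = tssAt[best], threshold = cand[best])
}

#' CDF (percentile) normalisation of a suitability surface
#'
#' Replaces each valid cell value by its empirical percentile
#' (rank - 0.5)/n over the valid cells, with average ranks for ties. The
#' output lies strictly inside (0, 1), is invariant under strictly
#' monotone transforms of the input, and maps a constant surface to 0.5
#' everywhere. This puts surfaces from different models on one comparable
#' probability scale.
#'
#' @param surface a \linkS4class{SuitabilitySurface}
#' @return a \linkS4class{SuitabilitySurface} (method tag suffixed
#'   "+cdf")
#' @export
cdfNormalize <- function(surface) {
  grid <- surface@grid
  valid <- which(!grid@nodataMask)
  if (length(valid) == 0) stop("no valid cells")
  v <- surface@values[valid]
  pct <- (rank(v, ties.method = "average") - 0.5) / length(v)
  m <- matrix(NA_real_, grid@nRows, grid@nCols)
  m[valid] <- pct
  SuitabilitySurface(grid, m,
                     methodTag = paste0(surface@methodTag, "+cdf"),
                     params = surface@params)
}

#' Jenks natural breaks (exact Fisher dynamic programming)
#'
#' Exact optimal 1-D classification minimising the within-class sum of
#' squared deviations, by dynamic programming over the sorted values.
#' Returns the nClasses - 1 internal breaks as the upper (maximum) value of
#' classes 1..nClasses-1; ties in the optimum resolve to the
#' lexicographically smallest break vector.
#'
#' @param values numeric vector (needs at least nClasses distinct values)
#' @param nClasses number of classes (>= 1)
#' @return numeric vector of nClasses - 1 breaks (empty for nClasses = 1)
#' @export
jenksBreaks <- function(values, nClasses) {
  if (nClasses < 1) stop("nClasses must be >= 1")
  values <- values[!is.na(values)]
  if (length(unique(values)) < nClasses)
    stop("need at least ", nClasses, " distinct values")
  if (nClasses == 1) return(numeric(0))
  fisherJenksCpp(sort(values), as.integer(nClasses))
}

#' Classify a suitability surface into four levels
#'
#' Combines a data-driven first break with fixed empirical thresholds: the
#' first break b1 comes from a 4-class Jenks run on (a seeded subsample of)
#' the valid cells and is clamped below 0.6 with a warning if needed;
#' classes are then [0, b1) unsuitable, [b1, 0.6) slightly, [0.6, 0.8)
#' moderately and [0.8, 1] highly suitable (boundary 0.8 classifies as
#' highly). Under the "mapping" scheme the surface is first linearly
#' rescaled to [0, 1]; under the "cdf" scheme it must already be
#' CDF-normalised (values within [0, 1]).
#'
#' @param surface a \linkS4class{SuitabilitySurface}
#' @param scheme "mapping" or "cdf"
#' @param maxCells Jenks subsample cap (default 10000)
#' @param seed seed for the subsample
#' @return a \linkS4class{ClassifiedMap}
#' @export
classifySurface <- function(surface, scheme = c("mapping", "cdf"),
                            maxCells = 10000L, seed = 1L) {
  scheme <- match.arg(scheme)
  grid <- surface@grid
  valid <- which(!grid@nodataMask)
  v <- surface@values[valid]
  if (length(unique(v)) < 2)
    stop("degenerate surface: a single distinct value cannot be classified")
  if (scheme == "mapping") {
    rng <- range(v)
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    stop("cdf scheme expects a CDF-normalised surface in [0, 1]")
  }
  sub <- if (length(v) > maxCells)
    withSeed(seed, v[sample.int(length(v), maxCells)]) else v
  nCl <- min(4L, length(unique(sub)))
  b1 <- jenksBreaks(sub, nCl)[1]
  clamped <- FALSE
  if (b1 >= 0.6) {
    warning("first natural break ", format(b1, digits = 4),
            " clamped below the 0.6 empirical threshold")
    b1 <- 0.6 - 1e-9
    clamped <- TRUE
  }
  cl <- findInterval(v, c(b1, 0.6, 0.8)) + 1L
  m <- matrix(NA_integer_, grid@nRows, grid@nCols)
  m[valid] <- cl
  new("ClassifiedMap", grid = grid, classes = m,
      breaksUsed = c(b1, 0.6, 0.8), schemeTag = scheme,
      params = list(subsample = min(length(v), maxCells), seed = seed,
                    clamped = clamped, source = surface@methodTag))
}
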