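#' @include evaluation.R
NULL

#' Class area proportions
#'
#' @param map a \linkS4class{ClassifiedMap}
#' @return named numeric: percentage of valid cells per class (sums to 100)
#' @export
areaProportions <- function(map) {
  cl <- map@classes[!map@grid@nodataMask]
  if (length(cl) == 0) stop("no valid cells")
  counts <- tabulate(cl, nbins = 4L)
  stats::setNames(100 * counts / length(cl), CLASS_LEVELS)
}

#' Occurrence hit rates per suitability class
#'
#' Each occurrence is assigned the class of its containing cell; points on
#' masked cells or outside the grid are excluded and counted in the
#' report. Percentages are over the included points.
#'
#' @param map a \linkS4class{ClassifiedMap}
#' @param occurrences an \linkS4class{OccurrenceSet}
#' @return list with \code{rates} (named percentages), \code{included} and
#'   \code{excluded} point counts
#' @export
hitRates <- function(map, occurrences) {
  idx <- cellIndexOf(map@grid, occurrences@points[, "lon"],
                     occurrences@points[, "lat"])
  ok <- !is.na(idx$cell) & !idx$masked
  if (!any(ok)) stop("all occurrence points fall on masked cells")
  cl <- map@classes[idx$cell[ok]]
  counts <- tabulate(cl, nbins = 4L)
  list(rates = stats::setNames(100 * counts / sum(ok), CLASS_LEVELS),
       included = sum(ok), excluded = sum(!ok))
}

#' Jaccard overlap of two classified maps
#'
#' |A intersect B| / |A union B| over valid cells, where A and B are the
#' cell sets falling in \code{classSet} in each map. When both sets are
#' empty the index is defined as 1 (identical emptiness) with a warning.
#'
#' @param mapA,mapB \linkS4class{ClassifiedMap}s on an identical grid
#' @param classSet subset of \code{\link{suitabilityClasses}}
#' @return Jaccard index in [0, 1]
#' @export
jaccardOverlap <- function(mapA, mapB, classSet = "highly") {
  if (!sameGrid(mapA, mapB)) stop("maps must share one grid")
  codes <- match(classSet, CLASS_LEVELS)
  if (anyNA(codes)) stop("unknown class in classSet")
  valid <- !mapA@grid@nodataMask
  a <- matrix(mapA@classes %in% codes, nrow(valid))[valid]
  b <- matrix(mapB@classes %in% codes, nrow(valid))[valid]
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both class sets empty; Jaccard defined as 1")
    return(1)
  }
  sum(a & b) / uni
}

#' Cross-model agreement map and Jaccard matrix
#'
#' Counts, per cell, how many of the classified maps assign a class in
#' \code{classSet}, and computes the pairwise Jaccard matrix of the
#' corresponding cell sets.
#'
#' @param maps named list of at least two \linkS4class{ClassifiedMap}s on
#'   one grid
#' @param classSet subset of \code{\link{suitabilityClasses}}
#' @return an \linkS4class{AgreementResult}
#' @export
agreementMap <- function(maps, classSet = "highly") {
  if (length(maps) < 2) stop("need at least two maps")
  grid <- maps[[1]]@grid
  for (m in maps[-1])
    if (!sameGrid(m, grid)) stop("maps must share one grid")
  codes <- match(classSet, CLASS_LEVELS)
  if (anyNA(codes)) stop("unknown class in classSet")
  count <- matrix(0L, grid@nRows, grid@nCols)
  for (m in maps)
    count <- count + matrix(as.integer(m@classes %in% codes),
                            grid@nRows, grid@nCols)
  count[grid@nodataMask] <- NA_integer_
  M <- length(maps)
  jac <- matrix(1, M, M)
  nms <- if (!is.null(names(maps))) names(maps)
  else paste0("map", seq_len(M))
  dimnames(jac) <- list(nms, nms)
  for (i in seq_len(M - 1)) for (j in (i + 1):M)
    jac[i, j] <- jac[j, i] <-
      suppressWarnings(jaccardOverlap(maps[[i]], maps[[j]], classSet))
  new("AgreementResult", countMap = count, jaccard = jac,
      classSet = classSet, grid = grid)
}
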