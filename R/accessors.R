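#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("rasterGrid", "EnvLayer", function(x) x@grid)
#' @rdname accessors
setMethod("rasterGrid", "ScoreStack", function(x) x@grid)
#' @rdname accessors
setMethod("rasterGrid", "SuitabilitySurface", function(x) x@grid)
#' @rdname accessors
setMethod("rasterGrid", "ClassifiedMap", function(x) x@grid)
#' @rdname accessors
setMethod("rasterGrid", "AgreementResult", function(x) x@grid)
#' @rdname accessors
setMethod("rasterGrid", "SyntheticTruth", function(x) x@trueSurface@grid)

#' @rdname accessors
setMethod("cellValues", "EnvLayer", function(x) x@values)
#' @rdname accessors
setMethod("cellValues", "SuitabilitySurface", function(x) x@values)
#' @rdname accessors
setMethod("cellValues", "ScoreStack", function(x) x@scores)
#' @rdname accessors
setMethod("cellValues", "AgreementResult", function(x) x@countMap)

#' @rdname accessors
setMethod("nodataMask", "RasterGrid", function(x) x@nodataMask)
#' @rdname accessors
setMethod("nodataMask", "EnvLayer", function(x) x@grid@nodataMask)
#' @rdname accessors
setMethod("nodataMask", "SuitabilitySurface", function(x) x@grid@nodataMask)

#' @rdname accessors
setMethod("variableNames", "ScoreStack", function(x) x@variableOrder)
#' @rdname accessors
setMethod("variableNames", "WeightVector", function(x) names(x@weights))
#' @rdname accessors
setMethod("variableNames", "JudgmentMatrix", function(x) x@labels)

#' @rdname accessors
setMethod("criterionWeights", "WeightVector", function(x) x@weights)
#' @rdname accessors
setMethod("criterionWeights", "AhpResult", function(x) x@weights@weights)

#' @rdname accessors
setMethod("methodTag", "SuitabilitySurface", function(x) x@methodTag)
#' @rdname accessors
setMethod("methodTag", "ClassifiedMap", function(x) x@schemeTag)

#' @rdname accessors
setMethod("classValues", "ClassifiedMap", function(x) x@classes)

#' @rdname accessors
setMethod("occurrenceCoords", "OccurrenceSet", function(x) x@points)

#' @rdname accessors
setMethod("consistencyRatio", "AhpResult", function(x) x@consistencyRatio)

#' Number of occurrence points
#' @param x an \linkS4class{OccurrenceSet}
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@points))

#' Cell-center coordinates of a grid
#'
#' @param grid a \linkS4class{RasterGrid}
#' @param rows,cols optional row/col indices (recycled together); default all
#'   cells in column-major order
#' @return matrix with columns lon, lat of cell centers (degrees)
#' @export
cellCenters <- function(grid, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    rows <- rep(seq_len(grid@nRows), times = grid@nCols)
    cols <- rep(seq_len(grid@nCols), each = grid@nRows)
  }
  cbind(lon = grid@origin[1] + (cols - 0.5) * grid@cellSize,
        lat = grid@origin[2] - (rows - 0.5) * grid@cellSize)
}

#' Locate points on a grid
#'
#' Maps lon/lat points to (row, col) cell indices under the half-open cell
#' convention (a point on a shared edge belongs to the cell south/east of
#' it). Points outside the grid extent get \code{NA} indices.
#'
#' @param grid a \linkS4class{RasterGrid}
#' @param lon,lat coordinate vectors in degrees
#' @return data.frame with columns row, col, cell (column-major linear
#'   index), masked (logical; \code{NA} when outside the extent)
#' @export
cellIndexOf <- function(grid, lon, lat) {
  col <- floor((lon - grid@origin[1]) / grid@cellSize) + 1
  row <- floor((grid@origin[2] - lat) / grid@cellSize) + 1
  # points exactly on the east/south outer edge belong to the last cell
  col[lon == grid@origin[1] + grid@nCols * grid@cellSize] <- grid@nCols
  row[lat == grid@origin[2] - grid@nRows * grid@cellSize] <- grid@nRows
  inside <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= grid@nRows & col >= 1 & col <= grid@nCols
  row[!inside] <- NA_integer_; col[!inside] <- NA_integer_
  cell <- row + (col - 1L) * grid@nRows
  masked <- rep(NA, length(row))
  ok <- !is.na(cell)
  masked[ok] <- grid@nodataMask[cbind(row[ok], col[ok])]
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer(cell), masked = masked)
}

#' Test whether two objects share a grid
#' @param a,b objects with a \code{rasterGrid} method or RasterGrids
#' @return logical
#' @export
sameGrid <- function(a, b) {
  ga <- if (is(a, "RasterGrid")) a else rasterGrid(a)
  gb <- if (is(b, "RasterGrid")) b else rasterGrid(b)
  ga@nRows == gb@nRows && ga@nCols == gb@nCols &&
    isTRUE(all.equal(ga@origin, gb@origin)) &&
    isTRUE(all.equal(ga@cellSize, gb@cellSize)) &&
    identical(ga@nodataMask, gb@nodataMask)
}
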