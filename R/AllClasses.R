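#' @import methods
NULL

CLASS_LEVELS <- c("unsuitable", "slightly", "moderately", "highly")

#' RasterGrid: shared grid definition
#'
#' Defines the grid every layer, surface and classified map in a run refers
#' to: dimensions, geographic placement of the upper-left corner, cell size in
#' decimal degrees, a CRS identifier and a per-cell nodata mask. Row 1 is the
#' northernmost row; cells are addressed (row, col) with half-open cell
#' intervals, so a point on a shared edge belongs to the cell to the
#' south/east of it.
#'
#' @slot nRows,nCols grid dimensions (>= 1)
#' @slot origin numeric length-2, (lon, lat) of the upper-left cell corner in
#'   decimal degrees
#' @slot cellSize cell edge length in decimal degrees (> 0)
#' @slot crsId free-text CRS identifier (default "EPSG:4326")
#' @slot nodataMask logical nRows x nCols matrix, \code{TRUE} where the cell
#'   carries no data
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(
    nRows = "integer", nCols = "integer",
    origin = "numeric", cellSize = "numeric",
    crsId = "character", nodataMask = "matrix"
  )
)

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (length(object@origin) != 2L || anyNA(object@origin))
    msg <- c(msg, "origin must be a finite (lon, lat) pair")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (!is.logical(object@nodataMask) ||
      !identical(dim(object@nodataMask), c(object@nRows, object@nCols)))
    msg <- c(msg, "nodataMask must be a logical nRows x nCols matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterGrid
#'
#' @param nRows,nCols grid dimensions
#' @param origin (lon, lat) of the upper-left corner in degrees
#' @param cellSize cell edge in degrees
#' @param crsId CRS identifier string
#' @param nodataMask logical matrix (\code{TRUE} = nodata); default all valid
#' @return a \linkS4class{RasterGrid}
#' @examples
#' g <- RasterGrid(10, 10, origin = c(80, 45), cellSize = 0.01)
#' @export
RasterGrid <- function(nRows, nCols, origin = c(0, 0), cellSize = 0.01,
                       crsId = "EPSG:4326", nodataMask = NULL) {
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  if (is.na(nRows) || is.na(nCols) || nRows < 1L || nCols < 1L)
    stop("grid dimensions must be positive integers")
  if (is.null(nodataMask))
    nodataMask <- matrix(FALSE, nRows, nCols)
  new("RasterGrid", nRows = nRows, nCols = nCols,
      origin = as.numeric(origin), cellSize = as.numeric(cellSize),
      crsId = crsId, nodataMask = nodataMask)
}

#' EnvLayer: one environmental variable on a grid
#'
#' @slot grid the \linkS4class{RasterGrid} the values live on
#' @slot values numeric nRows x nCols matrix; \code{NA} on masked cells
#' @slot variableName,units free-text metadata
#' @exportClass EnvLayer
setClass("EnvLayer",
  representation(grid = "RasterGrid", values = "matrix",
                 variableName = "character", units = "character")
)

setValidity("EnvLayer", function(object) {
  g <- object@grid
  if (!identical(dim(object@values), c(g@nRows, g@nCols)))
    return("values must match the grid dimensions")
  if (any(!is.finite(object@values[!g@nodataMask])))
    return("values must be finite on all non-masked cells")
  TRUE
})

#' Construct an EnvLayer
#' @param grid a \linkS4class{RasterGrid}
#' @param values numeric matrix matching the grid
#' @param variableName variable name
#' @param units unit string
#' @return an \linkS4class{EnvLayer}
#' @export
EnvLayer <- function(grid, values, variableName = "var", units = "") {
  values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  values[grid@nodataMask] <- NA_real_
  new("EnvLayer", grid = grid, values = values,
      variableName = variableName, units = units)
}

#' ScoreStack: per-cell, per-variable 1-5 suitability scores
#'
#' Houses the standardized suitability scores produced by grading an
#' environmental stack; the input to every multi-criteria combiner.
#'
#' @slot grid the shared \linkS4class{RasterGrid}
#' @slot scores integer array nRows x nCols x nVars, values in 1..5 on valid
#'   cells, \code{NA} on masked cells
#' @slot variableOrder variable names, one per slice, no duplicates
#' @exportClass ScoreStack
setClass("ScoreStack",
  representation(grid = "RasterGrid", scores = "array",
                 variableOrder = "character")
)

setValidity("ScoreStack", function(object) {
  g <- object@grid
  d <- dim(object@scores)
  if (length(d) != 3L || d[1] != g@nRows || d[2] != g@nCols)
    return("scores must be an nRows x nCols x nVars array")
  if (d[3] != length(object@variableOrder))
    return("variableOrder length must match the number of score slices")
  if (anyDuplicated(object@variableOrder))
    return("variableOrder must not contain duplicates")
  valid <- rep(!g@nodataMask, d[3])
  sc <- object@scores[valid]
  if (anyNA(sc) || any(sc < 1L | sc > 5L))
    return("scores on valid cells must lie in 1..5")
  TRUE
})

ScoreStack <- function(grid, scores, variableOrder) {
  new("ScoreStack", grid = grid, scores = scores,
      variableOrder = variableOrder)
}

#' WeightVector: criterion weights summing to one
#'
#' @slot weights named nonnegative numeric vector summing to 1 (within 1e-9)
#' @exportClass WeightVector
setClass("WeightVector", representation(weights = "numeric"))

setValidity("WeightVector", function(object) {
  w <- object@weights
  if (is.null(names(w)) || anyDuplicated(names(w)))
    return("weights must carry unique variable names")
  if (any(w < 0)) return("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 within 1e-9")
  TRUE
})

#' Construct a WeightVector
#' @param weights named nonnegative numeric; normalised to sum 1 when
#'   \code{normalize = TRUE}
#' @param normalize divide by the sum first (default TRUE)
#' @return a \linkS4class{WeightVector}
#' @export
WeightVector <- function(weights, normalize = TRUE) {
  if (normalize) {
    s <- sum(weights)
    if (s <= 0) stop("weights must have a positive sum")
    weights <- weights / s
  }
  new("WeightVector", weights = weights)
}

#' SuitabilitySurface: continuous per-cell suitability
#'
#' @slot grid the shared \linkS4class{RasterGrid}
#' @slot values numeric matrix, defined on all non-masked cells
#' @slot methodTag short tag identifying the producing method
#'   (e.g. "ahp", "topsis", "owa", "glm", "ensemble", "truth")
#' @slot params list of method parameters (e.g. the OWA decision parameter)
#' @exportClass SuitabilitySurface
setClass("SuitabilitySurface",
  representation(grid = "RasterGrid", values = "matrix",
                 methodTag = "character", params = "list")
)

setValidity("SuitabilitySurface", function(object) {
  g <- object@grid
  if (!identical(dim(object@values), c(g@nRows, g@nCols)))
    return("values must match the grid dimensions")
  if (any(!is.finite(object@values[!g@nodataMask])))
    return("surface must be defined on all non-masked cells")
  TRUE
})

SuitabilitySurface <- function(grid, values, methodTag = "surface",
                               params = list()) {
  values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  values[grid@nodataMask] <- NA_real_
  new("SuitabilitySurface", grid = grid, values = values,
      methodTag = methodTag, params = params)
}

#' ClassifiedMap: four-level suitability classification
#'
#' Classes are coded 1..4 = unsuitable, slightly, moderately, highly
#' suitable; \code{breaksUsed} records the three interval boundaries
#' (first natural break, 0.6, 0.8).
#'
#' @slot grid the shared \linkS4class{RasterGrid}
#' @slot classes integer matrix in 1..4 on valid cells, \code{NA} elsewhere
#' @slot breaksUsed numeric length 3: (b1, 0.6, 0.8), b1 < 0.6
#' @slot schemeTag "mapping" (linear 0-1 rescale) or "cdf"
#' @slot params bookkeeping (subsample size, clamping, seed)
#' @exportClass ClassifiedMap
setClass("ClassifiedMap",
  representation(grid = "RasterGrid", classes = "matrix",
                 breaksUsed = "numeric", schemeTag = "character",
                 params = "list")
)

setValidity("ClassifiedMap", function(object) {
  g <- object@grid
  if (!identical(dim(object@classes), c(g@nRows, g@nCols)))
    return("classes must match the grid dimensions")
  cl <- object@classes[!g@nodataMask]
  if (anyNA(cl) || any(cl < 1L | cl > 4L))
    return("classes on valid cells must lie in 1..4")
  if (length(object@breaksUsed) != 3L || object@breaksUsed[1] >= 0.6)
    return("breaksUsed must be (b1, 0.6, 0.8) with b1 < 0.6")
  if (!object@schemeTag %in% c("mapping", "cdf"))
    return("schemeTag must be 'mapping' or 'cdf'")
  TRUE
})

#' OccurrenceSet: presence (or pseudo-absence) points
#'
#' @slot points numeric matrix with columns \code{lon}, \code{lat} (degrees)
#' @slot speciesLabel species or sample label
#' @slot provenance free-text origin ("simulated", "thinned", ...)
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(points = "matrix", speciesLabel = "character",
                 provenance = "character")
)

setValidity("OccurrenceSet", function(object) {
  p <- object@points
  if (ncol(p) != 2L || !identical(colnames(p), c("lon", "lat")))
    return("points must be a matrix with columns lon, lat")
  if (nrow(p) > 0 && any(!is.finite(p)))
    return("coordinates must be finite")
  TRUE
})

#' Construct an OccurrenceSet
#' @param lon,lat coordinate vectors in decimal degrees
#' @param speciesLabel species label
#' @param provenance origin note
#' @return an \linkS4class{OccurrenceSet}
#' @export
OccurrenceSet <- function(lon = numeric(), lat = numeric(),
                          speciesLabel = "sp", provenance = "unknown") {
  p <- cbind(lon = as.numeric(lon), lat = as.numeric(lat))
  new("OccurrenceSet", points = p, speciesLabel = speciesLabel,
      provenance = provenance)
}

#' SyntheticTruth: a simulated landscape with known ground truth
#'
#' @slot envStack list of \linkS4class{EnvLayer}
#' @slot trueSurface \linkS4class{SuitabilitySurface} in [0,1]
#' @slot generatingWeights the \linkS4class{WeightVector} used to build truth
#' @slot seed integer seed that regenerates the object bit-identically
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(envStack = "list", trueSurface = "SuitabilitySurface",
                 generatingWeights = "WeightVector", seed = "integer")
)

#' GradingTable: expert 1-5 suitability grading rules for one variable
#'
#' Interval rules are unions of half-open [low, high) intervals (infinite
#' bounds allowed); categorical rules are sets of integer codes. Values
#' matched by no rule receive \code{fallbackScore} (least suitable).
#'
#' @slot variableName the graded variable
#' @slot kind "interval" or "categorical"
#' @slot rules list of \code{list(score =, lower =, upper =)} (interval) or
#'   \code{list(score =, codes =)} (categorical)
#' @slot fallbackScore score for unmatched values (default 1)
#' @exportClass GradingTable
setClass("GradingTable",
  representation(variableName = "character", kind = "character",
                 rules = "list", fallbackScore = "integer")
)

setValidity("GradingTable", function(object) {
  if (!object@kind %in% c("interval", "categorical"))
    return("kind must be 'interval' or 'categorical'")
  if (object@fallbackScore < 1L || object@fallbackScore > 5L)
    return("fallbackScore must lie in 1..5")
  for (r in object@rules) {
    if (r$score < 1 || r$score > 5) return("rule scores must lie in 1..5")
    if (object@kind == "interval") {
      if (length(r$lower) != length(r$upper) || length(r$lower) == 0)
        return("interval rules need matching non-empty lower/upper")
      if (any(r$lower >= r$upper))
        return("intervals must satisfy lower < upper")
    } else if (length(r$codes) == 0) {
      return("categorical rules need a non-empty code set")
    }
  }
  if (object@kind == "interval") {
    lows <- unlist(lapply(object@rules, `[[`, "lower"))
    ups  <- unlist(lapply(object@rules, `[[`, "upper"))
    o <- order(lows)
    if (length(lows) > 1 && any(ups[o][-length(o)] > lows[o][-1] + 1e-12))
      return("interval conditions must be pairwise disjoint")
  }
  TRUE
})

GradingTable <- function(variableName, kind, rules, fallbackScore = 1L) {
  rules <- lapply(rules, function(r) { r$score <- as.integer(r$score); r })
  new("GradingTable", variableName = variableName, kind = kind,
      rules = rules, fallbackScore = as.integer(fallbackScore))
}

#' JudgmentMatrix: reciprocal pairwise-comparison matrix on the 1-9 scale
#'
#' @slot mat n x n positive matrix with unit diagonal, entries in [1/9, 9],
#'   and \code{mat[j, i] == 1 / mat[i, j]}
#' @slot labels criterion names (rownames of \code{mat})
#' @exportClass JudgmentMatrix
setClass("JudgmentMatrix",
  representation(mat = "matrix", labels = "character")
)

setValidity("JudgmentMatrix", function(object) {
  m <- object@mat
  n <- nrow(m)
  if (n != ncol(m)) return("matrix must be square")
  if (length(object@labels) != n) return("labels must match matrix order")
  if (any(abs(diag(m) - 1) > 1e-9)) return("diagonal entries must all be 1")
  if (any(m < 1 / 9 - 1e-9 | m > 9 + 1e-9))
    return("entries must lie on the 1/9..9 scale")
  if (max(abs(m * t(m) - 1)) > 1e-6)
    return("matrix must be reciprocal: m[j,i] = 1/m[i,j]")
  TRUE
})

#' Construct a JudgmentMatrix
#' @param mat square positive reciprocal matrix
#' @param labels criterion names; defaults to rownames
#' @return a \linkS4class{JudgmentMatrix}
#' @export
JudgmentMatrix <- function(mat, labels = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(labels)) labels <- paste0("c", seq_len(nrow(mat)))
  dimnames(mat) <- list(labels, labels)
  new("JudgmentMatrix", mat = mat, labels = labels)
}

#' AhpResult: weights plus consistency diagnostics
#'
#' @slot weights derived \linkS4class{WeightVector}
#' @slot lambdaMax principal eigenvalue
#' @slot consistencyIndex (lambdaMax - n) / (n - 1)
#' @slot consistencyRatio consistencyIndex / randomIndex(n)
#' @slot acceptable \code{TRUE} iff consistencyRatio < 0.1
#' @exportClass AhpResult
setClass("AhpResult",
  representation(weights = "WeightVector", lambdaMax = "numeric",
                 consistencyIndex = "numeric", consistencyRatio = "numeric",
                 acceptable = "logical")
)

setValidity("AhpResult", function(object) {
  if (!identical(object@acceptable, object@consistencyRatio < 0.1))
    return("acceptable must equal (consistencyRatio < 0.1)")
  TRUE
})

#' ModelEval: repeated cross-validation summary
#'
#' @slot aucMean,aucSd,tssMean,tssSd summary statistics over all folds
#' @slot folds data.frame with one row per (repeat, fold) evaluation
#' @slot k,repeats,seed the cross-validation design
#' @exportClass ModelEval
setClass("ModelEval",
  representation(aucMean = "numeric", aucSd = "numeric",
                 tssMean = "numeric", tssSd = "numeric",
                 folds = "data.frame", k = "integer", repeats = "integer",
                 seed = "integer")
)

#' ScreeningReport: collinearity screening outcome
#'
#' @slot retained,dropped variable names (a partition of the input set)
#' @slot pairCorrelations data.frame (varA, varB, rho)
#' @slot tieBreakerScores per-variable univariate AUC used to break pairs
#' @slot threshold the |rho| threshold applied
#' @slot notes warnings (constant layers etc.)
#' @exportClass ScreeningReport
setClass("ScreeningReport",
  representation(retained = "character", dropped = "character",
                 pairCorrelations = "data.frame",
                 tieBreakerScores = "numeric", threshold = "numeric",
                 notes = "character")
)

#' AgreementResult: cross-model spatial agreement
#'
#' @slot countMap integer matrix: per cell, how many maps assign a class in
#'   the target class set
#' @slot jaccard symmetric pairwise Jaccard matrix in [0,1]
#' @slot classSet the class labels counted
#' @slot grid the shared grid
#' @exportClass AgreementResult
setClass("AgreementResult",
  representation(countMap = "matrix", jaccard = "matrix",
                 classSet = "character", grid = "RasterGrid")
)

#' FeatureSet: river/lake geometries as vertex chains
#'
#' Geometries are polylines/polygons given as dense vertex matrices
#' (columns lon, lat); distances are computed to vertices, so curves should
#' be vertexed finely relative to the grid cell size.
#'
#' @slot geometries list of 2-column numeric matrices (lon, lat)
#' @slot featureType "river" or "lake"
#' @exportClass FeatureSet
setClass("FeatureSet",
  representation(geometries = "list", featureType = "character")
)

setValidity("FeatureSet", function(object) {
  if (length(object@geometries) < 1) return("need at least one geometry")
  for (g in object@geometries) {
    if (!is.matrix(g) || ncol(g) != 2) return("geometries must be n x 2")
    if (any(abs(g[, 1]) > 360) || any(abs(g[, 2]) > 90))
      return("vertices outside plausible lon/lat bounds")
  }
  if (!object@featureType %in% c("river", "lake"))
    return("featureType must be 'river' or 'lake'")
  TRUE
})

#' Construct a FeatureSet
#' @param geometries list of 2-column matrices of (lon, lat) vertices
#' @param featureType "river" or "lake"
#' @return a \linkS4class{FeatureSet}
#' @export
FeatureSet <- function(geometries, featureType = "river") {
  if (is.matrix(geometries)) geometries <- list(geometries)
  new("FeatureSet", geometries = geometries, featureType = featureType)
}

#' The four suitability class labels
#'
#' @return character vector: unsuitable, slightly, moderately, highly
#' @export
suitabilityClasses <- function() CLASS_LEVELS
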