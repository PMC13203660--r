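#' @include accessors.R
NULL

setMethod("show", "RasterGrid", function(object) {
  cat("RasterGrid:", object@nRows, "x", object@nCols, "cells,",
      format(object@cellSize), "deg resolution\n")
  cat("  origin (UL corner):", format(object@origin[1]), "E,",
      format(object@origin[2]), "N  [", object@crsId, "]\n")
  cat("  nodata cells:", sum(object@nodataMask), "/",
      length(object@nodataMask), "\n")
})

setMethod("show", "EnvLayer", function(object) {
  v <- object@values[!object@grid@nodataMask]
  cat("EnvLayer '", object@variableName, "'",
      if (nzchar(object@units)) paste0(" [", object@units, "]"), "\n",
      sep = "")
  cat("  grid:", object@grid@nRows, "x", object@grid@nCols,
      " range:", format(min(v)), "..", format(max(v)), "\n")
})

setMethod("show", "ScoreStack", function(object) {
  cat("ScoreStack:", length(object@variableOrder), "graded variables on a",
      object@grid@nRows, "x", object@grid@nCols, "grid\n")
  cat("  variables:", paste(object@variableOrder, collapse = ", "), "\n")
})

setMethod("show", "WeightVector", function(object) {
  cat("WeightVector (", length(object@weights), " criteria):\n", sep = "")
  print(round(object@weights, 4))
})

setMethod("show", "SuitabilitySurface", function(object) {
  v <- object@values[!object@grid@nodataMask]
  cat("SuitabilitySurface [", object@methodTag, "] on a ",
      object@grid@nRows, " x ", object@grid@nCols, " grid\n", sep = "")
  cat("  range:", format(min(v)), "..", format(max(v)), "\n")
  if (length(object@params))
    cat("  params:", paste(names(object@params),
        vapply(object@params, function(p) format(p)[1], ""),
        sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ClassifiedMap", function(object) {
  cat("ClassifiedMap [", object@schemeTag, " scheme], breaks (",
      paste(format(object@breaksUsed, digits = 4), collapse = ", "),
      ")\n", sep = "")
  tab <- areaProportions(object)
  print(round(tab, 2))
})

setMethod("show", "OccurrenceSet", function(object) {
  cat("OccurrenceSet '", object@speciesLabel, "': ", nrow(object@points),
      " points (", object@provenance, ")\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: ", length(object@envStack),
      " environmental layers, seed ", object@seed, "\n", sep = "")
  show(object@trueSurface)
})

setMethod("show", "AhpResult", function(object) {
  cat("AhpResult: lambda_max = ", format(object@lambdaMax, digits = 8),
      ", CI = ", format(object@consistencyIndex, digits = 4),
      ", CR = ", format(object@consistencyRatio, digits = 4),
      if (object@acceptable) " (acceptable)" else " (NOT acceptable)",
      "\n", sep = "")
  show(object@weights)
})

setMethod("show", "ModelEval", function(object) {
  cat("ModelEval: ", object@k, "-fold x ", object@repeats, " repeats (",
      nrow(object@folds), " evaluations)\n", sep = "")
  cat("  AUC ", format(object@aucMean, digits = 4), " +/- ",
      format(object@aucSd, digits = 4), "   TSS ",
      format(object@tssMean, digits = 4), " +/- ",
      format(object@tssSd, digits = 4), "\n", sep = "")
})

setMethod("show", "ScreeningReport", function(object) {
  cat("ScreeningReport (|rho| > ", object@threshold, "): ",
      length(object@retained), " retained, ", length(object@dropped),
      " dropped\n", sep = "")
  if (length(object@dropped))
    cat("  dropped:", paste(object@dropped, collapse = ", "), "\n")
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "AgreementResult", function(object) {
  cat("AgreementResult over classes {",
      paste(object@classSet, collapse = ", "), "}: ",
      nrow(object@jaccard), " maps\n", sep = "")
  print(round(object@jaccard, 3))
})
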