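#' @include geo-prep.R
NULL

ruleFromYaml <- function(entry, kind) {
  if (kind == "interval") {
    iv <- entry$intervals
    lower <- vapply(iv, function(x) as.numeric(x[[1]]), 0)
    upper <- vapply(iv, function(x) as.numeric(x[[2]]), 0)
    list(score = as.integer(entry$score), lower = lower, upper = upper)
  } else {
    list(score = as.integer(entry$score),
         codes = as.integer(unlist(entry$codes)))
  }
}

#' Load grading tables from YAML
#'
#' The YAML file holds one entry per variable with its kind ("interval" or
#' "categorical"), an optional fallback score, and rules mapping half-open
#' [low, high) interval unions (or integer code sets) to scores 1..5.
#' Overlapping intervals or out-of-range scores are load errors.
#'
#' @param path path to a grading YAML file
#' @return named list of \linkS4class{GradingTable}
#' @seealso \code{\link{defaultGradingTables}} for the shipped default set
#' @export
loadGradingTables <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- list()
  for (v in doc$variables) {
    rules <- lapply(v$rules, ruleFromYaml, kind = v$kind)
    fb <- if (is.null(v$fallback)) 1L else as.integer(v$fallback)
    out[[v$name]] <- GradingTable(v$name, v$kind, rules, fb)
  }
  out
}

#' Save grading tables to YAML
#' @param tables named list of \linkS4class{GradingTable}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
saveGradingTables <- function(tables, path) {
  vars <- lapply(tables, function(t) {
    rules <- lapply(t@rules, function(r) {
      if (t@kind == "interval")
        list(score = r$score,
             intervals = mapply(function(l, u) list(l, u),
                                r$lower, r$upper, SIMPLIFY = FALSE))
      else list(score = r$score, codes = as.list(r$codes))
    })
    list(name = t@variableName, kind = t@kind,
         fallback = t@fallbackScore, rules = rules)
  })
  yaml::write_yaml(list(variables = unname(vars)), path)
  invisible(path)
}

#' The shipped default grading table set
#'
#' Twelve expert grading tables for the arid-grassland predictor set used by
#' \code{\link{defaultStackConfig}}: development-period temperature and
#' precipitation, overwintering LST and precipitation, NDVI, land cover,
#' aspect, slope, clay, sand, and distances to rivers and lakes. Land-cover
#' codes: 1 other, 2 desert, 3 forest, 4 gravels, 5 farmland, 6 grassland,
#' 7 meadow. Aspect codes: 0 flat, 1 N, 2 NE, 3 E, 4 SE, 5 S, 6 SW, 7 W,
#' 8 NW.
#'
#' @return named list of \linkS4class{GradingTable}
#' @export
defaultGradingTables <- function() {
  loadGradingTables(system.file("extdata", "grading_tables.yaml",
                                package = "habicomp", mustWork = TRUE))
}

#' Grade one environmental layer to 1-5 suitability scores
#'
#' Every valid cell value is mapped by the first matching rule of the
#' table; values matched by no rule receive the fallback score (least
#' suitable) and a warning reports how many cells fell through.
#'
#' @param layer an \linkS4class{EnvLayer}
#' @param table the matching \linkS4class{GradingTable}
#' @return an \linkS4class{EnvLayer} of integer scores in 1..5
#' @export
gradeLayer <- function(layer, table) {
  v <- layer@values
  valid <- !is.na(v)
  if (table@kind == "categorical") {
    vv <- v[valid]
    if (any(vv != round(vv)))
      stop("categorical grading table '", table@variableName,
           "' applied to a non-integer layer")
  }
  score <- matrix(NA_integer_, nrow(v), ncol(v))
  for (r in table@rules) {
    if (table@kind == "interval") {
      hit <- valid & is.na(score) &
        Reduce(`|`, mapply(function(lo, hi) v >= lo & v < hi,
                           r$lower, r$upper, SIMPLIFY = FALSE))
    } else {
      hit <- valid & is.na(score) & matrix(v %in% r$codes, nrow(v), ncol(v))
    }
    score[hit] <- r$score
  }
  unmatched <- valid & is.na(score)
  if (any(unmatched)) {
    warning(sum(unmatched), " cell(s) of '", table@variableName,
            "' matched no grading rule; assigned fallback score ",
            table@fallbackScore)
    score[unmatched] <- table@fallbackScore
  }
  EnvLayer(layer@grid, score, variableName = table@variableName,
           units = "score")
}

#' Grade a stack of layers into a ScoreStack
#'
#' @param stack named list of \linkS4class{EnvLayer}
#' @param tables named list of \linkS4class{GradingTable} covering every
#'   stack variable
#' @return a \linkS4class{ScoreStack} in the stack's variable order, on the
#'   combined nodata mask of all layers
#' @export
gradeStack <- function(stack, tables) {
  if (is.null(names(stack)))
    names(stack) <- vapply(stack, function(l) l@variableName, "")
  missing <- setdiff(names(stack), names(tables))
  if (length(missing))
    stop("missing grading table for: ", paste(missing, collapse = ", "))
  graded <- lapply(names(stack), function(nm)
    gradeLayer(stack[[nm]], tables[[nm]]))
  g0 <- stack[[1]]@grid
  mask <- Reduce(`|`, lapply(graded, function(l) is.na(l@values))) |
    g0@nodataMask
  grid <- RasterGrid(g0@nRows, g0@nCols, g0@origin, g0@cellSize, g0@crsId,
                     nodataMask = mask)
  arr <- array(NA_integer_, c(grid@nRows, grid@nCols, length(graded)))
  for (i in seq_along(graded)) {
    m <- graded[[i]]@values
    m[mask] <- NA_integer_
    arr[, , i] <- m
  }
  ScoreStack(grid, arr, names(stack))
}
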