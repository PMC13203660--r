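#' @include synthetic-landscape.R
NULL

KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON_EQ <- 111.320

#' Project lon/lat to local planar kilometres
#'
#' Equirectangular projection about the grid's mean latitude: adequate for
#' the regional extents the package targets, where a degree of longitude is
#' treated as \code{111.320 * cos(latRef)} km and a degree of latitude as
#' 110.574 km.
#'
#' @param grid a \linkS4class{RasterGrid} providing the reference latitude
#' @param lon,lat coordinates in degrees
#' @return matrix with columns x, y in km
#' @export
projectLocalKm <- function(grid, lon, lat) {
  latRef <- grid@origin[2] - grid@nRows * grid@cellSize / 2
  cbind(x = lon * KM_PER_DEG_LON_EQ * cos(latRef * pi / 180),
        y = lat * KM_PER_DEG_LAT)
}

# Resample one layer onto a target grid ("nearest" or "bilinear").
resampleLayer <- function(layer, target, method) {
  if (sameGrid(layer@grid, target) && method != "force")
    return(layer@values)
  g <- layer@grid
  rows <- rep(seq_len(target@nRows), times = target@nCols)
  cols <- rep(seq_len(target@nCols), each = target@nRows)
  ctr <- cellCenters(target, rows, cols)
  # fractional (row, col) position of each target center in source cell units
  fc <- (ctr[, "lon"] - g@origin[1]) / g@cellSize + 0.5
  fr <- (g@origin[2] - ctr[, "lat"]) / g@cellSize + 0.5
  out <- rep(NA_real_, length(fr))
  if (method == "nearest") {
    ri <- floor(fr + 0.5); ci <- floor(fc + 0.5)
    ok <- ri >= 1 & ri <= g@nRows & ci >= 1 & ci <= g@nCols
    out[ok] <- layer@values[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(fr); c0 <- floor(fc)
    wr <- fr - r0; wc <- fc - c0
    # clamp so border cells extrapolate by edge replication
    r0c <- pmin(pmax(r0, 1L), g@nRows); r1c <- pmin(pmax(r0 + 1, 1L), g@nRows)
    c0c <- pmin(pmax(c0, 1L), g@nCols); c1c <- pmin(pmax(c0 + 1, 1L), g@nCols)
    inside <- fr >= 0.5 - 1e-9 & fr <= g@nRows + 0.5 + 1e-9 &
      fc >= 0.5 - 1e-9 & fc <= g@nCols + 0.5 + 1e-9
    v00 <- layer@values[cbind(r0c, c0c)]
    v01 <- layer@values[cbind(r0c, c1c)]
    v10 <- layer@values[cbind(r1c, c0c)]
    v11 <- layer@values[cbind(r1c, c1c)]
    val <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
      wr * ((1 - wc) * v10 + wc * v11)
    out[inside] <- val[inside]
  }
  matrix(out, target@nRows, target@nCols)
}

#' Harmonize a stack of layers onto a shared target grid
#'
#' Resamples every layer onto \code{target}. Categorical variables (integer
#' codes) default to nearest-neighbour, continuous ones to bilinear; the
#' union of all source nodata (plus the target's own mask and any
#' out-of-extent cells) becomes the shared nodata mask of the output grid.
#'
#' @param layers named list of \linkS4class{EnvLayer}
#' @param target the \linkS4class{RasterGrid} to harmonize onto
#' @param methodMap optional named character vector mapping variable names to
#'   "nearest" or "bilinear"; unnamed variables are defaulted by type
#' @return named list of \linkS4class{EnvLayer} sharing one grid
#' @export
harmonizeStack <- function(layers, target, methodMap = character()) {
  if (is.null(names(layers)))
    names(layers) <- vapply(layers, function(l) l@variableName, "")
  vals <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    nm <- names(layers)[i]
    method <- if (nm %in% names(methodMap)) methodMap[[nm]]
    else {
      v <- l@values[!is.na(l@values)]
      if (length(v) && all(v == round(v)) && length(unique(v)) <= 32)
        "nearest" else "bilinear"
    }
    m <- resampleLayer(l, target, method)
    if (all(is.na(m)))
      stop("layer '", nm, "' has no overlap with the target extent")
    vals[[i]] <- m
  }
  mask <- Reduce(`|`, lapply(vals, is.na)) | target@nodataMask
  outGrid <- RasterGrid(target@nRows, target@nCols, target@origin,
                        target@cellSize, target@crsId, nodataMask = mask)
  out <- vector("list", length(layers))
  names(out) <- names(layers)
  for (i in seq_along(layers))
    out[[i]] <- EnvLayer(outGrid, vals[[i]],
                         variableName = layers[[i]]@variableName,
                         units = layers[[i]]@units)
  out
}

#' Aggregate monthly layers over a period
#'
#' Per-cell mean of all (year, month) layers whose month lies in
#' \code{months}. For the overwintering set \code{c(11, 12, 1, 2)}, January
#' and February layers are attributed to the season that started the
#' preceding November (affects only season bookkeeping, not the multi-year
#' mean itself).
#'
#' @param monthly list of \code{list(year =, month =, layer = EnvLayer)}
#' @param months integer set of month numbers to include
#' @param statistic currently only "mean"
#' @return an \linkS4class{EnvLayer} of the period mean
#' @export
aggregatePeriod <- function(monthly, months, statistic = "mean") {
  statistic <- match.arg(statistic, "mean")
  sel <- Filter(function(e) e$month %in% months, monthly)
  if (length(sel) == 0) stop("no layers match the requested months")
  acc <- sel[[1]]$layer@values * 0
  for (e in sel) acc <- acc + e$layer@values
  EnvLayer(sel[[1]]$layer@grid, acc / length(sel),
           variableName = paste0(sel[[1]]$layer@variableName, "_period"),
           units = sel[[1]]$layer@units)
}

#' Euclidean distance to the nearest feature
#'
#' Planar distance (km, after local projection of degrees to km) from each
#' cell center to the nearest vertex of any feature geometry. Geometries
#' should therefore be vertexed densely relative to the cell size.
#'
#' @param features a \linkS4class{FeatureSet}
#' @param grid a \linkS4class{RasterGrid}
#' @return an \linkS4class{EnvLayer} named \code{dist_<featureType>} (km)
#' @export
distanceToFeatures <- function(features, grid) {
  if (length(features@geometries) == 0) stop("empty feature set")
  V <- do.call(rbind, features@geometries)
  vkm <- projectLocalKm(grid, V[, 1], V[, 2])
  rows <- rep(seq_len(grid@nRows), times = grid@nCols)
  cols <- rep(seq_len(grid@nCols), each = grid@nRows)
  ctr <- cellCenters(grid, rows, cols)
  ckm <- projectLocalKm(grid, ctr[, "lon"], ctr[, "lat"])
  best <- rep(Inf, nrow(ckm))
  # chunk over vertices to bound the distance-matrix memory
  step <- max(1L, floor(2e6 / nrow(ckm)))
  for (s in seq(1, nrow(vkm), by = step)) {
    j <- s:min(s + step - 1, nrow(vkm))
    d2 <- outer(ckm[, 1], vkm[j, 1], `-`)^2 +
      outer(ckm[, 2], vkm[j, 2], `-`)^2
    best <- pmin(best, apply(d2, 1, min))
  }
  EnvLayer(grid, matrix(sqrt(best), grid@nRows, grid@nCols),
           variableName = paste0("dist_", features@featureType),
           units = "km")
}

#' Slope and aspect from a DEM
#'
#' Horn 3x3 finite differences on elevations in metres; cell spacing is
#' converted from degrees to metres per row of latitude. Slope is returned
#' in degrees. Aspect is the compass direction of the uphill gradient,
#' discretized into nine categories coded 0 = flat (slope < 1 degree),
#' 1 = N, 2 = NE, 3 = E, 4 = SE, 5 = S, 6 = SW, 7 = W, 8 = NW. Border cells
#' are masked.
#'
#' @param dem an \linkS4class{EnvLayer} of elevations in metres
#' @return list with \code{slope} (\linkS4class{EnvLayer}, degrees) and
#'   \code{aspect} (\linkS4class{EnvLayer}, category codes)
#' @export
terrainDerivatives <- function(dem) {
  g <- dem@grid
  if (g@nRows < 3 || g@nCols < 3) stop("grid must be at least 3 x 3")
  z <- dem@values
  nr <- g@nRows; nc <- g@nCols
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  sh <- function(dr, dc) z[ri + dr, ci + dc]
  lat <- g@origin[2] - (ri - 0.5) * g@cellSize
  dx <- g@cellSize * KM_PER_DEG_LON_EQ * cos(lat * pi / 180) * 1000
  dy <- g@cellSize * KM_PER_DEG_LAT * 1000
  gx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
         (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * dx)
  gy <- ((sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
         (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))) / (8 * dy)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  theta <- (atan2(gx, gy) * 180 / pi) %% 360
  sector <- (floor((theta + 22.5) / 45) %% 8) + 1   # 1=N .. 8=NW clockwise
  aspect <- ifelse(slope < 1, 0, sector)
  borderMask <- matrix(TRUE, nr, nc)
  borderMask[ri, ci] <- FALSE
  mask <- borderMask | g@nodataMask
  sFull <- matrix(NA_real_, nr, nc); sFull[ri, ci] <- slope
  aFull <- matrix(NA_real_, nr, nc); aFull[ri, ci] <- aspect
  outGrid <- RasterGrid(nr, nc, g@origin, g@cellSize, g@crsId,
                        nodataMask = mask)
  list(slope = EnvLayer(outGrid, sFull, "slope", "deg"),
       aspect = EnvLayer(outGrid, aFull, "aspect", "code"))
}

#' Spatially thin occurrence points
#'
#' Removes exact duplicates, then greedily retains points in a seeded random
#' order: a point is kept iff its great-circle (haversine) distance to every
#' already-kept point is at least \code{minDistKm}. The retained set
#' therefore has no pair closer than the threshold, and re-thinning a
#' thinned set changes nothing.
#'
#' @param points an \linkS4class{OccurrenceSet}
#' @param minDistKm minimum separation in km (>= 0)
#' @param seed seed for the retention order
#' @return a thinned \linkS4class{OccurrenceSet}
#' @export
thinOccurrences <- function(points, minDistKm = 5, seed = 1L) {
  if (minDistKm < 0) stop("minDistKm must be >= 0")
  p <- unique(points@points)
  n <- nrow(p)
  if (n == 0)
    return(OccurrenceSet(speciesLabel = points@speciesLabel,
                         provenance = "thinned(empty)"))
  ord <- withSeed(seed, sample.int(n))
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        all(geosphere::distHaversine(p[keep, , drop = FALSE],
                                     p[i, ]) / 1000 >= minDistKm))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  new("OccurrenceSet", points = p[keep, , drop = FALSE],
      speciesLabel = points@speciesLabel,
      provenance = paste0("thinned(minKm=", minDistKm, ", seed=", seed, ")"))
}

#' Screen variables for collinearity
#'
#' Spearman rank correlations are computed over all shared valid cells for
#' every variable pair. While any pair exceeds \code{rhoThreshold} in
#' absolute value, the pair with the largest |rho| is resolved by dropping
#' the member with the lower tie-breaker score: the univariate AUC of the
#' layer's values at the occurrence cells against a seeded uniform
#' background sample. Constant layers (undefined rho) are flagged and
#' auto-retained with a warning.
#'
#' @param stack named list of \linkS4class{EnvLayer} on one grid
#' @param occurrences an \linkS4class{OccurrenceSet} used for tie-breaking
#' @param rhoThreshold |rho| above which a pair is collinear (default 0.75)
#' @param nBackground background sample size for the tie-breaker (default
#'   1000, capped at the number of valid cells)
#' @param seed seed for the background sample
#' @return a \linkS4class{ScreeningReport}
#' @export
screenVariables <- function(stack, occurrences, rhoThreshold = 0.75,
                            nBackground = 1000, seed = 1L) {
  if (length(stack) < 2) stop("need at least 2 variables to screen")
  if (length(occurrences) < 5) stop("need at least 5 occurrences")
  if (is.null(names(stack)))
    names(stack) <- vapply(stack, function(l) l@variableName, "")
  grid <- stack[[1]]@grid
  valid <- which(!grid@nodataMask)
  X <- vapply(stack, function(l) l@values[valid], numeric(length(valid)))
  notes <- character()
  constVar <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(constVar)) {
    notes <- c(notes, paste0("constant layer auto-retained: ",
                             paste(names(stack)[constVar], collapse = ", ")))
    warning("constant layer(s) auto-retained: ",
            paste(names(stack)[constVar], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  pairTab <- data.frame(varA = colnames(rho)[pairs[, 1]],
                        varB = colnames(rho)[pairs[, 2]],
                        rho = rho[pairs])
  # tie-breaker: occurrence-vs-background discrimination per variable
  occCell <- cellIndexOf(grid, occurrences@points[, "lon"],
                         occurrences@points[, "lat"])
  occCell <- occCell$cell[!is.na(occCell$cell) & !occCell$masked]
  bg <- withSeed(seed,
                 sample(valid, min(nBackground, length(valid))))
  tie <- vapply(seq_along(stack), function(j) {
    pv <- stack[[j]]@values[occCell]
    av <- stack[[j]]@values[bg]
    if (stats::sd(c(pv, av)) == 0) return(0.5)
    rocAuc(pv, av)
  }, 0)
  names(tie) <- names(stack)
  retained <- names(stack)
  dropped <- character()
  repeat {
    active <- setdiff(retained, names(stack)[constVar])
    if (length(active) < 2) break
    sub <- abs(rho[active, active, drop = FALSE])
    diag(sub) <- 0
    if (max(sub, na.rm = TRUE) <= rhoThreshold) break
    ij <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    loser <- if (tie[a] < tie[b]) a
    else if (tie[b] < tie[a]) b
    else active[max(ij)]      # equal tie-breakers: drop the later variable
    retained <- setdiff(retained, loser)
    dropped <- c(dropped, loser)
  }
  new("ScreeningReport", retained = retained, dropped = dropped,
      pairCorrelations = pairTab, tieBreakerScores = tie,
      threshold = rhoThreshold, notes = notes)
}
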