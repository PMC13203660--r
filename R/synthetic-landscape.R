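#' @include rng.R io.R
NULL

# Row/column Gaussian smoothing matrices with edge-normalised weights, so the
# convolution neither inflates nor deflates the field near the border.
gaussSmoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  K / rowSums(K)
}

#' Generate a spatially autocorrelated random field
#'
#' Smooths white Gaussian noise with a separable Gaussian kernel whose
#' standard deviation is \code{correlationLength} cells, then restandardises
#' so the sample mean and standard deviation over valid cells match the
#' targets exactly. \code{correlationLength = 0} yields independent cell
#' values; \code{sd = 0} yields a constant field. Bit-reproducible for a
#' fixed seed.
#'
#' @param grid a \linkS4class{RasterGrid}
#' @param correlationLength kernel sd in cells (>= 0)
#' @param mean,sd target sample moments (sd >= 0)
#' @param seed integer seed
#' @param variableName,units metadata for the returned layer
#' @return an \linkS4class{EnvLayer}
#' @examples
#' g <- RasterGrid(50, 50, origin = c(80, 45), cellSize = 0.01)
#' f <- genRandomField(g, correlationLength = 4, mean = 10, sd = 2, seed = 1)
#' @export
genRandomField <- function(grid, correlationLength = 5, mean = 0, sd = 1,
                           seed = 1L, variableName = "field", units = "") {
  if (correlationLength < 0) stop("correlationLength must be >= 0")
  if (sd < 0) stop("sd must be >= 0")
  vals <- withSeed(seed, {
    z <- matrix(stats::rnorm(grid@nRows * grid@nCols),
                grid@nRows, grid@nCols)
    if (correlationLength > 0) {
      Kr <- gaussSmoother(grid@nRows, correlationLength)
      Kc <- gaussSmoother(grid@nCols, correlationLength)
      z <- Kr %*% z %*% t(Kc)
    }
    z
  })
  valid <- !grid@nodataMask
  if (sd == 0) {
    vals[] <- mean
  } else {
    v <- vals[valid]
    s <- stats::sd(v)
    if (s == 0) vals[] <- mean
    else vals <- (vals - base::mean(v)) / s * sd + mean
  }
  EnvLayer(grid, vals, variableName = variableName, units = units)
}

#' Default synthetic environmental stack configuration
#'
#' Twelve variables emulating a typical arid-grassland predictor set:
#' development-period temperature and precipitation, overwintering land
#' surface temperature and precipitation, growing-season NDVI, land cover,
#' aspect, slope, soil clay and sand content, and distances to rivers and
#' lakes. Ranges span the full grading intervals of the shipped grading
#' tables; land cover and aspect are categorical. Two features emulate the
#' joint structure of a real arid region: every variable carries a
#' \code{sharedLoading} on a common latent gradient (an "oasis-to-desert"
#' axis), so layers co-vary the way climate, vegetation, soil and
#' hydrology do (aspect is independent of it); and most variables are
#' skewed so the bulk of the landscape sits in its least-suitable bands
#' (cold, dry, sparse vegetation, sandy, far from water) with favorable
#' conditions confined to a fringe, the zero-inflated suitability
#' structure typical of desert-basin geography. Land-cover class
#' proportions are desert-dominated for the same reason.
#'
#' @return a list of per-variable config entries with fields \code{name},
#'   \code{kind} ("continuous"/"categorical"), \code{min}/\code{max} or
#'   \code{codes} (+ \code{props}), \code{correlationLength},
#'   \code{sharedLoading}, \code{skew} and \code{units}
#' @export
defaultStackConfig <- function() {
  cont <- function(name, min, max, cl, load, skew, units)
    list(name = name, kind = "continuous", min = min, max = max,
         correlationLength = cl, sharedLoading = load, skew = skew,
         units = units)
  cat_ <- function(name, codes, cl, load, props = NULL)
    list(name = name, kind = "categorical", codes = codes, props = props,
         correlationLength = cl, sharedLoading = load, skew = 0,
         units = "code")
  list(
    cont("temp_dev",       0,   34, 12,  0.85,  1, "degC"),
    cont("precip_dev",     0,  900, 12,  0.80,  1, "mm"),
    cont("lst_winter",   -30,   10, 12,  0.85,  1, "degC"),
    cont("precip_winter",  0,  250, 12,  0.70,  1, "mm"),
    cont("ndvi_dev",       0,  0.8,  8,  0.75,  1, ""),
    cat_("land_cover", 1:7, 10, 0.6,
         props = c(0.15, 0.45, 0.05, 0.15, 0.08, 0.08, 0.04)),
    cat_("aspect", 0:8, 6, 0),
    cont("slope",          0,   20,  6, -0.60,  1, "deg"),
    cont("clay",           0,  550, 10,  0.60,  1, "g/kg"),
    cont("sand",           0,  700, 10, -0.60, -1, "g/kg"),
    cont("dist_river",     0,    3,  8, -0.70, -1, "km"),
    cont("dist_lake",      0,    4,  8, -0.70, -1, "km")
  )
}

#' Generate a synthetic environmental raster stack
#'
#' One autocorrelated layer per configuration entry. Each standardised
#' field is a mixture of a variable-specific component and a shared latent
#' gradient (weighted by the entry's \code{sharedLoading}), then continuous
#' layers are min-max rescaled so their extremes hit the configured range
#' exactly and categorical layers are quantile-binned into the configured
#' integer codes (producing contiguous patches).
#'
#' @param grid a \linkS4class{RasterGrid}
#' @param config list of per-variable entries, see
#'   \code{\link{defaultStackConfig}}
#' @param seed integer seed; the latent field and each variable draw from
#'   offset sub-seeds
#' @return named list of \linkS4class{EnvLayer}
#' @export
genEnvStack <- function(grid, config = defaultStackConfig(), seed = 1L) {
  nms <- vapply(config, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate variable names in stack config")
  loads <- vapply(config, function(cf)
    if (is.null(cf$sharedLoading)) 0 else cf$sharedLoading, 0)
  latent <- if (any(loads != 0))
    genRandomField(grid, correlationLength = 15, mean = 0, sd = 1,
                   seed = as.integer(seed) + 13L)@values
  layers <- vector("list", length(config))
  names(layers) <- nms
  for (i in seq_along(config)) {
    cf <- config[[i]]
    f <- genRandomField(grid, cf$correlationLength, mean = 0, sd = 1,
                        seed = as.integer(seed) + i * 97L,
                        variableName = cf$name, units = cf$units)
    v <- f@values
    if (loads[i] != 0)
      v <- loads[i] * latent + sqrt(1 - loads[i]^2) * v
    # monotone Beta-quantile skew: > 0 piles mass at the low end of the
    # range, < 0 at the high end; direction (loading semantics) preserved
    sk <- if (is.null(cf$skew)) 0 else cf$skew
    if (sk != 0) {
      v <- (v - base::mean(v)) / stats::sd(v)
      u <- stats::pnorm(v)
      a <- 0.5 / abs(sk); b <- 1 + abs(sk)
      v <- if (sk > 0) stats::qbeta(u, a, b) else stats::qbeta(u, b, a)
    }
    valid <- !grid@nodataMask
    if (cf$kind == "continuous") {
      if (cf$min > cf$max) stop("config range must satisfy min <= max")
      rng <- range(v[valid])
      if (cf$min == cf$max || rng[1] == rng[2]) {
        v[] <- cf$min
      } else {
        v <- (v - rng[1]) / (rng[2] - rng[1]) * (cf$max - cf$min) + cf$min
      }
    } else {
      k <- length(cf$codes)
      pr <- if (is.null(cf$props)) rep(1 / k, k) else cf$props / sum(cf$props)
      qs <- stats::quantile(v[valid], probs = cumsum(c(0, pr)))
      bin <- findInterval(v, qs, rightmost.closed = TRUE, all.inside = TRUE)
      v <- matrix(cf$codes[bin], grid@nRows, grid@nCols)
    }
    layers[[i]] <- EnvLayer(grid, v, variableName = cf$name,
                            units = cf$units)
  }
  layers
}

#' Build a known true-suitability surface from a graded stack
#'
#' Grades the stack, combines the 1-5 scores by weighted linear combination
#' with the supplied generating weights, and rescales the result to [0,1]
#' (score 1 everywhere maps to 0, score 5 everywhere to 1). The returned
#' ground truth is what the occurrence sampler and all recovery tests work
#' against.
#'
#' @param stack named list of \linkS4class{EnvLayer}
#' @param gradingTables named list of \linkS4class{GradingTable} covering
#'   every stack variable named in \code{weights}
#' @param weights a \linkS4class{WeightVector} over graded variables
#' @param seed seed recorded on the object (regeneration bookkeeping)
#' @return a \linkS4class{SyntheticTruth}
#' @export
genTrueSuitability <- function(stack, gradingTables, weights, seed = 1L) {
  wn <- variableNames(weights)
  missing <- setdiff(wn, names(gradingTables))
  if (length(missing))
    stop("no grading table for: ", paste(missing, collapse = ", "))
  missing2 <- setdiff(wn, names(stack))
  if (length(missing2))
    stop("no stack layer for: ", paste(missing2, collapse = ", "))
  scores <- gradeStack(stack[wn], gradingTables[wn])
  hsi <- wlcSurface(scores, weights)
  truth <- SuitabilitySurface(hsi@grid, (hsi@values - 1) / 4,
                              methodTag = "truth",
                              params = list(seed = as.integer(seed)))
  new("SyntheticTruth", envStack = stack, trueSurface = truth,
      generatingWeights = weights, seed = as.integer(seed))
}

#' Sample occurrence points from a known suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' \code{trueSurface^gamma}; each drawn cell contributes one point jittered
#' uniformly within the cell. An optional clustered accessibility field
#' multiplies the sampling probability, emulating survey-effort bias.
#'
#' @param truth a \linkS4class{SyntheticTruth} (or a
#'   \linkS4class{SuitabilitySurface} used directly as truth)
#' @param n number of points (1 <= n <= number of valid cells)
#' @param gamma selection exponent (> 0 concentrates points on high-truth
#'   cells; default 2)
#' @param biasClusters optional \code{list(centers = 2-col lon/lat matrix,
#'   sdKm = , base = )}; accessibility = base + sum of Gaussian bumps
#' @param seed integer seed
#' @return an \linkS4class{OccurrenceSet}
#' @export
sampleOccurrences <- function(truth, n, gamma = 2, biasClusters = NULL,
                              seed = 1L) {
  surf <- if (is(truth, "SyntheticTruth")) truth@trueSurface else truth
  grid <- surf@grid
  valid <- which(!grid@nodataMask)
  if (n < 1) stop("n must be >= 1")
  if (length(valid) < n) stop("not enough valid cells to draw ", n, " points")
  tv <- surf@values[valid]
  if (all(tv == 0)) stop("true surface is zero everywhere; cannot sample")
  prob <- pmax(tv, 0)^gamma
  rc <- arrayInd(valid, c(grid@nRows, grid@nCols))
  ctr <- cellCenters(grid, rows = rc[, 1], cols = rc[, 2])
  if (!is.null(biasClusters)) {
    acc <- rep(if (is.null(biasClusters$base)) 0.05 else biasClusters$base,
               length(valid))
    sdKm <- if (is.null(biasClusters$sdKm)) 10 else biasClusters$sdKm
    for (k in seq_len(nrow(biasClusters$centers))) {
      d <- geosphere::distHaversine(ctr, biasClusters$centers[k, ]) / 1000
      acc <- acc + exp(-d^2 / (2 * sdKm^2))
    }
    prob <- prob * acc
  }
  if (sum(prob) == 0) stop("sampling probabilities are zero everywhere")
  withSeed(seed, {
    picks <- sample(seq_along(valid), n, replace = FALSE, prob = prob)
    jit <- matrix(stats::runif(2 * n, -0.5, 0.5), ncol = 2)
    lon <- ctr[picks, "lon"] + jit[, 1] * grid@cellSize
    lat <- ctr[picks, "lat"] + jit[, 2] * grid@cellSize
    OccurrenceSet(lon, lat, speciesLabel = "synthetic",
                  provenance = paste0("simulated seed=", seed,
                                      " gamma=", gamma))
  })
}
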