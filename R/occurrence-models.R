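#' @include mca-surfaces.R
NULL

#' Sample pseudo-absence points
#'
#' Draws \code{ratio} pseudo-absences per presence, uniformly at random
#' without replacement from the eligible cells: valid (non-masked) cells
#' that contain no presence point. Points are placed at cell centers. One
#' such set is meant to be reused across all models of a comparison.
#'
#' @param grid a \linkS4class{RasterGrid}
#' @param presences an \linkS4class{OccurrenceSet}
#' @param ratio pseudo-absences per presence (default 3, i.e. 1:3)
#' @param seed integer seed
#' @return an \linkS4class{OccurrenceSet} with
#'   \code{ratio * length(presences)} points
#' @export
samplePseudoAbsences <- function(grid, presences, ratio = 3, seed = 1L) {
  pc <- cellIndexOf(grid, presences@points[, "lon"],
                    presences@points[, "lat"])
  presCells <- unique(pc$cell[!is.na(pc$cell)])
  eligible <- setdiff(which(!grid@nodataMask), presCells)
  nNeed <- ratio * length(presences)
  if (length(eligible) < nNeed)
    stop("only ", length(eligible), " eligible cells for ", nNeed,
         " pseudo-absences")
  picks <- withSeed(seed, sample(eligible, nNeed, replace = FALSE))
  rc <- arrayInd(picks, c(grid@nRows, grid@nCols))
  ctr <- cellCenters(grid, rows = rc[, 1], cols = rc[, 2])
  OccurrenceSet(ctr[, "lon"], ctr[, "lat"],
                speciesLabel = presences@speciesLabel,
                provenance = paste0("pseudo-absence seed=", seed,
                                    " ratio=1:", ratio))
}

#' Build a labelled presence / pseudo-absence sample
#'
#' Extracts per-variable predictor values at the cells containing each
#' point. Points on masked or out-of-extent cells are dropped (with a
#' message); pseudo-absences sharing a cell with any presence are an error,
#' since the sampler guarantees exclusion.
#'
#' @param stack named list of \linkS4class{EnvLayer} predictors
#' @param presences,absences \linkS4class{OccurrenceSet}s
#' @return data.frame with columns \code{cellIndex}, \code{label}
#'   (1 presence / 0 pseudo-absence) and one column per predictor
#' @export
buildLabeledSample <- function(stack, presences, absences) {
  if (is.null(names(stack)))
    names(stack) <- vapply(stack, function(l) l@variableName, "")
  grid <- stack[[1]]@grid
  extract <- function(occ, label) {
    idx <- cellIndexOf(grid, occ@points[, "lon"], occ@points[, "lat"])
    keep <- !is.na(idx$cell) & !idx$masked
    if (any(!keep))
      message(sum(!keep), " point(s) dropped (masked or outside extent)")
    cells <- idx$cell[keep]
    X <- vapply(stack, function(l) l@values[cells], numeric(length(cells)))
    if (length(cells) == 1L) X <- matrix(X, nrow = 1,
                                         dimnames = list(NULL, names(stack)))
    data.frame(cellIndex = cells, label = label, X, check.names = FALSE)
  }
  dp <- extract(presences, 1L)
  da <- extract(absences, 0L)
  if (any(da$cellIndex %in% dp$cellIndex))
    stop("pseudo-absence shares a cell with a presence")
  out <- rbind(dp, da)
  if (any(!is.finite(as.matrix(out[, -(1:2), drop = FALSE]))))
    stop("non-finite predictor values in the labelled sample")
  out
}

# ridge-stabilised IRLS for the logistic model; X includes the intercept
irlsLogistic <- function(X, y, l2 = 1e-4, maxIter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  D <- diag(c(0, rep(l2, p - 1)), p)   # intercept unpenalised
  devOld <- Inf
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- solve(XtW %*% X + D, XtW %*% z)[, 1]
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    trace <- c(trace, dev)
    if (abs(devOld - dev) < tol * (abs(dev) + 0.1))
      return(list(beta = beta, deviance = dev, iterations = it,
                  converged = TRUE, trace = trace))
    devOld <- dev
  }
  stop("IRLS did not converge after ", maxIter,
       " iterations; deviance trace: ",
       paste(format(utils::tail(trace, 5), digits = 6), collapse = ", "))
}

#' Fit the logistic baseline suitability model
#'
#' Maximum-likelihood logistic regression of presence versus
#' pseudo-absence on the predictor columns of the sample, fitted by
#' iteratively reweighted least squares with a small ridge penalty on the
#' non-intercept coefficients for numerical stability under
#' quasi-separation. When a predictor stack is supplied, the fitted
#' probability is evaluated on every valid cell to give a suitability
#' surface.
#'
#' @param sample a labelled sample from \code{\link{buildLabeledSample}}
#' @param stack optional named list of \linkS4class{EnvLayer} matching the
#'   sample's predictor columns, used to predict the surface
#' @param l2 ridge penalty (default 1e-4)
#' @param maxIter IRLS iteration cap
#' @return list with \code{coefficients} (named, intercept first),
#'   \code{surface} (a \linkS4class{SuitabilitySurface} or NULL),
#'   \code{deviance}, \code{iterations}
#' @export
fitLogisticBaseline <- function(sample, stack = NULL, l2 = 1e-4,
                                maxIter = 100L) {
  if (length(unique(sample$label)) < 2)
    stop("both labels must be present")
  vars <- setdiff(names(sample), c("cellIndex", "label"))
  X <- cbind(`(Intercept)` = 1, as.matrix(sample[, vars, drop = FALSE]))
  # standardise internally for IRLS conditioning; report on input scale
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  fit <- irlsLogistic(Xs, sample$label, l2 = l2, maxIter = maxIter)
  beta <- fit$beta / scl
  beta[1] <- fit$beta[1] - sum(fit$beta[-1] * ctr[-1] / scl[-1])
  names(beta) <- colnames(X)
  surface <- NULL
  if (!is.null(stack)) {
    if (is.null(names(stack)))
      names(stack) <- vapply(stack, function(l) l@variableName, "")
    grid <- stack[[1]]@grid
    valid <- which(!grid@nodataMask)
    Xg <- vapply(stack[vars], function(l) l@values[valid],
                 numeric(length(valid)))
    eta <- beta[1] + as.vector(Xg %*% beta[-1])
    m <- matrix(NA_real_, grid@nRows, grid@nCols)
    m[valid] <- 1 / (1 + exp(-eta))
    surface <- SuitabilitySurface(grid, m, methodTag = "glm",
                                  params = list(l2 = l2))
  }
  list(coefficients = beta, surface = surface,
       deviance = fit$deviance, iterations = fit$iterations)
}

#' Repeated stratified cross-validation of the logistic baseline
#'
#' Splits the sample into k stratified folds (the presence:absence ratio is
#' preserved within folds), fits the logistic baseline on each training
#' part and scores AUC and maximum TSS on the held-out part; the whole
#' design is repeated with fresh fold assignments. Deterministic for a
#' fixed seed.
#'
#' @param sample a labelled sample from \code{\link{buildLabeledSample}}
#' @param k folds (default 10); each class must have at least k members
#' @param repeats repetitions (default 10)
#' @param seed integer seed
#' @param l2 ridge penalty passed to the fitter
#' @return a \linkS4class{ModelEval} with k x repeats fold evaluations
#' @export
crossValidate <- function(sample, k = 10L, repeats = 10L, seed = 1L,
                          l2 = 1e-4) {
  y <- sample$label
  if (min(table(y)) < k)
    stop("each class needs at least k = ", k, " members")
  vars <- setdiff(names(sample), c("cellIndex", "label"))
  res <- withSeed(seed, {
    rows <- vector("list", k * repeats)
    r <- 1L
    for (rep_ in seq_len(repeats)) {
      fold <- integer(length(y))
      for (cls in unique(y)) {
        i <- which(y == cls)
        ids <- rep_len(seq_len(k), length(i))
        fold[i] <- ids[sample.int(length(ids))]
      }
      for (f in seq_len(k)) {
        test <- fold == f
        fit <- fitLogisticBaseline(sample[!test, , drop = FALSE], l2 = l2)
        Xt <- as.matrix(sample[test, vars, drop = FALSE])
        sc <- 1 / (1 + exp(-(fit$coefficients[1] +
                               as.vector(Xt %*% fit$coefficients[-1]))))
        tssRes <- maxTss(sc, y[test] == 1)
        rows[[r]] <- data.frame(rep = rep_, fold = f,
                                auc = rocAuc(sc[y[test] == 1],
                                             sc[y[test] == 0]),
                                tss = tssRes$tss)
        r <- r + 1L
      }
    }
    do.call(rbind, rows)
  })
  new("ModelEval",
      aucMean = mean(res$auc), aucSd = stats::sd(res$auc),
      tssMean = mean(res$tss), tssSd = stats::sd(res$tss),
      folds = res, k = as.integer(k), repeats = as.integer(repeats),
      seed = as.integer(seed))
}

memberMetrics <- function(m) {
  if (!is.null(m$eval) && is(m$eval, "ModelEval"))
    c(auc = m$eval@aucMean, tss = m$eval@tssMean)
  else c(auc = m$auc, tss = m$tss)
}

#' TSS-weighted ensemble of suitability surfaces
#'
#' Members whose TSS exceeds \code{tssMin} and AUC exceeds \code{aucMin}
#' (both strictly) are selected; each selected surface is linearly rescaled
#' to [0,1] and combined as a per-cell weighted mean with weights
#' proportional to TSS. Members may carry a \linkS4class{ModelEval} or
#' plain \code{auc}/\code{tss} numbers (e.g. for externally produced
#' surfaces).
#'
#' @param members list of \code{list(surface =, eval =)} or
#'   \code{list(surface =, auc =, tss =)}
#' @param tssMin,aucMin selection gates (defaults 0.7 and 0.9)
#' @return a \linkS4class{SuitabilitySurface} (method tag "ensemble";
#'   selected member tags and weights in \code{params})
#' @export
ensembleCombine <- function(members, tssMin = 0.7, aucMin = 0.9) {
  met <- t(vapply(members, memberMetrics, c(auc = 0, tss = 0)))
  pass <- met[, "tss"] > tssMin & met[, "auc"] > aucMin
  if (!any(pass))
    stop("no ensemble member passes TSS > ", tssMin, " and AUC > ", aucMin,
         "; member metrics: ",
         paste(sprintf("(auc=%.3f, tss=%.3f)", met[, "auc"], met[, "tss"]),
               collapse = " "))
  sel <- members[pass]
  wts <- met[pass, "tss"] / sum(met[pass, "tss"])
  grid <- sel[[1]]$surface@grid
  acc <- matrix(0, grid@nRows, grid@nCols)
  tags <- character(length(sel))
  for (i in seq_along(sel)) {
    s <- sel[[i]]$surface
    if (!sameGrid(s, grid)) stop("ensemble members must share one grid")
    v <- s@values
    rng <- range(v, na.rm = TRUE)
    v <- if (rng[1] == rng[2]) v * 0 + 0.5
    else (v - rng[1]) / (rng[2] - rng[1])
    acc <- acc + wts[i] * v
    tags[i] <- s@methodTag
  }
  SuitabilitySurface(grid, acc, methodTag = "ensemble",
                     params = list(members = tags, weights = unname(wts),
                                   tssMin = tssMin, aucMin = aucMin))
}
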