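#' @include mca-ahp.R
NULL

# valid-cell score matrix (cells x variables) aligned with a weight vector
scoreMatrix <- function(scores, w) {
  vn <- variableNames(w)
  if (!setequal(vn, scores@variableOrder) ||
      length(vn) != length(scores@variableOrder))
    stop("weight variables do not match the score stack")
  valid <- which(!scores@grid@nodataMask)
  n <- scores@grid@nRows * scores@grid@nCols
  X <- vapply(match(vn, scores@variableOrder), function(k)
    scores@scores[valid + (k - 1L) * n], numeric(length(valid)))
  list(X = X, valid = valid)
}

fillSurface <- function(grid, valid, vals, methodTag, params = list()) {
  m <- matrix(NA_real_, grid@nRows, grid@nCols)
  m[valid] <- vals
  SuitabilitySurface(grid, m, methodTag = methodTag, params = params)
}

#' Weighted linear combination suitability surface
#'
#' The habitat suitability index of each cell is the weighted sum of its
#' per-variable 1-5 suitability scores, HSI_i = sum_j w_j x_ij; larger
#' values mean more suitable. With weights from \code{\link{ahpWeights}}
#' this is the AHP suitability surface.
#'
#' @param scores a \linkS4class{ScoreStack}
#' @param w a \linkS4class{WeightVector} over the stack's variables
#' @return a \linkS4class{SuitabilitySurface} (method tag "ahp_wlc"),
#'   values in [1, 5]
#' @export
wlcSurface <- function(scores, w) {
  sm <- scoreMatrix(scores, w)
  vals <- as.vector(sm$X %*% criterionWeights(w))
  fillSurface(scores@grid, sm$valid, vals, "ahp_wlc")
}

#' TOPSIS suitability surface
#'
#' Scores are standardised to (0, 1] by dividing by 5 (preserving the
#' absolute 1-5 scale), weighted (v_ij = w_j r_ij), and each cell is scored
#' by its relative closeness C_i = D-/(D+ + D-) to the per-variable ideal
#' best (A+) and worst (A-) cells, with Euclidean distances in weighted
#' criterion space. If every cell is identical both distances vanish and
#' C_i is defined as 0.5 with a warning.
#'
#' @param scores a \linkS4class{ScoreStack}
#' @param w a \linkS4class{WeightVector}
#' @return a \linkS4class{SuitabilitySurface} (method tag "topsis"),
#'   values in [0, 1]
#' @export
topsisSurface <- function(scores, w) {
  sm <- scoreMatrix(scores, w)
  if (nrow(sm$X) == 0) stop("no valid cells")
  V <- sweep(sm$X / 5, 2, criterionWeights(w), `*`)
  aPlus <- apply(V, 2, max)
  aMinus <- apply(V, 2, min)
  dPlus <- sqrt(rowSums(sweep(V, 2, aPlus)^2))
  dMinus <- sqrt(rowSums(sweep(V, 2, aMinus)^2))
  tot <- dPlus + dMinus
  C <- ifelse(tot == 0, 0.5, dMinus / tot)
  if (any(tot == 0))
    warning("degenerate TOPSIS: identical cells scored 0.5")
  fillSurface(scores@grid, sm$valid, C, "topsis")
}

clampAlpha <- function(alpha) {
  if (alpha < 1e-4 || alpha > 1e4) {
    warning("alpha clamped to [1e-4, 1e4]")
    alpha <- min(max(alpha, 1e-4), 1e4)
  }
  alpha
}

#' Order weights for ordered weighted averaging
#'
#' Given the criterion weights reordered by a cell's descending score order
#' (r_k), the order weight of rank j is
#' u_j = (sum_{k<=j} r_k)^alpha - (sum_{k<=j-1} r_k)^alpha, which sums to 1
#' exactly by telescoping. alpha < 1 shifts weight toward the highest
#' ranked (optimistic) values, alpha = 1 reproduces the criterion weights,
#' alpha > 1 shifts weight toward the lowest ranked (conservative) values.
#' alpha is clamped to [1e-4, 1e4] with a warning.
#'
#' @param w a \linkS4class{WeightVector}
#' @param rankedOrder permutation of the criteria by descending cell score
#' @param alpha decision parameter
#' @return numeric order weights u (same length as w, summing to 1)
#' @export
owaOrderWeights <- function(w, rankedOrder, alpha) {
  alpha <- clampAlpha(alpha)
  r <- criterionWeights(w)[rankedOrder]
  if (sum(r) <= 0) stop("zero-sum weights")
  r <- r / sum(r)
  cum <- cumsum(r)
  cum[length(cum)] <- 1   # guard the telescoping endpoint against roundoff
  unname(cum^alpha - c(0, cum[-length(cum)])^alpha)
}

#' Ordered weighted averaging suitability surface
#'
#' Per cell, the 1-5 scores are sorted in descending order (ties broken by
#' original variable index), the criterion weights are reordered
#' accordingly, order weights are formed with decision parameter alpha
#' (see \code{\link{owaOrderWeights}}) and the surface value is the order-
#' weighted sum. alpha = 1 reproduces the weighted linear combination
#' exactly; the extremes approach the per-cell maximum (alpha -> 0) and
#' minimum (alpha -> Inf) score.
#'
#' @param scores a \linkS4class{ScoreStack}
#' @param w a \linkS4class{WeightVector}
#' @param alpha decision parameter, clamped to [1e-4, 1e4]
#' @return a \linkS4class{SuitabilitySurface} (method tag "owa", alpha in
#'   \code{params})
#' @export
owaSurface <- function(scores, w, alpha) {
  alpha <- clampAlpha(alpha)
  sm <- scoreMatrix(scores, w)
  X <- sm$X
  nv <- ncol(X)
  wts <- criterionWeights(w)
  wts <- wts / sum(wts)
  # cells share few distinct score profiles; compute one value per profile
  key <- as.vector(X %*% 6^(seq_len(nv) - 1))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  Xu <- X[uk, , drop = FALSE]
  valsU <- vapply(seq_len(nrow(Xu)), function(i) {
    z <- Xu[i, ]
    ord <- order(-z, seq_len(nv))
    r <- wts[ord]
    cum <- cumsum(r)
    cum[nv] <- 1
    u <- cum^alpha - c(0, cum[-nv])^alpha
    sum(u * z[ord])
  }, 0)
  fillSurface(scores@grid, sm$valid, valsU[idx], "owa",
              params = list(alpha = alpha))
}
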