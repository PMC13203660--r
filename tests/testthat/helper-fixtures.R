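# shared fixtures and independent oracles, all built in code

smallGrid <- function(nr = 10, nc = 10, cellSize = 0.01, mask = NULL)
  RasterGrid(nr, nc, origin = c(80, 45), cellSize = cellSize,
             nodataMask = mask)

# a tiny ScoreStack from an explicit cells x variables integer matrix
# (cells fill the grid column-major)
toyScoreStack <- function(scoreMat, vars = colnames(scoreMat)) {
  n <- nrow(scoreMat)
  g <- RasterGrid(n, 1, origin = c(80, 45), cellSize = 0.01)
  arr <- array(NA_integer_, c(n, 1, ncol(scoreMat)))
  for (j in seq_len(ncol(scoreMat))) arr[, 1, j] <- scoreMat[, j]
  ScoreStack(g, arr, vars)
}

## independent oracles --------------------------------------------------

# AUC by exhaustive pair counting
aucPairOracle <- function(p, a) {
  gt <- sum(outer(p, a, ">"))
  eq <- sum(outer(p, a, "=="))
  (gt + 0.5 * eq) / (length(p) * length(a))
}

# maximum TSS by brute-force scan over a dense threshold set
tssBruteOracle <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(c(scores, scores - 1e-9, scores + 1e-9,
                        -Inf, Inf)))
  max(vapply(cand, function(t)
    mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1, 0))
}

# exact Jenks optimum by exhaustive enumeration of contiguous partitions;
# returns the minimal within-class sum of squared deviations
jenksBruteOracle <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (i in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, i], n)
    tot <- sum(vapply(seq_len(k), function(j)
      ssd(x[(cuts[j] + 1):cuts[j + 1]]), 0))
    best <- min(best, tot)
  }
  best
}

# within-class SSD of a sorted vector classified by upper-bound breaks
ssdOfBreaks <- function(x, breaks) {
  x <- sort(x)
  cls <- findInterval(x, breaks, left.open = TRUE) + 1
  sum(vapply(split(x, cls), function(v) sum((v - mean(v))^2), 0))
}

# AHP weights via dense eigendecomposition (independent of power iteration)
ahpEigenOracle <- function(M) {
  e <- eigen(M)
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  list(weights = v, lambdaMax = Re(e$values[i]))
}

# literal per-formula TOPSIS on a cells x vars score matrix
topsisOracle <- function(S, w) {
  R <- S / 5
  V <- sweep(R, 2, w, `*`)
  Ap <- apply(V, 2, max); Am <- apply(V, 2, min)
  Dp <- sqrt(rowSums(sweep(V, 2, Ap)^2))
  Dm <- sqrt(rowSums(sweep(V, 2, Am)^2))
  Dm / (Dp + Dm)
}

# literal order-weight composition for one cell
owaOracle <- function(z, w, alpha) {
  ord <- order(-z, seq_along(z))
  r <- w[ord] / sum(w)
  cum <- cumsum(r)
  u <- cum^alpha - c(0, cum[-length(cum)])^alpha
  sum(u * z[ord])
}

# random reciprocal judgment matrix on the Saaty scale
randomJudgmentMatrix <- function(n, seed) {
  set.seed(seed)
  saaty <- c(1 / (9:2), 1:9)
  M <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- sample(saaty, 1)
    M[i, j] <- v; M[j, i] <- 1 / v
  }
  JudgmentMatrix(M, paste0("c", seq_len(n)))
}

# haversine minimum pairwise distance in km
minPairKm <- function(points) {
  n <- nrow(points)
  if (n < 2) return(Inf)
  d <- Inf
  for (i in seq_len(n - 1))
    d <- min(d, min(geosphere::distHaversine(
      points[i, , drop = FALSE],
      points[(i + 1):n, , drop = FALSE])) / 1000)
  d
}
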