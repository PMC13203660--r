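#' @include grading.R
NULL

#' Saaty random consistency index
#'
#' Published random-index values for reciprocal matrices of order 1..15
#' (Saaty's simulated averages), used as the denominator of the consistency
#' ratio.
#'
#' @param n matrix order (1..15)
#' @return the random index RI(n)
#' @export
saatyRandomIndex <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
          1.51, 1.48, 1.56, 1.57, 1.59)
  if (n < 1 || n > length(ri))
    stop("random index table covers orders 1..", length(ri))
  ri[n]
}

#' Derive criterion weights from a pairwise-comparison matrix
#'
#' Weights are the normalised principal right eigenvector, computed by
#' power iteration to a relative tolerance of 1e-12. The consistency index
#' is (lambda_max - n)/(n - 1) and the consistency ratio divides it by the
#' random index for order n; matrices of order <= 2 are perfectly
#' consistent by construction (CR = 0). A ratio below 0.1 is the accepted
#' coherence threshold.
#'
#' @param m a \linkS4class{JudgmentMatrix} (or a reciprocal matrix coerced
#'   to one, which enforces the reciprocal invariants)
#' @return an \linkS4class{AhpResult}
#' @examples
#' m <- JudgmentMatrix(matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3,
#'                     byrow = TRUE), c("a", "b", "c"))
#' ahpWeights(m)
#' @export
ahpWeights <- function(m) {
  if (!is(m, "JudgmentMatrix")) m <- JudgmentMatrix(m)
  M <- m@mat
  n <- nrow(M)
  w <- rep(1 / n, n)
  for (it in seq_len(100000L)) {
    v <- as.vector(M %*% w)
    v <- v / sum(v)
    if (max(abs(v - w) / pmax(abs(v), 1e-300)) < 1e-12) { w <- v; break }
    w <- v
  }
  lambda <- sum(M %*% w)
  ci <- if (n > 2) (lambda - n) / (n - 1) else 0
  cr <- if (n <= 2) 0 else ci / saatyRandomIndex(n)
  names(w) <- m@labels
  new("AhpResult", weights = new("WeightVector", weights = w / sum(w)),
      lambdaMax = lambda, consistencyIndex = ci, consistencyRatio = cr,
      acceptable = cr < 0.1)
}

#' Read / write a judgment matrix as CSV
#'
#' The CSV carries criterion labels in the first column and header; entries
#' are on the 1-9 reciprocal scale (fractions stored as decimals).
#'
#' @param path file path
#' @return \code{readJudgmentMatrix}: a \linkS4class{JudgmentMatrix}
#' @export
readJudgmentMatrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  JudgmentMatrix(as.matrix(df), labels = rownames(df))
}

#' @rdname readJudgmentMatrix
#' @param m a \linkS4class{JudgmentMatrix}
#' @export
writeJudgmentMatrix <- function(m, path) {
  df <- as.data.frame(m@mat)
  utils::write.csv(cbind(criterion = m@labels, df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged default 12-criterion judgment matrix
#'
#' A single-level pairwise-comparison matrix over the twelve default
#' environmental variables, built from an ecologically ordered importance
#' ranking (thermal and vegetation conditions first, substrate and terrain
#' modifiers last) with entries on the Saaty 1-9 scale. Its consistency
#' ratio is below 0.1.
#'
#' @return a \linkS4class{JudgmentMatrix}
#' @export
defaultJudgmentMatrix <- function() {
  readJudgmentMatrix(system.file("extdata", "judgment_matrix.csv",
                                 package = "habicomp", mustWork = TRUE))
}
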