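presFixture <- function(g, n = 10, seed = 1) {
  vals <- matrix(0.5, g@nRows, g@nCols)
  sampleOccurrences(SuitabilitySurface(g, vals, "truth"), n,
                    gamma = 1, seed = seed)
}

test_that("pseudo-absence sampling respects ratio and exclusion", {
  g <- smallGrid(20, 20)
  pres <- presFixture(g, 10)
  pa <- samplePseudoAbsences(g, pres, ratio = 3, seed = 4)
  expect_equal(length(pa), 30)
  pc <- cellIndexOf(g, occurrenceCoords(pres)[, 1],
                    occurrenceCoords(pres)[, 2])$cell
  ac <- cellIndexOf(g, occurrenceCoords(pa)[, 1],
                    occurrenceCoords(pa)[, 2])$cell
  expect_length(intersect(pc, ac), 0)
})

test_that("a grid with exactly 3n eligible cells is drawn completely", {
  g <- RasterGrid(2, 20, origin = c(80, 45), cellSize = 0.01)
  pres <- presFixture(g, 10, seed = 2)
  pc <- unique(cellIndexOf(g, occurrenceCoords(pres)[, 1],
                           occurrenceCoords(pres)[, 2])$cell)
  eligible <- setdiff(seq_len(40), pc)
  pa <- samplePseudoAbsences(g, pres, ratio = 3, seed = 9)
  ac <- cellIndexOf(g, occurrenceCoords(pa)[, 1],
                    occurrenceCoords(pa)[, 2])$cell
  expect_setequal(ac, eligible)
  expect_error(samplePseudoAbsences(g, pres, ratio = 4), "eligible")
})

test_that("labelled samples extract predictors and enforce exclusion", {
  g <- smallGrid(15, 15)
  st <- list(x = genRandomField(g, 2, seed = 1, variableName = "x"),
             y = genRandomField(g, 2, seed = 2, variableName = "y"))
  pres <- presFixture(g, 8)
  pa <- samplePseudoAbsences(g, pres, 3, seed = 3)
  lab <- buildLabeledSample(st, pres, pa)
  expect_equal(nrow(lab), 32)
  expect_setequal(names(lab), c("cellIndex", "label", "x", "y"))
  i <- which(lab$label == 1)[1]
  expect_equal(lab$x[i], cellValues(st$x)[lab$cellIndex[i]])
  # a pseudo-absence in a presence cell must be refused
  clash <- OccurrenceSet(occurrenceCoords(pres)[1, 1],
                         occurrenceCoords(pres)[1, 2])
  expect_error(buildLabeledSample(st, pres, clash), "shares a cell")
})

test_that("the logistic baseline recovers known coefficients", {
  set.seed(77)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(`(Intercept)` = -0.5, x1 = 1.2, x2 = -0.8)
  eta <- beta[1] + X %*% beta[-1]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  samp <- data.frame(cellIndex = seq_len(n), label = y, X)
  fit <- fitLogisticBaseline(samp)
  expect_true(all(abs(fit$coefficients - beta) <= 0.1))
  # matches unpenalised ML (stats::glm) when the ridge vanishes
  fit0 <- fitLogisticBaseline(samp, l2 = 0)
  ref <- glm(y ~ X, family = binomial)
  expect_equal(unname(fit0$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("null and separable samples bracket the AUC range", {
  set.seed(5)
  n <- 400
  nullSamp <- data.frame(cellIndex = 1:n,
                         label = rep(0:1, each = n / 2),
                         x = rnorm(n))
  ev <- crossValidate(nullSamp, k = 5, repeats = 2, seed = 1)
  expect_lt(abs(ev@aucMean - 0.5), 0.12)
  sep <- data.frame(cellIndex = 1:n, label = rep(0:1, each = n / 2),
                    x = c(rnorm(n / 2, -4), rnorm(n / 2, 4)))
  evs <- crossValidate(sep, k = 5, repeats = 2, seed = 1)
  expect_equal(evs@aucMean, 1.0, tolerance = 1e-9)
  expect_equal(evs@tssMean, 1.0, tolerance = 1e-9)
})

test_that("cross-validation design and determinism contracts hold", {
  set.seed(13)
  n <- 200
  samp <- data.frame(cellIndex = 1:n, label = rep(0:1, c(150, 50)),
                     x = rnorm(n), z = rnorm(n))
  samp$x[samp$label == 1] <- samp$x[samp$label == 1] + 1.5
  ev <- crossValidate(samp, k = 10, repeats = 10, seed = 3)
  expect_equal(nrow(ev@folds), 100)
  ev2 <- crossValidate(samp, k = 10, repeats = 10, seed = 3)
  expect_identical(ev@folds, ev2@folds)
  expect_error(crossValidate(samp[c(1:5, 151:160), ], k = 10), "at least")
})

test_that("pseudo-absence exclusion holds across 100 seeds", {
  g <- smallGrid(12, 12)
  pres <- presFixture(g, 6)
  pc <- cellIndexOf(g, occurrenceCoords(pres)[, 1],
                    occurrenceCoords(pres)[, 2])$cell
  for (s in 1:100) {
    pa <- samplePseudoAbsences(g, pres, 3, seed = s)
    ac <- cellIndexOf(g, occurrenceCoords(pa)[, 1],
                      occurrenceCoords(pa)[, 2])$cell
    expect_length(intersect(pc, ac), 0)
  }
})

test_that("the ensemble gates, weights and bounds behave", {
  g <- smallGrid(8, 8)
  mk <- function(seed) SuitabilitySurface(
    g, matrix(runif(64), 8, 8), paste0("m", seed))
  set.seed(21)
  s1 <- mk(1); s2 <- mk(2); s3 <- mk(3)
  # single passing member: output is its rescaled surface
  one <- ensembleCombine(list(list(surface = s1, auc = 0.95, tss = 0.8)))
  v1 <- cellValues(s1)
  expect_equal(cellValues(one),
               (v1 - min(v1)) / (max(v1) - min(v1)), tolerance = 1e-12)
  # equal TSS members average per cell
  two <- ensembleCombine(list(list(surface = s1, auc = 0.95, tss = 0.8),
                              list(surface = s2, auc = 0.92, tss = 0.8)))
  r <- function(s) { v <- cellValues(s); (v - min(v)) / diff(range(v)) }
  expect_equal(cellValues(two), (r(s1) + r(s2)) / 2, tolerance = 1e-12)
  # a TSS 0.65 member is excluded and weights renormalise
  mix <- ensembleCombine(list(
    list(surface = s1, auc = 0.95, tss = 0.75),
    list(surface = s2, auc = 0.93, tss = 0.85),
    list(surface = s3, auc = 0.94, tss = 0.65)))
  w <- c(0.75, 0.85) / 1.6
  expect_equal(cellValues(mix), w[1] * r(s1) + w[2] * r(s2),
               tolerance = 1e-12)
  expect_equal(sum(unlist(mix@params$weights)), 1, tolerance = 1e-12)
  # bounded by pointwise min/max of rescaled members
  expect_true(all(cellValues(mix) >= pmin(r(s1), r(s2)) - 1e-12))
  expect_true(all(cellValues(mix) <= pmax(r(s1), r(s2)) + 1e-12))
  # nothing passes -> error listing metrics
  expect_error(ensembleCombine(list(
    list(surface = s1, auc = 0.95, tss = 0.7),
    list(surface = s2, auc = 0.9, tss = 0.9))), "auc=0.95")
})
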