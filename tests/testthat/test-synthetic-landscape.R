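test_that("random fields honour the zero-noise and determinism contracts", {
  g <- smallGrid(20, 20)
  flat <- genRandomField(g, correlationLength = 3, mean = 7, sd = 0, seed = 1)
  expect_true(all(cellValues(flat) == 7))

  a <- genRandomField(g, correlationLength = 4, mean = 2, sd = 3, seed = 9)
  b <- genRandomField(g, correlationLength = 4, mean = 2, sd = 3, seed = 9)
  expect_identical(cellValues(a), cellValues(b))
  c_ <- genRandomField(g, correlationLength = 4, mean = 2, sd = 3, seed = 10)
  expect_false(identical(cellValues(a), cellValues(c_)))

  v <- cellValues(a)[!nodataMask(a)]
  expect_equal(mean(v), 2, tolerance = 1e-12)
  expect_equal(sd(v), 3, tolerance = 1e-12)
})

test_that("correlationLength 0 yields uncorrelated cells (lag-1 check)", {
  g <- smallGrid(100, 100)
  f <- genRandomField(g, correlationLength = 0, seed = 3)
  v <- cellValues(f)
  lag1 <- cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))
  expect_lt(abs(lag1), 0.05)
  # and a positive correlation length induces strong lag-1 correlation
  fs <- genRandomField(g, correlationLength = 5, seed = 3)
  vs <- cellValues(fs)
  expect_gt(cor(as.vector(vs[-1, ]), as.vector(vs[-nrow(vs), ])), 0.5)
})

test_that("the default stack has 12 layers with exact ranges and kinds", {
  g <- smallGrid(40, 40)
  st <- genEnvStack(g, seed = 2)
  expect_length(st, 12)
  cfg <- defaultStackConfig()
  for (i in seq_along(cfg)) {
    cf <- cfg[[i]]
    v <- cellValues(st[[cf$name]])
    if (cf$kind == "continuous") {
      expect_equal(min(v), cf$min, tolerance = 1e-9)
      expect_equal(max(v), cf$max, tolerance = 1e-9)
    } else {
      expect_true(all(v %in% cf$codes))
    }
  }
  expect_error(genEnvStack(g, c(cfg, cfg[1])), "duplicate")
})

test_that("a degenerate range produces a constant layer", {
  g <- smallGrid(8, 8)
  cfg <- list(list(name = "x", kind = "continuous", min = 5, max = 5,
                   correlationLength = 2, units = ""))
  st <- genEnvStack(g, cfg, seed = 1)
  expect_true(all(cellValues(st$x) == 5))
})

test_that("true suitability is the rescaled weighted score combination", {
  # two-variable toy: hand-computed weighted scores
  g <- smallGrid(3, 1)
  a <- EnvLayer(g, matrix(c(18, 31, 2), 3, 1), "temp_dev", "degC")
  b <- EnvLayer(g, matrix(c(300, 50, 700), 3, 1), "precip_dev", "mm")
  tabs <- defaultGradingTables()
  w <- WeightVector(c(temp_dev = 0.6, precip_dev = 0.4))
  truth <- genTrueSuitability(list(temp_dev = a, precip_dev = b), tabs, w)
  # scores: temp (5, 1, 1); precip (5, 1, 2)
  hsi <- c(0.6 * 5 + 0.4 * 5, 0.6 * 1 + 0.4 * 1, 0.6 * 1 + 0.4 * 2)
  expect_equal(as.vector(cellValues(truth@trueSurface)), (hsi - 1) / 4)

  # all weight on one variable -> monotone transform of that score layer
  w1 <- WeightVector(c(temp_dev = 1, precip_dev = 0), normalize = FALSE)
  t1 <- genTrueSuitability(list(temp_dev = a, precip_dev = b), tabs, w1)
  expect_equal(as.vector(cellValues(t1@trueSurface)), (c(5, 1, 1) - 1) / 4)

  expect_error(genTrueSuitability(list(temp_dev = a), tabs,
                                  WeightVector(c(nope = 1))), "nope")
})

test_that("occurrence sampling follows the truth surface", {
  g <- smallGrid(40, 40)
  # two-level surface: high region = top 8 rows at 0.9, rest 0.1
  vals <- matrix(0.1, 40, 40); vals[1:8, ] <- 0.9
  surf <- SuitabilitySurface(g, vals, "truth")
  occ <- sampleOccurrences(surf, n = 480, gamma = 2, seed = 5)
  expect_equal(length(occ), 480)
  idx <- cellIndexOf(g, occurrenceCoords(occ)[, 1],
                     occurrenceCoords(occ)[, 2])
  expect_false(any(is.na(idx$cell)))
  # gamma large -> essentially all points in the high-level region
  occL <- sampleOccurrences(surf, n = 200, gamma = 50, seed = 5)
  rowsL <- cellIndexOf(g, occurrenceCoords(occL)[, 1],
                       occurrenceCoords(occL)[, 2])$row
  expect_gte(mean(rowsL <= 8), 0.99)
  # determinism
  occ2 <- sampleOccurrences(surf, n = 480, gamma = 2, seed = 5)
  expect_identical(occurrenceCoords(occ), occurrenceCoords(occ2))
  # errors
  expect_error(sampleOccurrences(
    SuitabilitySurface(g, matrix(0, 40, 40)), 10), "zero")
})

test_that("selection effect: occurrences sit on better cells than average", {
  g <- smallGrid(50, 50)
  st <- genEnvStack(g, seed = 4)
  tabs <- defaultGradingTables()
  w <- ahpWeights(defaultJudgmentMatrix())@weights
  truth <- suppressWarnings(genTrueSuitability(st, tabs, w, seed = 4))
  tv <- cellValues(truth@trueSurface)
  occ <- sampleOccurrences(truth, 1000, gamma = 2, seed = 6)
  at <- tv[cellIndexOf(g, occurrenceCoords(occ)[, 1],
                       occurrenceCoords(occ)[, 2])$cell]
  expect_gt(mean(at), mean(tv, na.rm = TRUE))
})

test_that("no occurrence lands on a masked cell", {
  mask <- matrix(FALSE, 30, 30); mask[, 1:10] <- TRUE
  g <- smallGrid(30, 30, mask = mask)
  vals <- matrix(0.5, 30, 30); vals[mask] <- NA
  surf <- SuitabilitySurface(g, vals, "truth")
  for (s in 1:5) {
    occ <- sampleOccurrences(surf, 100, gamma = 2, seed = s)
    idx <- cellIndexOf(g, occurrenceCoords(occ)[, 1],
                       occurrenceCoords(occ)[, 2])
    expect_false(any(idx$masked))
  }
})

test_that("clustered sampling bias concentrates points near cluster centers", {
  g <- smallGrid(40, 40)
  surf <- SuitabilitySurface(g, matrix(0.5, 40, 40), "truth")
  ctr <- cellCenters(g, 20, 20)
  bias <- list(centers = ctr, sdKm = 3, base = 0.01)
  occB <- sampleOccurrences(surf, 200, gamma = 2, biasClusters = bias,
                            seed = 2)
  dB <- geosphere::distHaversine(occurrenceCoords(occB), ctr[1, ]) / 1000
  occU <- sampleOccurrences(surf, 200, gamma = 2, seed = 2)
  dU <- geosphere::distHaversine(occurrenceCoords(occU), ctr[1, ]) / 1000
  expect_lt(median(dB), median(dU))
})
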