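test_that("harmonization is the identity on the target grid", {
  g <- smallGrid(12, 12)
  l <- genRandomField(g, 2, seed = 1, variableName = "x")
  out <- harmonizeStack(list(x = l), g)
  expect_equal(cellValues(out$x), cellValues(l))
  # constant layer stays constant under either method
  cl <- EnvLayer(smallGrid(24, 24, cellSize = 0.005), 3, "c")
  outc <- harmonizeStack(list(c = cl), g, methodMap = c(c = "bilinear"))
  expect_true(all(cellValues(outc$c) == 3))
})

test_that("bilinear 2x downsampling of a checkerboard averages 4 cells", {
  fine <- RasterGrid(8, 8, origin = c(80, 45), cellSize = 0.01)
  coarse <- RasterGrid(4, 4, origin = c(80, 45), cellSize = 0.02)
  cb <- EnvLayer(fine, outer(1:8, 1:8, function(i, j) (i + j) %% 2), "cb")
  out <- harmonizeStack(list(cb = cb), coarse,
                        methodMap = c(cb = "bilinear"))
  # each coarse center sits at the shared corner of 4 fine cells
  oracle <- matrix(NA_real_, 4, 4)
  v <- cellValues(cb)
  for (r in 1:4) for (c_ in 1:4)
    oracle[r, c_] <- mean(v[(2 * r - 1):(2 * r), (2 * c_ - 1):(2 * c_)])
  expect_equal(cellValues(out$cb), oracle, tolerance = 1e-12)
})

test_that("categorical layers default to nearest-neighbour resampling", {
  fine <- RasterGrid(8, 8, origin = c(80, 45), cellSize = 0.01)
  coarse <- RasterGrid(4, 4, origin = c(80, 45), cellSize = 0.02)
  codes <- EnvLayer(fine, matrix(rep(c(2, 7), each = 32), 8, 8), "lc")
  out <- harmonizeStack(list(lc = codes), coarse)
  expect_true(all(cellValues(out$lc) %in% c(2, 7)))
})

test_that("no overlap between layer and target is an error", {
  far <- RasterGrid(4, 4, origin = c(10, 10), cellSize = 0.01)
  g <- smallGrid(4, 4)
  l <- EnvLayer(far, 1, "x")
  expect_error(harmonizeStack(list(x = l), g), "overlap")
})

test_that("period aggregation equals the brute-force mean", {
  g <- smallGrid(6, 6)
  single <- list(list(year = 2001, month = 5,
                      layer = genRandomField(g, 2, seed = 1)))
  expect_equal(cellValues(aggregatePeriod(single, 5:8)),
               cellValues(single[[1]]$layer))

  two <- c(single, list(list(year = 2001, month = 7,
                             layer = genRandomField(g, 2, seed = 2))))
  expect_equal(cellValues(aggregatePeriod(two, 5:8)),
               (cellValues(two[[1]]$layer) + cellValues(two[[2]]$layer)) / 2)

  # 22 years x May-August against naive accumulation
  monthly <- list()
  k <- 0L
  for (y in 2001:2022) for (m in 5:8) {
    k <- k + 1L
    monthly[[k]] <- list(year = y, month = m,
                         layer = genRandomField(g, 1, seed = k))
  }
  # plus some out-of-period layers that must be ignored
  monthly[[k + 1]] <- list(year = 2001, month = 1,
                           layer = EnvLayer(g, 1e6, "x"))
  agg <- aggregatePeriod(monthly, 5:8)
  acc <- Reduce(`+`, lapply(monthly[1:88], function(e)
    cellValues(e$layer))) / 88
  expect_equal(cellValues(agg), acc, tolerance = 1e-12)
  expect_error(aggregatePeriod(single, 11), "no layers")
})

test_that("feature distance matches the exhaustive vertex oracle", {
  g <- smallGrid(15, 15)
  set.seed(7)
  verts <- cbind(runif(40, 80, 80.15), runif(40, 44.85, 45))
  fs <- FeatureSet(list(verts[1:25, ], verts[26:40, ]), "river")
  d <- distanceToFeatures(fs, g)
  ctr <- cellCenters(g)
  pc <- projectLocalKm(g, ctr[, 1], ctr[, 2])
  pv <- projectLocalKm(g, verts[, 1], verts[, 2])
  oracle <- vapply(seq_len(nrow(pc)), function(i)
    sqrt(min((pc[i, 1] - pv[, 1])^2 + (pc[i, 2] - pv[, 2])^2)), 0)
  expect_equal(as.vector(cellValues(d)), oracle, tolerance = 1e-9)
  expect_true(all(cellValues(d) >= 0))
})

test_that("a vertical line feature gives linearly increasing distance", {
  g <- smallGrid(5, 9)
  # feature runs along the centers of column 1
  ctr1 <- cellCenters(g, rows = 1:5, cols = rep(1, 5))
  fs <- FeatureSet(list(ctr1), "river")
  d <- cellValues(distanceToFeatures(fs, g))
  expect_equal(d[3, 1], 0, tolerance = 1e-12)
  # distance grows linearly with column offset (equal steps)
  steps <- diff(d[3, ])
  expect_equal(steps, rep(steps[1], 8), tolerance = 1e-9)
})

test_that("terrain derivatives recover analytic slope and aspect", {
  g <- RasterGrid(20, 20, origin = c(80, 45), cellSize = 0.01)
  lat <- 45 - (1:20 - 0.5) * 0.01
  # constant DEM: flat everywhere
  td0 <- terrainDerivatives(EnvLayer(g, 0, "dem", "m"))
  expect_true(all(cellValues(td0$slope)[2:19, 2:19] == 0))
  expect_true(all(cellValues(td0$aspect)[2:19, 2:19] == 0))

  # plane rising due north at ~2% grade: aspect category N (code 1)
  yKm <- outer(lat, rep(1, 20)) * 110.574
  demN <- EnvLayer(g, yKm * 1000 * 0.02, "dem", "m")
  tdN <- terrainDerivatives(demN)
  expect_true(all(cellValues(tdN$aspect)[2:19, 2:19] == 1))
  expect_true(all(cellValues(tdN$slope)[2:19, 2:19] > 1))

  # plane z = x tan(10 deg): slope 10 +/- 0.1 degrees on interior cells
  ctr <- cellCenters(g)
  xm <- matrix(projectLocalKm(g, ctr[, 1], ctr[, 2])[, 1] * 1000, 20, 20)
  dem10 <- EnvLayer(g, xm * tan(10 * pi / 180), "dem", "m")
  s10 <- cellValues(terrainDerivatives(dem10)$slope)[2:19, 2:19]
  expect_true(all(abs(s10 - 10) < 0.1))
  expect_error(terrainDerivatives(EnvLayer(smallGrid(2, 2), 1, "dem")),
               "3 x 3")
})

test_that("thinning obeys the minimum-distance rule", {
  # two points 3 km apart with a 5 km minimum: exactly one kept
  p2 <- OccurrenceSet(c(80, 80), c(45, 45 + 3 / 110.574))
  expect_equal(length(thinOccurrences(p2, 5, seed = 1)), 1)
  # all pairwise >= 5 km: everything kept (points ~11 km apart)
  pFar <- OccurrenceSet(c(80, 80.2, 80.4), c(45, 45, 45))
  expect_equal(length(thinOccurrences(pFar, 5, seed = 1)), 3)
  # duplicates removed first
  pDup <- OccurrenceSet(c(80, 80), c(45, 45))
  expect_equal(length(thinOccurrences(pDup, 5, seed = 1)), 1)
  # empty input -> empty output
  expect_equal(length(thinOccurrences(OccurrenceSet(), 5)), 0)
})

test_that("thinning is idempotent and respects the bound on clustered data", {
  set.seed(11)
  lon <- c(rnorm(60, 80, 0.01), rnorm(60, 80.5, 0.02))
  lat <- c(rnorm(60, 45, 0.01), rnorm(60, 45.2, 0.02))
  occ <- OccurrenceSet(lon, lat)
  th <- thinOccurrences(occ, 5, seed = 3)
  expect_gte(minPairKm(occurrenceCoords(th)), 5)
  th2 <- thinOccurrences(th, 5, seed = 99)
  expect_identical(occurrenceCoords(th2), occurrenceCoords(th))
})

test_that("screening reproduces manual pairwise elimination", {
  g <- smallGrid(30, 30)
  base <- genRandomField(g, 3, seed = 1)
  v <- cellValues(base)
  set.seed(2)
  # a and b are near-duplicates; c is independent
  stack <- list(
    a = EnvLayer(g, v, "a"),
    b = EnvLayer(g, v + matrix(rnorm(900, 0, 0.05), 30), "b"),
    c = genRandomField(g, 3, seed = 9, variableName = "c"))
  occ <- OccurrenceSet(runif(20, 80, 80.3), runif(20, 44.7, 45))
  rep_ <- screenVariables(stack, occ, rhoThreshold = 0.75, seed = 5)
  # exactly one of the duplicated pair dropped, c retained
  expect_length(rep_@dropped, 1)
  expect_true(rep_@dropped %in% c("a", "b"))
  expect_true("c" %in% rep_@retained)
  expect_setequal(c(rep_@retained, rep_@dropped), c("a", "b", "c"))
  # the member with the lower occurrence-vs-background AUC was dropped
  expect_equal(rep_@dropped,
               names(which.min(rep_@tieBreakerScores[c("a", "b")])))

  # all pairwise |rho| <= threshold: everything retained
  ind <- list(a = genRandomField(g, 0, seed = 1, variableName = "a"),
              b = genRandomField(g, 0, seed = 2, variableName = "b"),
              c = genRandomField(g, 0, seed = 3, variableName = "c"))
  repInd <- screenVariables(ind, occ, seed = 5)
  expect_length(repInd@dropped, 0)

  # constant layer flagged and auto-retained
  stack$k <- EnvLayer(g, 1, "k")
  expect_warning(repK <- screenVariables(stack, occ, seed = 5), "constant")
  expect_true("k" %in% repK@retained)
})
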