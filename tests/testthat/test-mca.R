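test_that("AHP handles symmetric and consistent matrices exactly", {
  r2 <- ahpWeights(JudgmentMatrix(matrix(1, 2, 2), c("a", "b")))
  expect_equal(unname(criterionWeights(r2)), c(0.5, 0.5))
  expect_equal(consistencyRatio(r2), 0)

  m <- JudgmentMatrix(matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3,
                             byrow = TRUE), c("a", "b", "c"))
  r3 <- ahpWeights(m)
  expect_equal(unname(criterionWeights(r3)), c(4, 2, 1) / 7,
               tolerance = 1e-10)
  expect_equal(r3@lambdaMax, 3, tolerance = 1e-10)
  expect_equal(consistencyRatio(r3), 0, tolerance = 1e-10)
  expect_true(r3@acceptable)
})

test_that("AHP agrees with dense eigendecomposition on random matrices", {
  for (n in c(3, 5, 7, 9)) for (s in 1:3) {
    jm <- randomJudgmentMatrix(n, seed = n * 100 + s)
    res <- ahpWeights(jm)
    oracle <- ahpEigenOracle(jm@mat)
    expect_equal(unname(criterionWeights(res)), oracle$weights,
                 tolerance = 1e-9)
    expect_equal(res@lambdaMax, oracle$lambdaMax, tolerance = 1e-9)
    expect_true(all(criterionWeights(res) > 0))
    expect_equal(res@consistencyIndex, (oracle$lambdaMax - n) / (n - 1),
                 tolerance = 1e-9)
  }
})

test_that("non-reciprocal matrices and oversized orders are rejected", {
  bad <- matrix(c(1, 2, 3, 1, 1, 2, 1/3, 1/2, 1), 3, byrow = TRUE)
  expect_error(ahpWeights(bad), "reciprocal")
  expect_error(saatyRandomIndex(16), "orders")
})

test_that("weighted linear combination matches per-cell arithmetic", {
  S <- cbind(a = c(4L, 3L, 1L), b = c(2L, 5L, 1L))
  st <- toyScoreStack(S)
  w <- WeightVector(c(a = 0.5, b = 0.5))
  expect_equal(as.vector(cellValues(wlcSurface(st, w))), c(3, 4, 1))
  # uniform scores give HSI = s for any valid weights
  w2 <- WeightVector(c(a = 0.73, b = 0.27), normalize = FALSE)
  su <- toyScoreStack(cbind(a = c(2L, 2L), b = c(2L, 2L)))
  expect_equal(as.vector(cellValues(wlcSurface(su, w2))), c(2, 2))
  expect_error(wlcSurface(st, WeightVector(c(x = 1))), "match")
})

test_that("TOPSIS endpoints, degenerate case and literal formula hold", {
  one <- toyScoreStack(cbind(a = c(5L, 1L)))
  C <- as.vector(cellValues(topsisSurface(one, WeightVector(c(a = 1)))))
  expect_equal(C, c(1, 0))

  same <- toyScoreStack(cbind(a = c(3L, 3L), b = c(2L, 2L)))
  expect_warning(
    Cd <- cellValues(topsisSurface(same, WeightVector(c(a = .5, b = .5)))),
    "degenerate")
  expect_true(all(Cd == 0.5))

  S <- cbind(a = c(5L, 2L, 1L), b = c(1L, 4L, 2L))
  w <- c(a = 0.7, b = 0.3)
  Cs <- as.vector(cellValues(topsisSurface(toyScoreStack(S),
                                           WeightVector(w))))
  expect_equal(Cs, topsisOracle(S, w), tolerance = 1e-12)
  expect_true(all(Cs >= 0 & Cs <= 1))
})

test_that("order weights telescope and reproduce the printed example", {
  w <- WeightVector(c(a = 0.6, b = 0.4))
  expect_equal(owaOrderWeights(w, 1:2, alpha = 1), c(0.6, 0.4),
               tolerance = 1e-12)
  expect_equal(owaOrderWeights(w, 1:2, alpha = 2), c(0.36, 0.64),
               tolerance = 1e-12)
  u <- owaOrderWeights(w, 2:1, alpha = 0.37)
  expect_equal(sum(u), 1, tolerance = 1e-12)
  expect_warning(uc <- owaOrderWeights(w, 1:2, alpha = 1e5), "clamped")
  expect_equal(sum(uc), 1, tolerance = 1e-12)
})

test_that("OWA matches the literal composition and its limits", {
  S <- cbind(a = c(4L, 1L, 3L), b = c(2L, 5L, 3L), c = c(5L, 2L, 1L))
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  wv <- WeightVector(w)
  st <- toyScoreStack(S)
  for (alpha in c(0.25, 1, 2, 7)) {
    got <- as.vector(cellValues(owaSurface(st, wv, alpha)))
    want <- apply(S, 1, owaOracle, w = w, alpha = alpha)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # optimistic / conservative limits
  expect_equal(as.vector(cellValues(owaSurface(st, wv, 1e-4))),
               apply(S, 1, max), tolerance = 1e-3)
  expect_equal(as.vector(cellValues(owaSurface(st, wv, 1e4))),
               apply(S, 1, min), tolerance = 1e-3)
  # alpha = 1 reproduces the weighted linear combination
  expect_equal(cellValues(owaSurface(st, wv, 1)),
               cellValues(wlcSurface(st, wv)), tolerance = 1e-12)
})

test_that("OWA is a convex combination, non-increasing in alpha", {
  set.seed(31)
  S <- matrix(sample(1:5, 60, replace = TRUE), 12, 5,
              dimnames = list(NULL, letters[1:5]))
  st <- toyScoreStack(S)
  wv <- WeightVector(setNames(runif(5, 0.1, 1), letters[1:5]))
  alphas <- c(1e-4, 0.1, 0.5, 1, 2, 5, 20, 1e4)
  prev <- NULL
  for (alpha in alphas) {
    v <- as.vector(cellValues(owaSurface(st, wv, alpha)))
    expect_true(all(v >= apply(S, 1, min) - 1e-9))
    expect_true(all(v <= apply(S, 1, max) + 1e-9))
    if (!is.null(prev)) expect_true(all(v <= prev + 1e-9))
    prev <- v
  }
})

test_that("the packaged judgment matrix is reciprocal and labelled", {
  jm <- defaultJudgmentMatrix()
  expect_length(variableNames(jm), 12)
  expect_setequal(variableNames(jm),
                  vapply(defaultStackConfig(), `[[`, "", "name"))
  expect_true(validObject(jm))
})
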