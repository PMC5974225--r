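test_that("window and gap spine counts follow the interval definitions", {
  lay <- uniformLayout(10)                 # unit spacing, positions 0..9
  ## window of length 3 from any interior spine holds 4 spines
  expect_equal(windowSpineCount(lay, 3, 3, 2), 4L)
  ## window shorter than the spacing holds only the start spine: below m
  expect_equal(windowSpineCount(SpineLayout(c(0, 5, 10), c(TRUE, TRUE, FALSE)),
                                1, 2, 2), 0L)
  ## flush at the segment start: trailing gap truncated to [0, d_i)
  gh <- gapSpineCounts(lay, 2, 3, 5)
  expect_equal(gh[["g"]], 1L)
  ## empty neighbourhoods
  lay2 <- SpineLayout(c(0, 10, 20), c(TRUE, FALSE, TRUE))
  expect_equal(unname(gapSpineCounts(lay2, 2, 3, 2)), c(0L, 0L))
  ## random layout against a direct interval recount
  set.seed(42)
  p <- sort(runif(12, 0, 30))
  layr <- SpineLayout(p, rep(FALSE, 12))
  for (i in c(1, 5, 12)) {
    gh <- gapSpineCounts(layr, i, 4, 3)
    expect_equal(gh[["g"]], sum(p >= p[i] - 3 & p < p[i] - 1e-12))
    hi <- min(p[12], p[i] + 4 + 3)
    expect_equal(gh[["h"]], sum(p > p[i] + 4 + 1e-12 & p <= hi + 1e-9))
  }
})

test_that("uniform spacing recovers the order-based treatment exactly", {
  lay <- worked_layout()
  for (M in 2:9) for (m in 2:min(5, M)) {
    a <- likelihoodValue(specificEnsembleLikelihoodDistance(lay, M - 1, m, 2))
    b <- likelihoodValue(specificEnsembleLikelihood(30, 5, M, m, 2))
    expect_equal(a, b, tolerance = 1e-12, info = sprintf("M=%d m=%d", M, m))
    a <- likelihoodValue(ensembleProbabilityDistance(lay, M - 1, m, 2))
    b <- likelihoodValue(ensembleProbability(30, 5, M, m, 2))
    expect_equal(a, b, tolerance = 1e-12, info = sprintf("p M=%d m=%d", M, m))
  }
})

test_that("degenerate all-labeled layouts give probability one or zero", {
  lay <- SpineLayout(c(0, 1.5, 2, 4), rep(TRUE, 4))
  expect_equal(likelihoodValue(ensembleProbabilityDistance(lay, 4, 4, 1)), 1)
  expect_equal(likelihoodValue(ensembleProbabilityDistance(lay, 2, 4, 1)), 0)
})

test_that("distance likelihoods equal the geometric enumeration oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    N <- sample(8:11, 1)
    p <- sort(runif(N, 0, 22))
    lab <- seq_len(N) %in% sample(N, 3)
    lay <- SpineLayout(p, lab)
    for (lM in c(4, 9)) for (m in 2:3) {
      o <- enumerateDistanceOracle(lay, lM, m, 3)
      cf <- likelihoodValue(ensembleProbabilityDistance(lay, lM, m, 3))
      expect_equal(cf, o$windowProbability, tolerance = 1e-12,
                   info = sprintf("seed=%d lM=%g m=%d", seed, lM, m))
    }
  }
})

test_that("likelihoods are invariant under translation of all positions", {
  set.seed(9)
  p <- sort(runif(10, 0, 25))
  lab <- seq_len(10) %in% sample(10, 4)
  for (shift in c(0, 3.7, 120)) {
    lay <- SpineLayout(p + shift, lab)
    v <- likelihoodValue(specificEnsembleLikelihoodDistance(lay, 6, 2, 4))
    if (shift == 0) ref <- v
    expect_equal(v, ref, tolerance = 1e-12)
  }
})

test_that("the published convention reproduces the worked-example cells", {
  lay <- worked_layout()
  expect_equal(likelihoodValue(specificEnsembleLikelihoodDistance(
    lay, 1, 2, 2, convention = "published")), 52923 / 142506,
    tolerance = 1e-12)
  expect_equal(likelihoodValue(specificEnsembleLikelihoodDistance(
    lay, 8, 5, 2, convention = "published")), 805 / 142506,
    tolerance = 1e-12)
  ## clipped distal windows and the closed leading-gap interval are what
  ## distinguish it from the exclusive convention
  expect_equal(likelihoodValue(specificEnsembleLikelihoodDistance(
    lay, 8, 5, 2, convention = "exclusive")), 770 / 142506,
    tolerance = 1e-12)
})

test_that("duplicate spine positions are counted individually", {
  lay <- SpineLayout(c(0, 1, 1, 2, 5), c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(windowSpineCount(lay, 1, 2, 2), 4L)
  o <- enumerateDistanceOracle(lay, 2, 2, 2)
  cf <- likelihoodValue(ensembleProbabilityDistance(lay, 2, 2, 2))
  expect_equal(cf, o$windowProbability, tolerance = 1e-12)
})
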