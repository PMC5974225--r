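test_that("total arrangements and argument checking", {
  expect_equal(cnt(totalArrangements(5, 5)), 1)
  expect_equal(cnt(totalArrangements(4, 2)), 6)
  expect_equal(cnt(totalArrangements(30, 5)), 142506)
  expect_error(totalArrangements(3, 5), "exceed")
  expect_error(totalArrangements(-1, 0), "integer")
})

test_that("packing-ratio threshold follows the distance criterion", {
  expect_equal(packingRatioThreshold(1, 1), 0.5)
  ## approaches 1/deltaCrit for large m
  expect_equal(packingRatioThreshold(1e6, 2), 0.5, tolerance = 1e-5)
  expect_error(packingRatioThreshold(0, 1))
})

test_that("internal arrangements fix both ensemble ends", {
  expect_equal(cnt(internalArrangements(2, 2)), 1)
  expect_equal(cnt(internalArrangements(6, 4)), 6)
  expect_equal(cnt(internalArrangements(9, 5)), 35)
  expect_error(internalArrangements(5, 1), "at least 2")
  ## strict counting equals brute-force enumeration of admissible subsets
  for (M in 4:8) for (m in 2:min(M, 4)) for (g in 1:3) {
    if (m == 2) {
      brute <- if (M - 1 <= g) 1 else 0
    } else {
      brute <- 0
      for (mid in utils::combn(M - 2, m - 2, simplify = FALSE)) {
        pos <- c(1, mid + 1, M)
        if (all(diff(pos) <= g)) brute <- brute + 1
      }
    }
    expect_equal(cnt(internalArrangements(M, m, g, strict = TRUE)), brute,
                 info = sprintf("M=%d m=%d g=%d", M, m, g))
  }
})

test_that("external arrangements: degenerate, reduction and closed form", {
  ## ensemble filling the segment: a single arrangement
  expect_equal(cnt(externalArrangements(10, 4, 10, 4, 2)), 1)
  expect_equal(cnt(externalArrangements(7, 2, 7, 2, 5)), 1)
  ## g = 0 degenerates to the naive placement count
  expect_equal(cnt(externalArrangements(12, 4, 5, 3, 0)),
               (12 - 5 + 1) * choose(12 - 5, 1))
  ## equals the two-term closed form whenever N - M >= 2 g
  for (N in c(12, 20)) for (M in 2:6) for (g in 1:3) for (nm in 0:3) {
    if (N - M < 2 * g) next
    expect_equal(cnt(SpineClusters:::external_count(N, nm + 2, M, 2, g)),
                 cnt(SpineClusters:::external_count_closed(N, nm + 2, M, 2, g)),
                 info = sprintf("N=%d M=%d g=%d nm=%d", N, M, g, nm))
  }
})

test_that("ensemble probability matches brute-force enumeration", {
  ## (N=12, n=3, M=4, m=3, g=1): qualifying outside-placements by enumeration
  o <- enumerateAssignmentsOracle(12, 3, 4, 3, 1)
  p <- ensembleProbability(12, 3, 4, 3, 1)
  expect_equal(likelihoodValue(p), o$windowProbability, tolerance = 1e-12)
  ## (N=10, n=2, M=2, m=2, g=1): adjacent labeled pair with clean gaps
  o <- enumerateAssignmentsOracle(10, 2, 2, 2, 1)
  p <- ensembleProbability(10, 2, 2, 2, 1)
  expect_equal(likelihoodValue(p), o$windowProbability, tolerance = 1e-12)
  expect_equal(as.numeric(denominatorCount(p)), choose(10, 2))
})

test_that("likelihoods are normalized and SEL is non-increasing in m", {
  for (N in c(10, 30)) for (g in 1:2) {
    n <- 5
    for (M in 2:min(N, 9)) {
      prev <- Inf
      for (m in 2:min(n, M)) {
        v <- likelihoodValue(specificEnsembleLikelihood(N, n, M, m, g))
        expect_gte(v, 0); expect_lte(v, 1)
        expect_lte(v, prev + 1e-12)
        prev <- v
      }
    }
  }
})

test_that("maximal ensemble size", {
  expect_equal(maxEnsembleSize(5, 2), 9L)
  expect_equal(maxEnsembleSize(2, 1), 2L)
  expect_equal(maxEnsembleSize(4, 3), 10L)
  expect_error(maxEnsembleSize(1, 2), "at least 2")
  ## constructive check: a maximally spread admissible ensemble exists and
  ## detection sees it as one ensemble
  n <- 4; g <- 3
  members <- 1 + (0:(n - 1)) * g
  types <- detect_types_ranks(members, g)
  expect_equal(nrow(types), 1L)
  expect_equal(unname(types[1, "M"]), maxEnsembleSize(n, g) - 0)
})

test_that("oracle refuses runaway enumeration and handles n = 0", {
  expect_error(enumerateAssignmentsOracle(40, 20, 4, 3, 1), "guard")
  o <- enumerateAssignmentsOracle(8, 0, 3, 2, 1)
  expect_equal(o$windows, 0)
  expect_equal(o$hitProbability, 0)
})
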