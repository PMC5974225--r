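test_that("tree totals accumulate over segments", {
  t1 <- small_tree(30, NA_integer_, labeled = c(1, 5, 9, 20, 27))
  expect_equal(unname(treeTotals(t1)), c(30, 5))
  t3 <- small_tree(c(10, 8, 12), c(NA, 1, 1), labeled = c(2, 3, 11, 19, 25, 30))
  expect_equal(unname(treeTotals(t3)), c(30, 6))
  ## independent accumulation
  expect_equal(treeTotals(t3)[["N"]],
               sum(vapply(treeSegments(t3), nSpines, 0)))
})

test_that("a one-segment tree reduces exactly to the segment treatment", {
  tr <- small_tree(12, NA_integer_, labeled = c(2, 3, 9))
  for (M in 2:6) for (m in 2:min(3, M)) for (g in 1:2) {
    expect_equal(likelihoodValue(treeEnsembleProbability(tr, M, m, g)),
                 likelihoodValue(ensembleProbability(12, 3, M, m, g)),
                 tolerance = 1e-12,
                 info = sprintf("M=%d m=%d g=%d", M, m, g))
  }
  expect_equal(
    likelihoodValue(treeSpecificEnsembleLikelihood(tr, 4, 2, 2)),
    likelihoodValue(specificEnsembleLikelihood(12, 3, 4, 2, 2)),
    tolerance = 1e-12)
})

test_that("open-end gap accounting matches hand enumeration", {
  ## root of 3 spines (2 labeled), two children of 2 spines; gap 1.
  ## An adjacent labeled pair within the root: flush placements leave the
  ## remaining assignments 2/21 (n_tot = 2) and 6/35 (n_tot = 3, with the
  ## open-end gap covering one spine on each child).
  tr2 <- small_tree(c(3, 2, 2), c(NA, 1, 1), labeled = c(1, 2))
  expect_equal(likelihoodValue(segmentEnsembleProbabilityTree(tr2, 1, 2, 2, 1)),
               2 / 21, tolerance = 1e-12)
  tr3 <- small_tree(c(3, 2, 2), c(NA, 1, 1), labeled = c(1, 2, 4))
  expect_equal(likelihoodValue(segmentEnsembleProbabilityTree(tr3, 1, 2, 2, 1)),
               6 / 35, tolerance = 1e-12)
})

test_that("branch-point placement counts match the composition formulas", {
  expect_equal(branchpointTwoSegmentPlacements(2), 3L)
  expect_equal(branchpointTwoSegmentPlacements(3), 6L)
  expect_equal(branchpointTwoSegmentPlacements(6), 15L)
  expect_equal(branchpointThreeSegmentPlacements(3), 1L)
  expect_equal(branchpointThreeSegmentPlacements(4), 3L)
  expect_equal(branchpointThreeSegmentPlacements(6), 10L)
  expect_error(branchpointTwoSegmentPlacements(1))
  expect_error(branchpointThreeSegmentPlacements(2))
  ## explicit enumeration: on long segments every split fits
  tr <- small_tree(c(12, 12, 12), c(NA, 1, 1))
  for (M in c(3, 6)) {
    pl <- SpineClusters:::branchpoint_placements(tr, 1, 2, 3, M, 1)
    deltas <- vapply(pl, `[[`, 0L, "delta")
    expect_equal(sum(deltas == 2), branchpointTwoSegmentPlacements(M))
    expect_equal(sum(deltas == 3), branchpointThreeSegmentPlacements(M))
  }
})

test_that("closed forms are recovered when all segments are long enough", {
  tr <- small_tree(c(20, 10, 10), c(NA, 1, 1), labeled = c(2, 5, 25))
  ## within-segment likelihood on the root (one closed, one open end),
  ## with the open-end term carrying the full doubled gap
  expect_equal(
    likelihoodValue(segmentEnsembleProbabilityTree(tr, 1, 3, 2, 2)),
    likelihoodValue(SpineClusters:::open_end_closed_form(40, 3, 20, 3, 2, 2,
                                                nClosedEnds = 1,
                                                nOpenEnds = 1)),
    tolerance = 1e-12)
  ## branch point: two- and three-segment terms
  for (M in 3:5) for (m in 2:3) {
    expect_equal(
      likelihoodValue(branchpointEnsembleProbability(tr, 1, M, m, 2)),
      likelihoodValue(SpineClusters:::branchpoint_closed_form(40, 3, M, m, 2)),
      tolerance = 1e-12, info = sprintf("M=%d m=%d", M, m))
  }
  ## m = 2: the three-segment term vanishes by the binomial convention
  pl <- SpineClusters:::branchpoint_placements(tr, 1, 2, 3, 4, 2)
  r3 <- SpineClusters:::placements_numerator(
    Filter(function(p) p$delta == 3, pl), 40, 3, 4, 2)
  expect_equal(cnt(r3$num), 0)
})

test_that("tree likelihoods equal full enumeration on small trees", {
  trees <- list(
    small_tree(c(4, 3, 3), c(NA, 1, 1), labeled = c(1, 3, 6)),
    small_tree(c(3, 2, 2, 2, 2), c(NA, 1, 1, 2, 2), labeled = c(2, 5, 8, 11)))
  for (tr in trees) {
    tt <- treeTotals(tr)
    for (g in 1:2) for (M in 2:5) for (m in 2:min(3, M)) {
      o <- enumerateTreeOracle(tr, M, m, g)
      cf <- likelihoodValue(treeEnsembleProbability(tr, M, m, g))
      expect_equal(cf, o$windowProbability, tolerance = 1e-12,
                   info = sprintf("Ntot=%d g=%d M=%d m=%d",
                                  tt[["N"]], g, M, m))
      ## assignments with several same-type windows explain any excess of
      ## the window count over the hit count
      if (o$multiples == 0) expect_equal(o$windows, o$hits)
      else expect_gt(o$windows, o$hits)
    }
  }
})

test_that("gap recursion through short segments; upper-bound mode flags", {
  ## middle segment of a chain shorter than the residual gap: in recursive
  ## mode the gap continues into the grandchildren, matching enumeration
  tr <- small_tree(c(3, 1, 1, 2, 2), c(NA, 1, 1, 2, 2), labeled = c(2, 3, 9))
  for (M in 2:3) for (m in 2:2) {
    o <- enumerateTreeOracle(tr, M, m, 2)
    cf <- treeEnsembleProbability(tr, M, m, 2, gapExtension = "recursive")
    expect_equal(likelihoodValue(cf), o$windowProbability, tolerance = 1e-12)
    ub <- treeEnsembleProbability(tr, M, m, 2, gapExtension = "upper_bound")
    expect_gte(likelihoodValue(ub), likelihoodValue(cf) - 1e-12)
  }
  ## the truncated computation is flagged as an upper bound
  ub <- segmentEnsembleProbabilityTree(tr, 1, 2, 2, 2,
                                       gapExtension = "upper_bound")
  expect_true(isUpperBound(ub))
})

test_that("degree-3 branchings are rejected", {
  segs <- lapply(1:4, function(i) uniformLayout(3, integer(0), paste0("s", i)))
  expect_error(DendriteTree(segs, c(NA, 1L, 1L, 1L)), "degree")
})
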