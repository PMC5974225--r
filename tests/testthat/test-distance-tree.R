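test_that("a closed-end-only segment reduces to the segment treatment", {
  set.seed(3)
  p <- sort(runif(9, 0, 18))
  lab <- seq_len(9) %in% sample(9, 3)
  lay <- SpineLayout(p, lab)
  tr <- DendriteTree(list(lay), NA_integer_)
  for (lM in c(5, 9)) for (m in 2:3) {
    expect_equal(
      likelihoodValue(segmentProbabilityDistanceTree(tr, 1, lM, m, 3)),
      likelihoodValue(ensembleProbabilityDistance(lay, lM, m, 3)),
      tolerance = 1e-12)
  }
  expect_equal(likelihoodValue(treeSELDistance(tr, 6, 2, 3)),
               likelihoodValue(specificEnsembleLikelihoodDistance(lay, 6, 2, 3)),
               tolerance = 1e-12)
})

test_that("distance tree likelihoods equal the enumeration oracle", {
  mk <- function(pos, labidx, len) SpineLayout(pos, seq_along(pos) %in% labidx,
                                               length = len)
  trees <- list(
    DendriteTree(list(mk(c(1, 3, 5), 2, 6), mk(c(1, 2.5, 4), 3, 5),
                      mk(c(2, 4), integer(0), 5)), c(NA, 1L, 1L)),
    DendriteTree(list(mk(c(0.5, 2, 4.5), 1, 5), mk(c(1, 2), 2, 3),
                      mk(c(0.5, 1.5, 3), c(1, 3), 4)), c(NA, 1L, 1L)))
  for (tr in trees) {
    for (lM in c(3, 5.5)) for (m in 2:3) {
      o <- enumerateDistanceTreeOracle(tr, lM, m, 2)
      cf <- likelihoodValue(treeProbabilityDistance(tr, lM, m, 2))
      expect_equal(cf, o$windowProbability, tolerance = 1e-12,
                   info = sprintf("lM=%g m=%d", lM, m))
    }
  }
})

test_that("open-end gap length spills over onto both adjacent segments", {
  ## root with a window ending 1 um before the branch point and gap 3:
  ## 2 um of the gap lie on each child
  mk <- function(pos, labidx, len) SpineLayout(pos, seq_along(pos) %in% labidx,
                                               length = len)
  tr <- DendriteTree(list(mk(c(0, 2, 5), c(1, 3), 6),
                          mk(c(1, 3), integer(0), 4),
                          mk(c(1.5, 3.5), integer(0), 4)), c(NA, 1L, 1L))
  zones <- SpineClusters:::distance_tree_segment_zones(tr, 1, 5, 3)
  z <- zones[[1]]                        # window [0, 5] over all root spines
  expect_equal(z$Mi, 3L)
  ## residual gap length beyond the root: 0 + 5 + 3 - 6 = 2 um on each child
  expect_setequal(z$gaps, c(4L, 6L))     # child spines at 1 and 1.5 um
})

test_that("a spine triple around a branch point forms a certain ensemble", {
  mk <- function(pos, labidx, len) SpineLayout(pos, seq_along(pos) %in% labidx,
                                               length = len)
  toy <- DendriteTree(list(mk(4, 1, 5), mk(0.5, 1, 4), mk(1, 1, 4)),
                      c(NA, 1L, 1L))
  ## extents 1 + 0.5 + 1 = 2.5 <= 3, all three arms labeled
  expect_equal(likelihoodValue(branchpointProbabilityDistance(toy, 1, 3, 3, 1.5)),
               1, tolerance = 1e-12)
  ## no triple fits a much shorter ensemble length
  expect_equal(likelihoodValue(branchpointProbabilityDistance(toy, 1, 0.5, 3, 1.5)),
               0)
  ## two-segment occupancy uses two labeled arm ends
  o <- enumerateDistanceTreeOracle(toy, 1.6, 2, 1)
  cf <- likelihoodValue(treeProbabilityDistance(toy, 1.6, 2, 1))
  expect_equal(cf, o$windowProbability, tolerance = 1e-12)
})
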