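test_that("analytic error model of the reshuffling estimate", {
  expect_equal(reshuffleVariance(0, 100), 0)
  expect_equal(reshuffleVariance(0.5, 100), 25)
  expect_equal(reshuffleVariance(0.01, 1e6), 9900)
  expect_error(reshuffleVariance(1.2, 10))
  expect_equal(reshuffleCV(1, 50), 0)
  expect_error(reshuffleCV(0, 50))
  ## quadrupling the rounds halves the CV
  expect_equal(reshuffleCV(0.03, 4e4), reshuffleCV(0.03, 1e4) / 2,
               tolerance = 1e-12)
  ## one million rounds reach the one-percent error for p = 0.01
  expect_lte(reshuffleCV(0.01, 1e6), 0.01)
})

test_that("reshuffling estimates converge to the exact likelihood", {
  lay <- worked_layout()
  ## impossible target: no hits
  r0 <- reshuffleLikelihoodEstimate(uniformLayout(10, 1:2),
                                    EnsembleType(3, 3, 1), 200, seed = 1)
  expect_equal(r0@estimate, 0)
  ## the (3, 3) type: SEL-event probability known exactly (no assignment
  ## can hold two disjoint such ensembles with n = 5)
  exact <- likelihoodValue(specificEnsembleLikelihood(30, 5, 3, 3, 2))
  r <- reshuffleLikelihoodEstimate(lay, EnsembleType(3, 3, 2), 2e4,
                                   seed = 11, exact = exact)
  expect_lt(abs(r@zScore), 4)
  expect_equal(r@estimate, r@hits / r@rounds)
  ## fixed seed reproduces the estimate exactly
  r2 <- reshuffleLikelihoodEstimate(lay, EnsembleType(3, 3, 2), 2e4,
                                    seed = 11, exact = exact)
  expect_identical(r@hits, r2@hits)
  ## distance targets run through the same machinery
  rd <- reshuffleLikelihoodEstimate(lay, DistanceEnsembleType(2, 3, 2), 2e4,
                                    seed = 11, exact = exact)
  expect_lt(abs(rd@zScore), 4)
})

test_that("tree reshuffling agrees with the tree-wide SEL event", {
  tr <- small_tree(c(6, 5, 5), c(NA, 1, 1), labeled = c(2, 3, 9, 14))
  ## window-count and hit probability coincide when multiples are absent
  o <- enumerateTreeOracle(tr, 3, 3, 1)
  r <- reshuffleLikelihoodEstimate(tr, EnsembleType(3, 3, 1), 2e4, seed = 5,
                                   exact = o$hitProbability)
  expect_lt(abs(r@zScore), 4)
})
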