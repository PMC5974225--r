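test_that("exact binomial coefficients are exact beyond double precision", {
  expect_equal(cnt(exactChoose(5, 5)), 1)
  expect_equal(cnt(exactChoose(4, 2)), 6)
  expect_equal(cnt(exactChoose(30, 5)), 142506)
  ## value with 30 digits, known exactly; base::choose() rounds here
  expect_identical(as.character(exactChoose(100, 50)),
                   "100891344545564193334812497256")
  ## vanishing convention
  expect_equal(cnt(exactChoose(3, 5)), 0)
  expect_equal(cnt(exactChoose(-2, 0)), 0)
  expect_equal(cnt(exactChoose(4, -1)), 0)
})

test_that("big-integer ratio stays accurate for huge operands", {
  a <- exactChoose(600, 300)
  b <- exactChoose(600, 299)
  ## C(n,k)/C(n,k-1) = (n-k+1)/k
  expect_equal(SpineClusters:::bi_ratio(a, b), 301 / 300, tolerance = 1e-12)
  expect_true(is.infinite(as.numeric(exactChoose(2500, 1250))))
})

test_that("addition, subtraction and string round-trips are exact", {
  a <- exactChoose(80, 40)
  b <- exactChoose(80, 39)
  s <- SpineClusters:::bi_add(a, b)
  ## Pascal: C(81,40) = C(80,40) + C(80,39)
  expect_identical(SpineClusters:::bi_to_string(s),
                   as.character(exactChoose(81, 40)))
  d <- SpineClusters:::bi_sub(s, b)
  expect_identical(SpineClusters:::bi_to_string(d), as.character(a))
  str <- as.character(exactChoose(123, 61))
  expect_identical(SpineClusters:::bi_to_string(SpineClusters:::str_to_bi(str)),
                   str)
})
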