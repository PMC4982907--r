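test_that("2x2 chi-square matches the hand-computed oracle", {
  m <- matrix(c(45, 36, 44, 67), 2)
  res <- chiSquare2x2(m)
  expect_equal(res$statistic, chi2_oracle(m), tolerance = 1e-12)
  expect_equal(res$statistic, 4.77, tolerance = 0.01)
  expect_equal(res$p.value, 0.029, tolerance = 0.01)
  ## identical proportions: statistic 0, p 1
  eq <- chiSquare2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("Yates correction can only shrink the statistic", {
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    expect_gte(chiSquare2x2(m, correct = FALSE)$statistic,
               chiSquare2x2(m, correct = TRUE)$statistic)
  }
})

test_that("exact rank-sum p-values match full enumeration (n, m <= 6)", {
  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
  ## complete separation at n = m = 3: exact two-sided p = 2/20
  sep <- rankSumTest(c(4, 5, 6), c(1, 2, 3))
  expect_true(sep$exact)
  expect_equal(sep$p.value, 0.1)
  expect_equal(unname(sep$U), 9)
  set.seed(14)
  for (rep in 1:15) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    x <- runif(n)
    y <- runif(m)
    got <- rankSumTest(x, y)
    expect_true(got$exact)
    expect_equal(got$p.value, mw_enum_p(x, y), tolerance = 1e-12)
    ## U identity: U_a + U_b = n * m
    expect_equal(unname(got$U + rankSumTest(y, x)$U), n * m)
  }
})

test_that("tied samples fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3)
  res <- rankSumTest(a, a)
  expect_false(res$exact)
  expect_equal(res$p.value, 1)
})

test_that("Wilson intervals behave at the boundaries", {
  all_hit <- fractionWithCI(20, 20)
  expect_equal(all_hit$proportion, 1)
  expect_equal(all_hit$upper, 1)
  expect_lt(all_hit$lower, 1)
  none <- fractionWithCI(0, 15)
  expect_equal(none$proportion, 0)
  expect_equal(none$lower, 0)
  expect_gt(none$upper, 0)
  expect_error(fractionWithCI(1, 0), "positive")
  ## replicate-retina summary: mean and SE
  s <- replicateFractionSummary(c(0.8, 0.9, 1.0))
  expect_equal(s$mean, 0.9)
  expect_equal(s$se, 0.0577, tolerance = 1e-3)
})

test_that("density masks keep dense areas and drop sparse clusters", {
  set.seed(40)
  dense <- cbind(rnorm(1000, 0, 150), rnorm(1000, 0, 150))
  sparse <- cbind(rnorm(100, 2000, 150), rnorm(100, 2000, 150))
  cells <- data.frame(x_um = c(dense[, 1], sparse[, 1]),
                      y_um = c(dense[, 2], sparse[, 2]),
                      label_GFP = TRUE)
  map <- LabeledCellMap(cells)
  mask <- densityMask(map, "GFP", cellSize = 100, minDensity = 0.5)
  expect_true(any(maskContains(mask, dense[, 1], dense[, 2])))
  ## every grid cell of the sparse cluster is below half the peak density
  expect_false(any(maskContains(mask, sparse[, 1], sparse[, 2])))
  ## minDensity = 1 keeps only peak-density cells
  m1 <- densityMask(map, "GFP", cellSize = 100, minDensity = 1)
  expect_equal(sum(m1$keep), sum(m1$counts == max(m1$counts)))
})

test_that("co-label fractions recover the generating probability", {
  p1 <- simulateRetinaMap(defaultRetinaMapParams(colabelProb = 1),
                          seed = 2)
  expect_equal(colabelFraction(p1, "GFP", "DiD"), 1)
  p0 <- simulateRetinaMap(defaultRetinaMapParams(colabelProb = 0),
                          seed = 2)
  expect_equal(colabelFraction(p0, "GFP", "DiD"), 0)
  ## binomial SE bound at p = 0.8 with ~1000 cells in the mask
  prm <- defaultRetinaMapParams(colabelProb = 0.8)
  prm$channels$GFP$n <- 1000
  map <- simulateRetinaMap(prm, seed = 9)
  mask <- densityMask(map, "GFP", cellSize = 200, minDensity = 0)
  fr <- colabelFraction(map, "GFP", "DiD", mask)
  expect_lt(abs(fr - 0.8), 3 * sqrt(0.8 * 0.2 / 1000))
  ## no reference cells inside the mask -> NA with a message
  far <- densityMask(map, "GFP", cellSize = 200, minDensity = 0)
  far$keep[] <- FALSE
  expect_message(res <- colabelFraction(map, "GFP", "DiD", far),
                 "no reference")
  expect_true(is.na(res))
})

test_that("co-label estimator is unbiased across seeds", {
  prm <- defaultRetinaMapParams(colabelProb = 0.7)
  prm$channels$GFP$n <- 200
  prm$channels$mCherry$n <- 0
  fr <- vapply(1:200, function(s)
    colabelFraction(simulateRetinaMap(prm, seed = s), "GFP", "DiD"), 0)
  se <- sqrt(0.7 * 0.3 / 200) / sqrt(200)
  expect_lt(abs(mean(fr) - 0.7), 4 * se)
})
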