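twoGroupStudy <- function(seed = 1, kappas = 30, nGenes = 5,
                          groupSizes = c(3, 3), perturbations = NULL) {
  simulateStudy(syntheticConfig(nGenes = nGenes, groupSizes = groupSizes,
                                kappas = kappas,
                                perturbations = perturbations, seed = seed))
}

test_that("T vanishes when groups are identical copies and is rotation-invariant", {
  st <- twoGroupStudy(seed = 4)
  ## identical copies: duplicate group 1's experiments as group 2
  th <- phaseAngles(st)[, 1:3]
  dup <- PhaseStudy(cbind(th, th), groups = rep(c("a", "b"), each = 3),
                    kappa = 10, experimentIds = paste0("e", 1:6))
  det <- testCommonOrder(dup, B = 5, seed = 1)
  expect_equal(det@statistic, 0)
  ## T through the exported testStatistic with explicit orders
  est <- estimateOrder(dup)
  expect_equal(testStatistic(dup, list(est, est), est), det@statistic)
  ## per-experiment rotation leaves T unchanged
  st2 <- twoGroupStudy(seed = 9, perturbations = list(NULL, list(
    type = "swap", genes = c(1, 2))))
  T1 <- testCommonOrder(st2, B = 1, seed = 2)@statistic
  rot <- wrapAngle(sweep(phaseAngles(st2), 2,
                         seq(0.5, 3.5, length.out = 6), "+"))
  stRot <- PhaseStudy(rot, groups = experimentGroups(st2), kappa = 30)
  expect_equal(testCommonOrder(stRot, B = 1, seed = 2)@statistic, T1,
               tolerance = 1e-10)
})

test_that("a reversed group on concentrated data drives T toward 1", {
  cfg <- syntheticConfig(nGenes = 5, groupSizes = c(4, 4), kappas = 200,
                         seed = 21)
  st <- simulateStudy(cfg)
  th <- phaseAngles(st)
  ## reverse temporal direction in group 2
  th[, 5:8] <- wrapAngle(-th[, 5:8])
  stRev <- PhaseStudy(th, groups = experimentGroups(st), kappa = 200)
  T <- testCommonOrder(stRev, B = 1, seed = 3)@statistic
  expect_gt(T, 0.8)
  expect_lte(T, 1)
})

test_that("resampling draws each experiment with probability 1/(S p_s)", {
  gc <- rep(1:2, times = c(2, 4))   # S = 2, p = (2, 4)
  set.seed(123)
  draws <- 20000L
  counts <- integer(6)
  for (b in seq_len(draws)) {
    idx <- phaseOrder:::.drawResampleIdx(gc)
    tab <- tabulate(idx, 6)
    counts <- counts + tab
  }
  N <- draws * 6   # total selections
  pTrue <- c(rep(1 / (2 * 2), 2), rep(1 / (2 * 4), 4))
  for (j in 1:6) {
    se <- sqrt(N * pTrue[j] * (1 - pTrue[j]))
    expect_lt(abs(counts[j] - N * pTrue[j]), 3 * se)
  }
})

test_that("resampleStudy keeps sizes, recomputes weights, honors seeds", {
  st <- twoGroupStudy(seed = 6, groupSizes = c(2, 4), kappas = c(rep(5, 2),
                                                                 rep(20, 4)))
  rs <- resampleStudy(st, seed = 42)
  expect_equal(dim(rs), dim(st))
  expect_equal(table(experimentGroups(rs)), table(experimentGroups(st)))
  expect_equal(sum(experimentWeights(rs)), 1, tolerance = 1e-12)
  expect_equal(phaseAngles(resampleStudy(st, seed = 42)), phaseAngles(rs))
  ## S = 1 reduces to uniform within the single group
  one <- makeStudy(phaseAngles(st), kappa = kappaValues(st))
  expect_silent(resampleStudy(one, seed = 1))
})

test_that("p-value follows the (1 + #)/(1 + B) convention", {
  st <- twoGroupStudy(seed = 8)
  tt <- testCommonOrder(st, B = 37, seed = 5)
  expect_equal(tt@pValue,
               (1 + sum(tt@resampledStats >= tt@statistic)) / (1 + 37))
  expect_gt(tt@pValue, 0)
  expect_lte(tt@pValue, 1)
  t1 <- testCommonOrder(st, B = 1, seed = 5)
  expect_true(t1@pValue %in% c(0.5, 1))
  expect_error(testCommonOrder(st, B = 0, seed = 1), "B must be")
})

test_that("the test is fully reproducible given a seed", {
  st <- twoGroupStudy(seed = 10)
  a <- testCommonOrder(st, B = 25, seed = 77)
  b <- testCommonOrder(st, B = 25, seed = 77)
  expect_identical(a@pValue, b@pValue)
  expect_identical(a@resampledStats, b@resampledStats)
  expect_true(a@globalOrder@order == b@globalOrder@order)
})

test_that("partial-order aggregation handles degenerate and limiting cases", {
  A <- CircularOrder(c(1, 3, 4, 5, 2))
  ## all resamples agree: simple order, confidence 1
  solo <- aggregateOrderFrequencies(list(A), 500)
  expect_equal(solo@confidence, 1)
  expect_equal(lengths(solo@blocks), rep(1L, 5))

  B <- CircularOrder(c(1, 3, 4, 2, 5))
  both <- aggregateOrderFrequencies(list(A, B), c(600, 300), total = 1000)
  expect_equal(both@confidence, 0.9)
  ## threshold 1.0: modal order only
  modalOnly <- aggregateOrderFrequencies(list(A, B), c(600, 300),
                                         freqThreshold = 1, total = 1000)
  expect_equal(modalOnly@confidence, 0.6)
  expect_equal(lengths(modalOnly@blocks), rep(1L, 5))
  ## confidence is nonincreasing in the threshold
  conf <- vapply(c(0.05, 0.2, 0.4, 1), function(thr)
    aggregateOrderFrequencies(list(A, B), c(600, 300), freqThreshold = thr,
                              total = 1000)@confidence, numeric(1))
  expect_true(all(diff(conf) <= 1e-12))
  ## confidence at least the modal frequency
  expect_true(all(conf >= 0.6 - 1e-12))
})

test_that("confidencePartialOrder concentrates on the true order", {
  cfg <- syntheticConfig(nGenes = 4, groupSizes = c(3, 3), kappas = 100,
                         seed = 14)
  st <- simulateStudy(cfg)
  po <- confidencePartialOrder(st, B = 60, seed = 2)
  expect_gte(po@confidence, 0.9)
  expect_true(po@modalOrder == trueOrder(cfg))
  ## reproducible
  po2 <- confidencePartialOrder(st, B = 60, seed = 2)
  expect_identical(po@confidence, po2@confidence)
  expect_identical(po@blocks, po2@blocks)
})

test_that("forward selection keeps a fully concordant panel", {
  cfg <- syntheticConfig(nGenes = 5, groupSizes = c(3, 3), kappas = 100,
                         seed = 17)
  st <- simulateStudy(cfg)
  fs <- forwardSelection(st, alphaLevel = 0.05, B = 50, seed = 3)
  expect_equal(fs@genes, geneIds(st))
  expect_gte(fs@test@pValue, 0.05)
  expect_equal(fs@test@B, 50L)
})

test_that("forward selection drops a gene planted out of order", {
  cfg <- syntheticConfig(nGenes = 6, groupSizes = c(4, 4), kappas = 50,
                         perturbations = list(NULL,
                                              list(type = "shuffle",
                                                   gene = 3L)),
                         seed = 23)
  st <- simulateStudy(cfg)
  fs <- forwardSelection(st, alphaLevel = 0.05, B = 100, seed = 4)
  expect_equal(fs@genes, paste0("g", c(1, 2, 4, 5, 6)))
})
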