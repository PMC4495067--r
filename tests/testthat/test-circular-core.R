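test_that("circular mean pools angles on the circle, not the line", {
  expect_equal(circularMean(c(pi / 4, pi / 4)), pi / 4)
  expect_equal(circularMean(c(0.1, 2 * pi - 0.1)), 0)
  ## the arithmetic mean of (0.1, 2*pi - 0.1) would be pi -- the opposite pole
  expect_error(circularMean(c(0, pi)), "undefined circular mean")
  expect_equal(circularMean(c(0, pi / 2), weights = c(1, 0)), 0)
  expect_error(circularMean(c(0, 1), weights = c(1, 1, 1)), "length")
  expect_error(circularMean(c(0, 1), weights = c(0, 0)), "weights")
})

test_that("circular mean minimizes the weighted cosine loss (grid check)", {
  set.seed(42)
  grid <- seq(0, 2 * pi, by = 0.001)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    th <- runif(k, 0, 2 * pi)
    w <- runif(k, 0.1, 2)
    m <- circularMean(th, w)
    lossAt <- function(x) sum(w * (1 - cos(th - x)))
    gridMin <- min(vapply(grid, lossAt, numeric(1)))
    expect_lte(lossAt(m), gridMin + 1e-5)
  }
})

test_that("circular mean is rotation-equivariant", {
  set.seed(7)
  th <- runif(6, 0, 2 * pi)
  for (delta in c(0.3, pi, 5.5)) {
    expect_equal(circularMean(wrapAngle(th + delta)),
                 wrapAngle(circularMean(th) + delta), tolerance = 1e-10)
  }
})

test_that("SCE matches its definition and is rotation-invariant", {
  v <- runif(5, 0, 2 * pi)
  expect_equal(sce(v, v), 0)
  expect_equal(sce(0, pi), 2)                      # antipode: max per-gene error
  expect_equal(sce(c(0, pi / 2), c(pi / 2, pi / 2)), 1)
  expect_error(sce(c(0, 1), 0), "length")
  set.seed(11)
  a <- runif(8, 0, 2 * pi)
  b <- runif(8, 0, 2 * pi)
  expect_equal(sce(wrapAngle(a + 1.1), wrapAngle(b + 1.1)), sce(a, b),
               tolerance = 1e-12)
  expect_lte(sce(a, b), 2 * 8)
})

test_that("kappa weights are proportional and sum to one", {
  expect_equal(weightsFromKappa(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(weightsFromKappa(5), 1)
  expect_equal(weightsFromKappa(rep(3, 7)), rep(1 / 7, 7))
  set.seed(3)
  for (rep in 1:20) {
    k <- runif(sample(2:10, 1), 0.01, 100)
    expect_equal(sum(weightsFromKappa(k)), 1, tolerance = 1e-12)
  }
  expect_error(weightsFromKappa(c(1, 0)), "positive")
  expect_error(weightsFromKappa(c(1, -2)), "positive")
})

test_that("kappa estimation recovers concentration from residuals", {
  expect_warning(k <- estimateKappa(rep(1.3, 10)), "capping")
  expect_equal(k, 500)
  set.seed(99)
  k5 <- estimateKappa(rvonmises(10000, 0, 5))
  expect_gte(k5, 4.5)
  expect_lte(k5, 5.5)
  set.seed(100)
  kUnif <- estimateKappa(runif(10000, 0, 2 * pi))
  expect_lt(kUnif, 0.1)
  expect_error(estimateKappa(0.5), "at least 2")
})

test_that("MSCE reduces to per-experiment SCE/n and is zero on ordered data", {
  n <- 4
  th <- matrix(c(0.2, 1.4, 3.0, 5.1), n, 1, dimnames = list(paste0("g", 1:n)))
  st1 <- makeStudy(th, kappa = 7)
  ord <- CircularOrder(1:n, geneIds(st1))
  expect_equal(msce(st1, ord), 0)

  ## single experiment with a violation: MSCE = SCE(CIRE)/n
  bad <- matrix(c(0, pi, pi / 2), 3, 1,
                dimnames = list(paste0("g", 1:3)))
  stBad <- makeStudy(bad, kappa = 3)
  o3 <- CircularOrder(1:3, geneIds(stBad))
  f <- cireFit(bad[, 1], o3)
  expect_equal(msce(stBad, o3), f@sce / 3, tolerance = 1e-12)

  ## two experiments, hand-built violation, equal weights: average of the two
  two <- cbind(c(0.2, 1.4, 3.0), c(0, pi, pi / 2))
  rownames(two) <- paste0("g", 1:3)
  st2 <- makeStudy(two, kappa = c(5, 5))
  expect_equal(st2 |> experimentWeights(), c(0.5, 0.5))
  expect_equal(msce(st2, o3), 0.5 * 0 + 0.5 * f@sce / 3, tolerance = 1e-12)
})
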