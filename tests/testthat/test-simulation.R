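test_that("von Mises sampling matches its theoretical resultant length", {
  set.seed(55)
  for (kappa in c(0.5, 2, 10)) {
    x <- rvonmises(20000, mu = 1, kappa = kappa)
    rbar <- sqrt(mean(sin(x))^2 + mean(cos(x))^2)
    A <- besselA(kappa)
    ## var of Rbar is approx (1 - A^2 - A/kappa)/N
    se <- sqrt(max(1 - A^2 - A / kappa, 1e-6) / 20000)
    expect_lt(abs(rbar - A), 3 * se + 5e-3)
    m <- atan2(mean(sin(x)), mean(cos(x)))
    expect_lt(abs(m - 1), 0.05)
  }
  ## kappa = 0: circular uniform
  set.seed(56)
  u <- rvonmises(20000, 0, 0)
  expect_lt(sqrt(mean(sin(u))^2 + mean(cos(u))^2), 0.02)
})

test_that("huge concentration pins observations to the true phases", {
  cfg <- syntheticConfig(nGenes = 5, groupSizes = 2, kappas = 1e6, seed = 2)
  st <- simulateStudy(cfg)
  diffs <- abs(wrapAngle(phaseAngles(st) - cfg@phases + pi) - pi)
  expect_true(all(diffs < 0.01))
})

test_that("per-gene circular means converge to the true phases", {
  cfg <- syntheticConfig(nGenes = 4, groupSizes = 1000, kappas = 10, seed = 3)
  st <- simulateStudy(cfg)
  se <- 1 / sqrt(1000 * 10)   # approx circular SE at large kappa
  for (i in 1:4) {
    m <- circularMean(phaseAngles(st)[i, ])
    expect_lt(abs(wrapAngle(m - cfg@phases[i] + pi) - pi), 3 * se + 1e-3)
  }
})

test_that("identical seeds give bitwise-identical studies", {
  cfg <- syntheticConfig(nGenes = 5, groupSizes = c(3, 2), kappas = 20,
                         seed = 9)
  expect_identical(phaseAngles(simulateStudy(cfg)),
                   phaseAngles(simulateStudy(cfg)))
})

test_that("perturbing one group leaves the other group's draws unchanged", {
  base <- syntheticConfig(nGenes = 5, groupSizes = c(3, 3), kappas = 30,
                          seed = 12)
  pert <- syntheticConfig(nGenes = 5, groupSizes = c(3, 3), kappas = 30,
                          perturbations = list(NULL, list(type = "swap",
                                                          genes = c(1, 2))),
                          seed = 12)
  a <- phaseAngles(simulateStudy(base))
  b <- phaseAngles(simulateStudy(pert))
  expect_identical(a[, 1:3], b[, 1:3])
  expect_false(identical(a[, 4:6], b[, 4:6]))
  ## the harness never mutates its input config
  expect_identical(pert@phases, base@phases)
})

test_that("shuffle perturbation always changes the gene's cyclic position", {
  for (seed in 1:20) {
    cfg <- syntheticConfig(nGenes = 6, groupSizes = c(1, 1), kappas = 1e6,
                           perturbations = list(NULL, list(type = "shuffle",
                                                           gene = 3L)),
                           seed = seed)
    st <- simulateStudy(cfg)
    ## group 2's near-noiseless angles must violate the generating order
    expect_false(satisfiesOrder(phaseAngles(st)[, 2], trueOrder(cfg)))
  }
})

test_that("shift and swap perturbations act on the stated genes only", {
  cfg <- syntheticConfig(nGenes = 4, groupSizes = c(1, 1, 1), kappas = 1e8,
                         perturbations = list(NULL,
                                              list(type = "shift", gene = 2L,
                                                   delta = 0.7),
                                              list(type = "swap",
                                                   genes = c(1L, 3L))),
                         seed = 5)
  st <- simulateStudy(cfg)
  th <- phaseAngles(st)
  expect_equal(wrapAngle(th[2, 2] - th[2, 1]), 0.7, tolerance = 1e-3)
  expect_equal(th[c(1, 3), 3], th[c(3, 1), 1], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(th[c(2, 4), 3], th[c(2, 4), 1], tolerance = 1e-3)
})

test_that("degenerate alpha levels give degenerate rejection rates", {
  cfg <- syntheticConfig(nGenes = 4, groupSizes = c(2, 2), kappas = 20,
                         seed = 7)
  oc1 <- type1Error(cfg, nReps = 5, B = 10, alphaLevel = 1, seed = 1)
  expect_equal(oc1@rejectionRate, 1)
  oc0 <- type1Error(cfg, nReps = 5, B = 10, alphaLevel = 0, seed = 1)
  expect_equal(oc0@rejectionRate, 0)
  expect_equal(oc0@standardError, 0)
  expect_length(oc0@pValues, 5)
  expect_error(type1Error(syntheticConfig(
    nGenes = 4, groupSizes = c(2, 2), kappas = 20,
    perturbations = list(NULL, list(type = "swap", genes = c(1, 2))),
    seed = 1)), "null configuration")
})

test_that("a zero shift reproduces the null harness exactly", {
  null <- syntheticConfig(nGenes = 4, groupSizes = c(2, 2), kappas = 25,
                          seed = 8)
  zero <- syntheticConfig(nGenes = 4, groupSizes = c(2, 2), kappas = 25,
                          perturbations = list(NULL, list(type = "shift",
                                                          gene = 1L,
                                                          delta = 0)),
                          seed = 8)
  ocN <- type1Error(null, nReps = 4, B = 20, seed = 2)
  ocZ <- testPower(zero, nReps = 4, B = 20, seed = 2)
  expect_identical(ocN@pValues, ocZ@pValues)
})

test_that("an adjacent swap at high concentration is detected with high power", {
  cfg <- syntheticConfig(nGenes = 5, groupSizes = c(4, 4), kappas = 50,
                         perturbations = list(NULL, list(type = "swap",
                                                         genes = c(2L, 3L))),
                         seed = 19)
  oc <- testPower(cfg, nReps = 30, B = 100, alphaLevel = 0.05, seed = 6)
  expect_gte(oc@rejectionRate, 0.8)
})
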