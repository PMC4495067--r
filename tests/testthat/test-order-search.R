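test_that("directed distances follow the printed branches", {
  expect_equal(d1(0, 0), 0)
  expect_equal(d1(0, pi / 2), 1)
  expect_equal(d1(0, 3 * pi / 2), 3)            # 3 - cos(pi/2)
  expect_equal(d2(0, pi / 2), 3)                # 3 - cos(-pi/2)
  expect_equal(d2(0, 2 * pi - 1e-9), 1 - cos(1e-9), tolerance = 1e-12)
  ## both branches meet at Delta = pi
  expect_equal(d1(0, pi), 2)
  expect_equal(d2(0, pi), 2)
})

test_that("edge cost takes the cheaper direction under the alpha penalty", {
  expect_equal(edgeCost(0, pi / 2, alpha = 3), 1)           # min(1, 9)
  expect_equal(edgeCost(0, 7 * pi / 4, alpha = 3),
               3 * (1 - cos(pi / 4)), tolerance = 1e-12)    # clockwise shortcut
  ## alpha = 1: no penalty, cost symmetric
  set.seed(1)
  th <- runif(10, 0, 2 * pi)
  for (i in 1:5)
    expect_equal(edgeCost(th[i], th[i + 5], 1), edgeCost(th[i + 5], th[i], 1),
                 tolerance = 1e-12)
  expect_error(edgeCost(0, 1, alpha = 0.5), "alpha")
})

test_that("cost matrix is the weighted sum of per-experiment layers", {
  th <- cbind(c(0.3, 2.0, 4.4), c(1.0, 2.2, 5.0))
  rownames(th) <- paste0("g", 1:3)
  st <- makeStudy(th, kappa = c(3, 7))   # weights 0.3, 0.7
  cm <- buildCostMatrix(st, alpha = 3)
  expect_equal(cm@weights, c(0.3, 0.7))
  manual <- 0.3 * outer(th[, 1], th[, 1], edgeCost) +
            0.7 * outer(th[, 2], th[, 2], edgeCost)
  diag(manual) <- 0
  expect_equal(unname(cm@E), unname(manual), tolerance = 1e-12)
  ## entrywise hand computation of one entry
  expect_equal(cm@E["g1", "g2"],
               0.3 * min(d1(0.3, 2.0), 3 * d2(0.3, 2.0)) +
               0.7 * min(d1(1.0, 2.2), 3 * d2(1.0, 2.2)), tolerance = 1e-12)

  ## single experiment: E equals its own layer
  st1 <- makeStudy(th[, 1, drop = FALSE], kappa = 5)
  cm1 <- buildCostMatrix(st1)
  expect_equal(cm1@E, cm1@layers[, , 1])

  ## duplicated experiment with split weights matches one full-weight copy
  stDup <- makeStudy(th[, c(1, 1)], kappa = c(4, 4))
  expect_equal(buildCostMatrix(stDup)@E, cm1@E, tolerance = 1e-12)

  ## C++ fast path agrees with the R construction
  expect_equal(unname(phaseOrder:::cpp_cost_matrix(th, c(0.3, 0.7), 3)),
               unname(cm@E), tolerance = 1e-12)
})

test_that("Held-Karp finds the exhaustive-enumeration optimum", {
  set.seed(321)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    E <- matrix(runif(n * n, 0, 4), n, n)
    diag(E) <- 0
    tour <- phaseOrder:::cpp_solve_tsp(E, TRUE) + 1
    cost <- sum(E[cbind(tour, c(tour[-1], tour[1]))])
    expect_equal(cost, bruteTourCost(E), tolerance = 1e-10)
  }
  ## n = 3: the cheaper of the only two directed tours
  E3 <- matrix(c(0, 1, 5, 5, 0, 1, 1, 5, 0), 3, 3)
  t3 <- solveTSP(E3, genes = c("a", "b", "c"))
  costs <- c(E3[1, 2] + E3[2, 3] + E3[3, 1], E3[1, 3] + E3[3, 2] + E3[2, 1])
  tour <- orderSequence(t3)
  expect_equal(sum(E3[cbind(tour, c(tour[-1], tour[1]))]), min(costs))
})

test_that("TSP on well-separated angles returns the data's own arrangement", {
  th <- matrix(wrapAngle(2 * pi * (0:5) / 6 + 0.2), ncol = 1)
  rownames(th) <- paste0("g", 1:6)
  st <- makeStudy(th, kappa = 10)
  ord <- solveTSP(buildCostMatrix(st))
  expect_true(ord == CircularOrder(1:6, geneIds(st)))
  ## and agrees with brute-force enumeration of the cost matrix
  E <- buildCostMatrix(st)@E
  tour <- orderSequence(ord)
  expect_equal(sum(E[cbind(tour, c(tour[-1], tour[1]))]), bruteTourCost(E),
               tolerance = 1e-12)
})

test_that("symmetric costs make a tour and its reversal equally expensive", {
  set.seed(12)
  th <- matrix(runif(6, 0, 2 * pi), ncol = 1)
  rownames(th) <- paste0("g", 1:6)
  E <- buildCostMatrix(makeStudy(th), alpha = 1)@E
  expect_equal(unname(E), unname(t(E)), tolerance = 1e-12)
  tour <- orderSequence(solveTSP(E, genes = rownames(th)))
  rev_ <- rev(tour)
  cost <- function(tt) sum(E[cbind(tt, c(tt[-1], tt[1]))])
  expect_equal(cost(tour), cost(rev_), tolerance = 1e-12)
})

test_that("circular local minimization removes planted bumps, never ascends", {
  set.seed(77)
  cfg <- syntheticConfig(nGenes = 4, groupSizes = 3, kappas = 80, seed = 5)
  st <- simulateStudy(cfg)
  good <- CircularOrder(1:4, geneIds(st))
  ## plant an adjacent transposition
  bumped <- CircularOrder(c(2, 1, 3, 4), geneIds(st))
  refined <- circularLocalMinimization(bumped, st)
  expect_true(refined == good)
  expect_lt(msce(st, refined), msce(st, bumped))
  ## locally optimal input is a fixed point
  expect_true(circularLocalMinimization(good, st) == good)
  ## supplied rotation of the same cycle cannot change the outcome
  rotated <- CircularOrder(c(3, 4, 2, 1), geneIds(st))  # rotation of bumped
  expect_true(circularLocalMinimization(rotated, st) == refined)
  ## monotone descent from random starts
  for (rep in 1:5) {
    start <- CircularOrder(sample(4), geneIds(st))
    out <- circularLocalMinimization(start, st)
    expect_lte(msce(st, out), msce(st, start) + 1e-12)
  }
})

test_that("estimateOrder attains the brute-force MSCE optimum on
           concentrated instances", {
  set.seed(2301)
  agree <- 0
  nInst <- 100
  for (rep in seq_len(nInst)) {
    n <- 5
    cfg <- syntheticConfig(nGenes = n, groupSizes = 2, kappas = 30,
                           phases = sort(runif(n, 0, 2 * pi)),
                           seed = sample.int(1e6, 1))
    st <- simulateStudy(cfg)
    est <- estimateOrder(st)
    if (abs(est@msce - bruteBestMSCE(st)) < 1e-9) agree <- agree + 1
    expect_lte(est@msce, est@preMsce + 1e-12)
  }
  expect_gte(agree, 95)
})

test_that("order estimation is invariant to per-experiment rotations", {
  cfg <- syntheticConfig(nGenes = 5, groupSizes = 4, kappas = 40, seed = 31)
  st <- simulateStudy(cfg)
  est <- estimateOrder(st)
  th <- phaseAngles(st)
  set.seed(1)
  rot <- wrapAngle(sweep(th, 2, runif(ncol(th), 0, 2 * pi), "+"))
  stRot <- PhaseStudy(rot, groups = experimentGroups(st),
                      kappa = kappaValues(st))
  estRot <- estimateOrder(stRot)
  expect_true(est@order == estRot@order)
  expect_equal(est@msce, estRot@msce, tolerance = 1e-10)
})

test_that("single ordered experiment gives its own cyclic order with MSCE 0", {
  th <- matrix(c(0.5, 1.7, 2.9, 4.1, 5.3), ncol = 1)
  rownames(th) <- paste0("g", 1:5)
  est <- estimateOrder(makeStudy(th, kappa = 20))
  expect_true(est@order == CircularOrder(1:5, rownames(th)))
  expect_equal(est@msce, 0)
  expect_equal(est@solver, "exact")
})
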