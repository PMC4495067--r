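## Independent oracles and small fixture builders shared across the suite.

twoPi <- 2 * pi

## Quick study from a phase matrix (one group unless stated).
makeStudy <- function(theta, groups = rep("s1", ncol(theta)), kappa = 50) {
  if (is.null(rownames(theta)))
    rownames(theta) <- paste0("g", seq_len(nrow(theta)))
  PhaseStudy(theta, groups = groups, kappa = kappa)
}

## All permutations of a vector (tiny n only).
permsOf <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permsOf(v[-i]), function(p) c(v[i], p)))
  out
}

## All distinct directed circular orders on 1..n (first element fixed at 1).
allCircularOrders <- function(n) {
  lapply(permsOf(seq_len(n)[-1L]), function(p) c(1L, p))
}

## Exhaustive directed-tour minimum of a cost matrix.
bruteTourCost <- function(E) {
  n <- nrow(E)
  best <- Inf
  for (p in allCircularOrders(n)) {
    tour <- c(p, p[1L])
    best <- min(best, sum(E[cbind(tour[-length(tour)], tour[-1L])]))
  }
  best
}

## Exhaustive minimum MSCE over all directed circular orders of a study.
bruteBestMSCE <- function(study) {
  n <- nrow(study)
  vals <- vapply(allCircularOrders(n), function(s)
    msce(study, CircularOrder(s, geneIds(study))), numeric(1L))
  min(vals)
}

## Brute-force CIRE oracle: exhaustive over (cut x composition into
## consecutive level-set blocks), each block's common angle minimized over a
## dense 1-D grid, monotone feasibility checked across blocks in the cut's
## unwrapped window.  Independent of the circular-mean closed form.
cireGridOracle <- function(obs, seqv, step = 0.004) {
  n <- length(seqv)
  best <- Inf
  for (cut in seq_len(n)) {
    idx <- seqv[((seq_len(n) - 1L + cut - 1L) %% n) + 1L]
    a <- obs[idx[1L]]
    grid <- a + seq(0, twoPi - step / 2, by = step)
    for (mask in 0:(2^(n - 1L) - 1L)) {
      bounds <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
      starts <- c(1L, bounds + 1L)
      ends <- c(bounds, n)
      tot <- 0
      prev <- -Inf
      feasible <- TRUE
      for (b in seq_along(starts)) {
        members <- idx[starts[b]:ends[b]]
        loss <- colSums(1 - cos(outer(obs[members], grid, "-")))
        bi <- which.min(loss)
        if (grid[bi] < prev - 1e-9) {
          feasible <- FALSE
          break
        }
        prev <- grid[bi]
        tot <- tot + loss[bi]
      }
      if (feasible && tot < best) best <- tot
    }
  }
  best
}

## A(kappa) = I1/I0, the expected mean resultant length of a von Mises.
besselA <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)
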