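#' Asymmetric circular travel distances
#'
#' Distances between two phase angles depending on the direction of travel
#' around the circle.  With \eqn{\Delta = (\theta_k - \theta_h) \bmod 2\pi}:
#' counterclockwise travel costs \eqn{d_1 = 1 - \cos\Delta} for
#' \eqn{0 \le \Delta \le \pi} and \eqn{3 - \cos(\Delta - \pi)} for
#' \eqn{\pi < \Delta \le 2\pi}; clockwise travel \eqn{d_2} uses the mirrored
#' branches.  Both are continuous, lie in \eqn{[0, 4]}, and satisfy the
#' identity \eqn{d_1 + d_2 \equiv 4}.
#'
#' @param thetaH,thetaK origin and destination angles (radians; vectorized).
#' @return numeric vector of distances in \eqn{[0, 4]}.
#' @examples
#' d1(0, pi / 2)   # 1
#' d2(0, pi / 2)   # 3
#' d1(0, 3 * pi / 2)  # 3
#' @export
d1 <- function(thetaH, thetaK) {
  d <- wrapAngle(thetaK - thetaH)
  ifelse(d <= pi, 1 - cos(d), 3 - cos(d - pi))
}

#' @rdname d1
#' @export
d2 <- function(thetaH, thetaK) {
  d <- wrapAngle(thetaK - thetaH)
  ifelse(d <= pi, 3 - cos(d - pi), 1 - cos(d))
}

#' Directed edge cost between two genes in one experiment
#'
#' \eqn{\min(d_1, \alpha d_2)}: travel counterclockwise at cost \eqn{d_1},
#' or clockwise at cost \eqn{d_2} inflated by the penalty \eqn{\alpha \ge 1}.
#' The penalty encodes that temporal progression is counterclockwise;
#' clockwise shortcuts are allowed but discouraged.  Asymmetric in
#' \eqn{(h, k)} unless \eqn{\alpha = 1}.
#'
#' @param thetaH,thetaK origin and destination angles (radians; vectorized).
#' @param alpha clockwise penalty, >= 1; default 3.
#' @return numeric vector of nonnegative costs.
#' @examples
#' edgeCost(0, pi / 2)       # 1: counterclockwise wins
#' edgeCost(0, 7 * pi / 4)   # ~0.879: the clockwise shortcut wins
#' @export
edgeCost <- function(thetaH, thetaK, alpha = 3) {
  if (any(alpha < 1)) stop("alpha must be >= 1")
  pmin(d1(thetaH, thetaK), alpha * d2(thetaH, thetaK))
}

#' CostMatrix: weighted travel costs between genes
#'
#' The pooled cost \eqn{E_{hk} = \sum_j \omega_j \min(d_{1j}(h,k),
#' \alpha\, d_{2j}(h,k))} together with the per-experiment layers
#' \eqn{E^j} retained for diagnostics.
#'
#' @slot E n x n pooled cost matrix (diagonal unused, set to 0).
#' @slot layers n x n x P array of per-experiment costs.
#' @slot alpha the clockwise penalty used.
#' @slot weights the experiment weights used.
#'
#' @exportClass CostMatrix
setClass("CostMatrix",
         representation(E = "matrix", layers = "array", alpha = "numeric",
                        weights = "numeric"))

setMethod("show", "CostMatrix", function(object) {
  cat("CostMatrix: ", nrow(object@E), " genes, ",
      dim(object@layers)[3L], " experiment layer(s), alpha = ",
      object@alpha, "\n", sep = "")
})

#' Build the travel-cost matrix of a study
#'
#' @param study a \linkS4class{PhaseStudy}.
#' @param alpha clockwise penalty (default 3).
#' @return a \linkS4class{CostMatrix}.
#' @export
buildCostMatrix <- function(study, alpha = 3) {
  th <- phaseAngles(study)
  w <- experimentWeights(study)
  n <- nrow(th)
  P <- ncol(th)
  layers <- array(0, dim = c(n, n, P),
                  dimnames = list(rownames(th), rownames(th), colnames(th)))
  for (j in seq_len(P)) {
    lj <- outer(th[, j], th[, j], function(h, k) edgeCost(h, k, alpha))
    diag(lj) <- 0
    layers[, , j] <- lj
  }
  E <- matrix(0, n, n, dimnames = list(rownames(th), rownames(th)))
  for (j in seq_len(P)) E <- E + w[j] * layers[, , j]
  new("CostMatrix", E = E, layers = layers, alpha = alpha, weights = w)
}

#' Solve the asymmetric TSP over the gene cost matrix
#'
#' Finds the directed tour of minimum total cost -- the candidate circular
#' order.  For \code{n <= nExact} the exactly optimal tour is computed by
#' Held-Karp dynamic programming; beyond that a nearest-neighbour
#' construction refined by or-opt segment relocation (orientation-preserving,
#' hence safe for asymmetric costs) is used.
#'
#' @param costs a \linkS4class{CostMatrix} or a plain square cost matrix.
#' @param nExact exact-solver threshold (default 15).
#' @param genes optional gene labels when \code{costs} is a plain matrix.
#' @return a \linkS4class{CircularOrder}; an attribute-free trivial order
#'   (with a warning) when n < 3.
#' @export
solveTSP <- function(costs, nExact = 15L, genes = NULL) {
  E <- if (is(costs, "CostMatrix")) costs@E else as.matrix(costs)
  n <- nrow(E)
  if (is.null(genes)) genes <- rownames(E)
  if (n < 3L) {
    warning("fewer than 3 nodes: every arrangement is a tour")
    return(CircularOrder(seq_len(n), genes))
  }
  if (nExact > 18L) nExact <- 18L  # Held-Karp memory grows as 2^n
  tour <- cpp_solve_tsp(E, n <= nExact)
  CircularOrder(tour + 1L, genes)
}

#' @describeIn circularLocalMinimization Refine an order by sweeping all
#'   cyclic consecutive triples: each triple's six arrangements are scored
#'   by the study MSCE with the rest of the order fixed, and a rearrangement
#'   is accepted iff it strictly lowers the MSCE.  Sweeps repeat until a
#'   full sweep makes no change (or \code{maxSweeps} is hit); the result
#'   never has higher MSCE than the input.  This is the circular analogue of
#'   local Kemenization in rank aggregation.
#' @param order a \linkS4class{CircularOrder}.
#' @param study the \linkS4class{PhaseStudy} scoring the order.
#' @param maxSweeps sweep cap (default 50).
#' @param ... unused.
#' @export
setMethod("circularLocalMinimization",
          signature(order = "CircularOrder", study = "PhaseStudy"),
          function(order, study, maxSweeps = 50L, ...) {
  .checkOrderPanel(order, study)
  refined <- cpp_local_min(order@sequence - 1L, phaseAngles(study),
                           experimentWeights(study), as.integer(maxSweeps))
  CircularOrder(refined + 1L, order@genes)
})

#' @describeIn estimateOrder Estimate the common circular order of a study:
#'   build the weighted asymmetric cost matrix, solve the TSP (exactly via
#'   Held-Karp for \code{n <= nExact}), then refine with circular local
#'   minimization.  Both the pre-refinement tour and the refined estimate
#'   are recorded.
#' @param study a \linkS4class{PhaseStudy} with n >= 3 genes.
#' @param alpha clockwise travel penalty (default 3).
#' @param nExact exact-TSP threshold (default 15).
#' @param maxSweeps local-minimization sweep cap (default 50).
#' @param ... unused.
#' @return an \linkS4class{OrderEstimate}.
#' @examples
#' st <- simulateStudy(syntheticConfig(nGenes = 5, groupSizes = 3,
#'                                     kappas = 50, seed = 7))
#' estimateOrder(st)
#' @export
setMethod("estimateOrder", "PhaseStudy",
          function(study, alpha = 3, nExact = 15L, maxSweeps = 50L, ...) {
  if (nrow(study) < 3L)
    stop("need at least 3 genes to estimate a circular order")
  if (nExact > 18L) nExact <- 18L
  res <- cpp_estimate_order(phaseAngles(study), experimentWeights(study),
                            alpha, as.integer(nExact),
                            as.integer(maxSweeps))
  genes <- geneIds(study)
  new("OrderEstimate",
      order = CircularOrder(res$order + 1L, genes),
      msce = as.numeric(res$msce),
      preRefinement = CircularOrder(res$order0 + 1L, genes),
      preMsce = as.numeric(res$msce0),
      solver = if (isTRUE(res$exact)) "exact" else "heuristic",
      alpha = alpha)
})

setMethod("show", "OrderEstimate", function(object) {
  cat("OrderEstimate (", object@solver, " TSP, alpha = ", object@alpha,
      ")\n  order: ", paste(orderCycle(object@order), collapse = " -> "),
      " -> ...\n  MSCE:  ", format(object@msce, digits = 6), "\n", sep = "")
})
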