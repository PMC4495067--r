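## Shared circular-arithmetic substrate: angle canonicalization, circular
## means, the SCE/MSCE objectives and kappa-based experiment weights.

#' Canonicalize angles to [0, 2*pi)
#'
#' Reduces any real angle (radians) modulo \eqn{2\pi} into \eqn{[0, 2\pi)}.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector in \eqn{[0, 2\pi)}.
#' @examples
#' wrapAngle(c(-pi / 2, 2 * pi, 7))
#' @export
wrapAngle <- function(x) {
  x %% (2 * pi)
}

#' Weighted circular mean
#'
#' The direction of the weighted resultant vector,
#' \code{atan2(sum(w * sin(theta)), sum(w * cos(theta)))}, canonicalized to
#' \eqn{[0, 2\pi)}.  This is the minimizer of the weighted cosine loss
#' \eqn{\sum_i w_i \{1 - \cos(\theta_i - m)\}} over \eqn{m} -- the pooling
#' primitive used throughout (arithmetic means are meaningless for angles).
#'
#' @param angles numeric vector of angles (radians; wrapped internally).
#' @param weights nonnegative weights, recycled-length-checked; default equal.
#' @param tol resultant-length tolerance below which the mean is declared
#'   undefined (antipodal cancellation).
#' @return a single angle in \eqn{[0, 2\pi)}.
#' @examples
#' circularMean(c(0.1, 2 * pi - 0.1))  # 0: symmetric about the pole
#' @export
circularMean <- function(angles, weights = NULL, tol = 1e-10) {
  if (is.null(weights)) weights <- rep(1, length(angles))
  if (length(weights) != length(angles))
    stop("weights must match angles in length")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero")
  s <- sum(weights * sin(angles))
  c <- sum(weights * cos(angles))
  if (sqrt(s^2 + c^2) / sum(weights) < tol)
    stop("undefined circular mean: resultant length below tolerance ",
         "(antipodal cancellation)")
  wrapAngle(atan2(s, c))
}

#' Sum of circular errors (SCE)
#'
#' \eqn{\mathrm{SCE}(\theta, \tilde\theta) = \sum_i \{1 - \cos(\theta_i -
#' \tilde\theta_i)\}}, the circular distance between an observed and a fitted
#' angle vector; bounded by \eqn{[0, 2n]}.
#'
#' @param observed,fitted numeric angle vectors of equal length.
#' @return nonnegative scalar.
#' @examples
#' sce(c(0, pi / 2), c(pi / 2, pi / 2))  # 1
#' @export
sce <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("observed and fitted must have the same length")
  sum(1 - cos(observed - fitted))
}

#' Experiment weights from von Mises concentrations
#'
#' \eqn{\omega_j = \kappa_j / \sum_j \kappa_j}: experiments whose phase
#' estimates are more concentrated (less noisy) carry more weight.
#'
#' @param kappas positive concentrations, one per experiment.
#' @return nonnegative weights summing to 1.
#' @examples
#' weightsFromKappa(c(1, 1, 2))
#' @export
weightsFromKappa <- function(kappas) {
  if (any(!is.finite(kappas)) || any(kappas <= 0))
    stop("all kappa must be positive and finite")
  kappas / sum(kappas)
}

#' Estimate a von Mises concentration from residual angles
#'
#' Maximum-likelihood estimate of \eqn{\kappa} from the mean resultant length
#' \eqn{\bar R} of the residuals, via Fisher's standard approximation to
#' \eqn{A^{-1}(\bar R)} where \eqn{A(\kappa) = I_1(\kappa)/I_0(\kappa)}.
#' Monotone increasing in \eqn{\bar R}.  This is a convenience for studies
#' whose metadata lacks \eqn{\kappa}; externally supplied concentrations
#' always take precedence.
#'
#' @param residuals angle residuals (radians), length >= 2.
#' @param kappaMax cap returned for degenerate concentrations
#'   (\eqn{\bar R \approx 1}); a warning is raised.
#' @return positive scalar estimate of \eqn{\kappa}.
#' @examples
#' set.seed(1)
#' estimateKappa(rvonmises(500, 0, 5))
#' @export
estimateKappa <- function(residuals, kappaMax = 500) {
  if (length(residuals) < 2L)
    stop("need at least 2 residual angles")
  rbar <- sqrt(mean(sin(residuals))^2 + mean(cos(residuals))^2)
  if (rbar >= 1 - 1e-8) {
    warning("degenerate concentration (mean resultant length ~ 1); ",
            "capping kappa at ", kappaMax)
    return(kappaMax)
  }
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  if (k > kappaMax) {
    warning("degenerate concentration; capping kappa at ", kappaMax)
    k <- kappaMax
  }
  max(k, .Machine$double.eps)
}

#' @describeIn msce Weighted mean sum of circular errors of a study under a
#'   circular order: \eqn{\sum_j \omega_j \mathrm{SCE}(\Theta_j,
#'   \tilde\Theta_j(O)) / n}, where \eqn{\tilde\Theta_j(O)} is the circular
#'   isotonic regression fit of experiment \eqn{j} under \eqn{O}.
#' @param study a \linkS4class{PhaseStudy}.
#' @param order a \linkS4class{CircularOrder} over the study's gene panel.
#' @param ... unused.
#' @return \code{msce}: a nonnegative scalar.
#' @examples
#' st <- simulateStudy(syntheticConfig(nGenes = 4, groupSizes = 2,
#'                                     kappas = 50, seed = 1))
#' msce(st, CircularOrder(1:4, geneIds(st)))
#' @export
setMethod("msce", signature(study = "PhaseStudy", order = "CircularOrder"),
          function(study, order, ...) {
  .checkOrderPanel(order, study)
  cpp_msce(phaseAngles(study), experimentWeights(study),
           order@sequence - 1L)
})
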