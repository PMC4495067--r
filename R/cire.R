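#' Circular isotonic regression (CIRE)
#'
#' Fits the angle vector closest to \code{observed} in sum of circular
#' errors, subject to a fixed circular order constraint: traversed along
#' the order from some starting point, the fitted angles are nondecreasing
#' on an unwrapped scale with total span at most \eqn{2\pi} (ties allowed).
#'
#' The fit is computed by best-cut pool-adjacent-violators: for each of the
#' n possible cut positions the observed angles are lifted into the window
#' \eqn{[\theta_{o_c}, \theta_{o_c} + 2\pi)} and PAVA is run with the cosine
#' loss, pooling violating neighbours into level-set blocks whose common
#' angle is the circular mean of their members; the feasible cut with the
#' smallest SCE wins (ties to the smallest cut index).
#'
#' @param observed numeric vector of angles (radians; wrapped internally),
#'   length >= 2.
#' @param order a \linkS4class{CircularOrder} over the same index set.
#' @return a \linkS4class{CIREFit}.
#' @examples
#' f <- cireFit(c(0, pi, pi / 2), CircularOrder(1:3))
#' f@fitted   # (0, 3*pi/4, 3*pi/4): the violating pair is pooled
#' f@sce      # 2 * (1 - cos(pi/4))
#' @export
cireFit <- function(observed, order) {
  n <- length(observed)
  if (n < 2L)
    stop("need at least 2 angles")
  if (length(order@sequence) != n)
    stop("order length does not match the observed vector")
  obs <- wrapAngle(as.numeric(observed))
  res <- cpp_cire(obs, order@sequence - 1L)
  new("CIREFit", fitted = as.numeric(res$fitted),
      blocks = as.integer(res$blocks), sce = as.numeric(res$sce),
      order = order, cut = as.integer(res$cut))
}

setMethod("show", "CIREFit", function(object) {
  cat("CIREFit: n = ", length(object@fitted),
      ", blocks = ", max(object@blocks),
      ", SCE = ", format(object@sce, digits = 6), "\n", sep = "")
})

#' Does an angle vector satisfy a circular order?
#'
#' TRUE iff, traversing the angles along the order's cycle, every
#' counterclockwise gap is nonnegative and the gaps sum to at most
#' \eqn{2\pi} (equivalently, the cycle winds around the circle at most
#' once; ties are allowed).
#'
#' @param angles numeric vector of angles (radians).
#' @param order a \linkS4class{CircularOrder} of matching length.
#' @param tol numeric slack on the \eqn{2\pi} winding bound.
#' @return logical scalar.
#' @examples
#' satisfiesOrder(c(0, pi / 2, pi), CircularOrder(1:3))  # TRUE
#' satisfiesOrder(c(0, pi, pi / 2), CircularOrder(1:3))  # FALSE
#' @export
satisfiesOrder <- function(angles, order, tol = 1e-9) {
  if (length(angles) != length(order@sequence))
    stop("angles and order must have matching lengths")
  a <- wrapAngle(as.numeric(angles))[order@sequence]
  gaps <- wrapAngle(c(a[-1L], a[1L]) - a)
  sum(gaps) <= 2 * pi + tol
}
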