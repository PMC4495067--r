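#' Construct a CircularOrder
#'
#' A circular (cyclic) order \eqn{\phi_{o_1} \preceq \phi_{o_2} \preceq
#' \cdots \preceq \phi_{o_n} \preceq \phi_{o_1}} among genes, represented by
#' a permutation of gene indices.  The representative is canonicalized by
#' rotating the cycle so the smallest gene index comes first; rotations of
#' the same cycle therefore construct identical objects, while a reversed
#' cycle does not (direction encodes temporal progression).
#'
#' @param sequence integer permutation of \code{1..n} (any rotation).
#' @param genes gene labels aligned with indices \code{1..n}; default
#'   \code{g1..gn}.
#' @return a \linkS4class{CircularOrder}.
#' @examples
#' CircularOrder(c(3, 1, 2)) == CircularOrder(c(1, 2, 3))  # TRUE: rotation
#' CircularOrder(c(1, 3, 2)) == CircularOrder(c(1, 2, 3))  # FALSE: reversal
#' @export
CircularOrder <- function(sequence, genes = NULL) {
  sequence <- as.integer(sequence)
  n <- length(sequence)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  new("CircularOrder", sequence = .canonRotation(sequence),
      genes = as.character(genes))
}

.canonRotation <- function(sequence) {
  n <- length(sequence)
  if (n == 0L) return(integer())
  p <- which.min(sequence)
  sequence[((seq_len(n) - 1L + p - 1L) %% n) + 1L]
}

#' @describeIn CircularOrder the canonical index sequence.
#' @param order a \code{CircularOrder}.
#' @export
orderSequence <- function(order) order@sequence

#' @describeIn CircularOrder gene labels traversed in cycle order.
#' @export
orderedGenes <- function(order) order@genes[order@sequence]

setMethod("length", "CircularOrder", function(x) length(x@sequence))

setMethod("show", "CircularOrder", function(object) {
  cat("CircularOrder (n = ", length(object), "): ",
      paste(orderedGenes(object), collapse = " -> "), " -> ...\n", sep = "")
})

#' @export
setMethod("==", signature("CircularOrder", "CircularOrder"),
          function(e1, e2) {
  identical(e1@sequence, e2@sequence) && identical(e1@genes, e2@genes)
})

#' @export
setMethod("!=", signature("CircularOrder", "CircularOrder"),
          function(e1, e2) !(e1 == e2))

setMethod("as.character", "CircularOrder", function(x)
  paste(orderedGenes(x), collapse = " -> "))

## Internal canonical key used for tabulating bootstrap orders.
.orderKey <- function(sequence) paste(.canonRotation(sequence), collapse = ",")

.keyToSequence <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

#' Serialize a circular order as a gene-id cycle
#'
#' The cycle is rotated to start at the lexicographically smallest gene
#' label, the convention used in JSON reports.
#'
#' @param order a \linkS4class{CircularOrder}.
#' @return character vector of gene labels.
#' @export
orderCycle <- function(order) {
  g <- orderedGenes(order)
  p <- which(g == min(g))[1L]
  n <- length(g)
  g[((seq_len(n) - 1L + p - 1L) %% n) + 1L]
}
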