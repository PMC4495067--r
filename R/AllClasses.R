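#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils read.csv read.delim write.csv combn
NULL

#' PhaseStudy: phase-angle observations across experiments and groups
#'
#' A \code{PhaseStudy} is a \linkS4class{SummarizedExperiment} holding one
#' assay, \code{"phase"}: an n-gene by P-experiment matrix of phase angles in
#' radians, canonicalized to \eqn{[0, 2\pi)}.  Counterclockwise is the
#' direction of temporal progression.  Column metadata carries, per
#' experiment, the group (e.g. species) label, the von Mises concentration
#' \eqn{\kappa_j} of its phase estimates, and the derived analysis weight
#' \eqn{\omega_j = \kappa_j / \sum_j \kappa_j} (normalized once over all P
#' experiments entering the study).
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#'
#' @seealso \code{\link{PhaseStudy}} (constructor),
#'   \code{\link{phaseAngles}}, \code{\link{estimateOrder}},
#'   \code{\link{testCommonOrder}}
#' @exportClass PhaseStudy
setClass("PhaseStudy", contains = "SummarizedExperiment")

.validPhaseStudy <- function(object) {
  msg <- character()
  if (!("phase" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'phase' is required")
  else {
    ph <- SummarizedExperiment::assay(object, "phase")
    if (!is.numeric(ph) || anyNA(ph) || any(!is.finite(ph)))
      msg <- c(msg, "phase angles must be finite numbers")
    else if (any(ph < 0) || any(ph >= 2 * pi))
      msg <- c(msg, "phase angles must be canonicalized to [0, 2*pi)")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("experiment_id", "group_id", "kappa", "weight")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  else {
    if (any(cd$kappa <= 0) || anyNA(cd$kappa))
      msg <- c(msg, "all kappa must be > 0")
    if (abs(sum(cd$weight) - 1) > 1e-8)
      msg <- c(msg, "experiment weights must sum to 1")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("PhaseStudy", .validPhaseStudy)

#' CircularOrder: a rotation-invariant cyclic arrangement of genes
#'
#' Stores a cyclic permutation \eqn{O = (o_1, \ldots, o_n)} of gene indices.
#' Two orders are equivalent iff one is a cyclic rotation of the other;
#' the stored representative is canonical (starts at the smallest gene
#' index), so \code{==} compares cyclic equivalence classes directly.
#' Reversal is \emph{not} an equivalence: the direction encodes temporal
#' progression (counterclockwise).
#'
#' @slot sequence integer permutation of \code{seq_len(n)}, canonical
#'   rotation (smallest index first).
#' @slot genes character vector of gene labels, aligned with gene indices
#'   \code{1..n} (i.e. \code{genes[i]} labels gene \code{i}, not position
#'   \code{i} of the cycle).
#'
#' @exportClass CircularOrder
setClass("CircularOrder",
         representation(sequence = "integer", genes = "character"))

setValidity("CircularOrder", function(object) {
  n <- length(object@sequence)
  msg <- character()
  if (!identical(sort(object@sequence), seq_len(n)))
    msg <- c(msg, "sequence must be a permutation of 1..n")
  else if (n > 0L && object@sequence[1L] != min(object@sequence))
    msg <- c(msg, "sequence must be in canonical rotation (smallest index first)")
  if (length(object@genes) != n)
    msg <- c(msg, "genes must have one label per gene")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene labels must be unique")
  if (length(msg)) msg else TRUE
})

#' CIREFit: a circular isotonic regression fit
#'
#' Order-constrained fitted angles for one experiment: the angle vector
#' closest to the observations in sum-of-circular-errors (SCE) subject to a
#' circular order constraint.  Fitted angles are constant on consecutive
#' level-set blocks; each block's shared angle is the circular mean of its
#' members' observed angles.
#'
#' @slot fitted numeric, fitted angles in \eqn{[0, 2\pi)}, by gene index.
#' @slot blocks integer, level-set block membership by gene index (block 1
#'   starts at the winning cut).
#' @slot sce the attained sum of circular errors.
#' @slot order the \linkS4class{CircularOrder} the fit was constrained to.
#' @slot cut the winning cut position (1-based, along the order sequence).
#'
#' @exportClass CIREFit
setClass("CIREFit",
         representation(fitted = "numeric", blocks = "integer",
                        sce = "numeric", order = "CircularOrder",
                        cut = "integer"))

#' OrderEstimate: an estimated common circular order
#'
#' @slot order the refined estimate (after circular local minimization).
#' @slot msce mean sum of circular errors of \code{order}.
#' @slot preRefinement the TSP tour before refinement.
#' @slot preMsce MSCE of the unrefined tour.
#' @slot solver \code{"exact"} (Held-Karp) or \code{"heuristic"}.
#' @slot alpha the clockwise travel penalty used for the cost matrix.
#'
#' @exportClass OrderEstimate
setClass("OrderEstimate",
         representation(order = "CircularOrder", msce = "numeric",
                        preRefinement = "CircularOrder", preMsce = "numeric",
                        solver = "character", alpha = "numeric"))

#' CommonOrderTest: resampling test of a common circular order
#'
#' @slot statistic observed value of the ANOVA-like statistic T.
#' @slot pValue resampling p-value, \code{(1 + #\{T_b >= T_obs\}) / (1 + B)}.
#' @slot B number of resamples.
#' @slot resampledStats the B resampled statistics.
#' @slot seed the RNG seed used.
#' @slot groupOrders list of per-group \linkS4class{OrderEstimate}s.
#' @slot globalOrder the pooled-data \linkS4class{OrderEstimate}.
#' @slot globalMSCE,withinMSCE the two variability terms of T.
#'
#' @exportClass CommonOrderTest
setClass("CommonOrderTest",
         representation(statistic = "numeric", pValue = "numeric",
                        B = "integer", resampledStats = "numeric",
                        seed = "integer", groupOrders = "list",
                        globalOrder = "OrderEstimate",
                        globalMSCE = "numeric", withinMSCE = "numeric"))

#' PartialOrderResult: a circular partial order with bootstrap confidence
#'
#' Blocks of tied genes arranged around the circle, produced by merging the
#' most frequent bootstrap orders that are coherent with the modal order,
#' together with the confidence coefficient (the summed relative frequency
#' of the merged orders).
#'
#' @slot blocks ordered list of character vectors (cyclic block sequence).
#' @slot confidence fraction in \eqn{[0, 1]}.
#' @slot frequencies data.frame with columns \code{order} (canonical cycle
#'   string) and \code{count}.
#' @slot includedOrders canonical strings of the orders merged into the
#'   partial order.
#' @slot threshold the relative-frequency threshold used for merging.
#' @slot total total number of resamples tabulated.
#' @slot modalOrder the most frequent simple order.
#'
#' @exportClass PartialOrderResult
setClass("PartialOrderResult",
         representation(blocks = "list", confidence = "numeric",
                        frequencies = "data.frame",
                        includedOrders = "character", threshold = "numeric",
                        total = "integer", modalOrder = "CircularOrder"))

#' SyntheticConfig: study conditions for the synthetic-data generator
#'
#' Describes a simulated study: n genes with true phases \eqn{\phi_i} on the
#' unit circle, S groups with \eqn{p_s} experiments each, per-experiment
#' observations \eqn{\theta_{ij}} drawn from the von Mises distribution
#' \eqn{M(\phi_i^{(s)}, \kappa_j)}, where \eqn{\phi^{(s)}} applies the
#' group's perturbation (none, swap, shift or shuffle).
#'
#' @slot nGenes number of genes.
#' @slot phases true phase angles, radians in \eqn{[0, 2\pi)}.
#' @slot groupSizes experiments per group, \eqn{p_1, \ldots, p_S}.
#' @slot kappas per-experiment von Mises concentrations (length P).
#' @slot perturbations list, one element per group: \code{NULL} or a list
#'   with \code{type} in \code{"swap"}, \code{"shift"}, \code{"shuffle"}.
#' @slot seed master RNG seed; split into one substream per experiment.
#' @slot genes,groupIds labels.
#'
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
         representation(nGenes = "integer", phases = "numeric",
                        groupSizes = "integer", kappas = "numeric",
                        perturbations = "list", seed = "integer",
                        genes = "character", groupIds = "character"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@phases) != object@nGenes)
    msg <- c(msg, "phases must have one angle per gene")
  if (any(object@groupSizes < 1L))
    msg <- c(msg, "each group needs at least one experiment")
  if (length(object@kappas) != sum(object@groupSizes))
    msg <- c(msg, "kappas must have one value per experiment")
  if (any(object@kappas <= 0))
    msg <- c(msg, "all kappas must be > 0")
  if (length(object@perturbations) != length(object@groupSizes))
    msg <- c(msg, "one perturbation entry (possibly NULL) per group")
  if (length(msg)) msg else TRUE
})

#' OperatingCharacteristics: rejection-rate summary of a simulation harness
#'
#' @slot nReps number of simulated studies.
#' @slot alphaLevel nominal test level.
#' @slot rejectionRate fraction of studies with p-value <= alphaLevel.
#' @slot standardError \code{sqrt(r * (1 - r) / nReps)}.
#' @slot pValues the per-replicate p-values.
#'
#' @exportClass OperatingCharacteristics
setClass("OperatingCharacteristics",
         representation(nReps = "integer", alphaLevel = "numeric",
                        rejectionRate = "numeric", standardError = "numeric",
                        pValues = "numeric"))

#' ForwardSelectionResult: outcome of the forward gene-selection procedure
#'
#' @slot genes gene labels of the selected subset (panel order).
#' @slot geneIndices indices into the study's panel.
#' @slot test the \linkS4class{CommonOrderTest} of the selected subset (the
#'   same resampling draw used during selection), or \code{NULL} when no
#'   seed triple passed.
#' @slot pathPValues p-values along the greedy path (seed triple first).
#' @slot alphaLevel,B,seed tuning echoed for provenance.
#' @slot rule short description of the (re-derived) greedy rule used.
#'
#' @exportClass ForwardSelectionResult
setClass("ForwardSelectionResult",
         representation(genes = "character", geneIndices = "integer",
                        test = "ANY", pathPValues = "numeric",
                        alphaLevel = "numeric", B = "integer",
                        seed = "integer", rule = "character"))
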