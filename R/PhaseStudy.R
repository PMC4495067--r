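#' Construct a PhaseStudy
#'
#' Assembles the full study object: an n-gene by P-experiment matrix of
#' phase angles plus per-experiment metadata (group label and von Mises
#' concentration \eqn{\kappa_j}).  Angles are canonicalized to
#' \eqn{[0, 2\pi)}; weights \eqn{\omega_j = \kappa_j / \sum \kappa_j} are
#' computed once over all experiments entering the study.
#'
#' @param phase numeric matrix, genes in rows, experiments in columns.
#'   Row names are gene ids (generated as \code{g1..gn} if absent).
#' @param groups group/species label per experiment (length P).
#' @param kappa positive von Mises concentration per experiment (length P,
#'   scalars recycled).
#' @param experimentIds experiment labels; default column names or
#'   \code{e1..eP}.
#' @param angleUnit \code{"radians"} (default) or \code{"degrees"};
#'   degree input is converted at this boundary only.
#' @return a \linkS4class{PhaseStudy}.
#' @examples
#' ph <- matrix(c(0, 1, 2, 0.1, 1.1, 2.1), nrow = 3,
#'              dimnames = list(c("gA", "gB", "gC"), NULL))
#' PhaseStudy(ph, groups = c("s1", "s1"), kappa = c(10, 20))
#' @export
PhaseStudy <- function(phase, groups, kappa,
                       experimentIds = colnames(phase),
                       angleUnit = c("radians", "degrees")) {
  angleUnit <- match.arg(angleUnit)
  phase <- as.matrix(phase)
  if (angleUnit == "degrees") phase <- phase * pi / 180
  phase <- wrapAngle(phase)
  P <- ncol(phase)
  if (length(groups) != P)
    stop("groups must have one label per experiment column")
  kappa <- rep_len(as.numeric(kappa), P)
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop("all kappa must be positive and finite")
  if (is.null(experimentIds)) experimentIds <- paste0("e", seq_len(P))
  if (is.null(rownames(phase)))
    rownames(phase) <- paste0("g", seq_len(nrow(phase)))
  colnames(phase) <- experimentIds
  cd <- S4Vectors::DataFrame(experiment_id = as.character(experimentIds),
                             group_id = as.character(groups),
                             kappa = kappa,
                             weight = weightsFromKappa(kappa),
                             row.names = experimentIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(phase = phase), colData = cd)
  new("PhaseStudy", se)
}

#' @describeIn PhaseStudy the n x P matrix of phase angles (radians).
#' @param x a \code{PhaseStudy}.
#' @export
setMethod("phaseAngles", "PhaseStudy", function(x)
  SummarizedExperiment::assay(x, "phase"))

#' @describeIn PhaseStudy gene ids (rownames).
#' @export
setMethod("geneIds", "PhaseStudy", function(x) rownames(x))

#' @describeIn PhaseStudy group label per experiment.
#' @export
setMethod("experimentGroups", "PhaseStudy", function(x)
  SummarizedExperiment::colData(x)$group_id)

#' @describeIn PhaseStudy von Mises concentration per experiment.
#' @export
setMethod("kappaValues", "PhaseStudy", function(x)
  SummarizedExperiment::colData(x)$kappa)

#' @describeIn PhaseStudy analysis weights (kappa-proportional, sum to 1).
#' @export
setMethod("experimentWeights", "PhaseStudy", function(x)
  SummarizedExperiment::colData(x)$weight)

setMethod("show", "PhaseStudy", function(object) {
  gr <- experimentGroups(object)
  cat("PhaseStudy: ", nrow(object), " genes x ", ncol(object),
      " experiments in ", length(unique(gr)), " group(s)\n", sep = "")
  cat("  groups: ",
      paste(sprintf("%s (%d)", unique(gr), as.integer(table(gr)[unique(gr)])),
            collapse = ", "), "\n", sep = "")
  cat("  kappa range: [", format(min(kappaValues(object)), digits = 4), ", ",
      format(max(kappaValues(object)), digits = 4), "]\n", sep = "")
})

## Integer group codes in order of first appearance (1..S).
.groupCodes <- function(study) {
  gr <- experimentGroups(study)
  match(gr, unique(gr))
}

.checkOrderPanel <- function(order, study) {
  if (length(order@sequence) != nrow(study))
    stop("order is not over the study's gene panel")
  if (!identical(order@genes, geneIds(study)))
    stop("order gene labels do not match the study's panel")
  invisible(TRUE)
}
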