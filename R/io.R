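## Readers/writers for phase-angle tables and versioned JSON reports.

.REPORT_SCHEMA <- "phaseOrder-report/1.0"

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.parseError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phaseOrderParseError",
                                     "error", "condition")))
}

#' Read a study from a phase table and an experiment-metadata table
#'
#' The phase table (CSV or TSV by extension) has gene ids in the first
#' column and one column of phase angles per experiment.  The metadata
#' table has columns \code{experiment_id}, \code{group_id} and
#' \code{kappa}.  The angle unit is declared, never guessed; degrees are
#' converted at this boundary.
#'
#' Parse failures raise distinct, named conditions (all subclasses of
#' \code{phaseOrderParseError}): \code{phaseOrderDuplicateGeneError},
#' \code{phaseOrderNonNumericError}, \code{phaseOrderMetadataMismatchError}
#' and \code{phaseOrderKappaError}.
#'
#' @param phasePath path to the gene x experiment phase table.
#' @param metadataPath path to the experiment metadata table.
#' @param angleUnit \code{"radians"} (default) or \code{"degrees"}.
#' @param estimateKappaIfMissing when TRUE, a missing/NA \code{kappa}
#'   column is filled with \code{\link{estimateKappa}} applied to each
#'   experiment's residuals about the per-gene circular means; otherwise
#'   missing kappa is a parse error.
#' @return a \linkS4class{PhaseStudy}.
#' @export
readStudy <- function(phasePath, metadataPath,
                      angleUnit = c("radians", "degrees"),
                      estimateKappaIfMissing = FALSE) {
  angleUnit <- match.arg(angleUnit)
  ph <- .readTable(phasePath)
  md <- .readTable(metadataPath)
  genes <- as.character(ph[[1L]])
  if (anyDuplicated(genes))
    .parseError(paste0("duplicate gene ids: ",
                       paste(unique(genes[duplicated(genes)]),
                             collapse = ", ")),
                "phaseOrderDuplicateGeneError")
  cols <- ph[, -1L, drop = FALSE]
  if (!all(vapply(cols, is.numeric, logical(1L))) || anyNA(cols))
    .parseError("non-numeric phase cells", "phaseOrderNonNumericError")
  mat <- as.matrix(cols)
  rownames(mat) <- genes
  need <- c("experiment_id", "group_id")
  if (!all(need %in% colnames(md)))
    .parseError("metadata must have experiment_id and group_id columns",
                "phaseOrderMetadataMismatchError")
  missing <- setdiff(colnames(mat), md$experiment_id)
  if (length(missing))
    .parseError(paste0("experiments without metadata: ",
                       paste(missing, collapse = ", ")),
                "phaseOrderMetadataMismatchError")
  unknown <- setdiff(md$experiment_id, colnames(mat))
  if (length(unknown))
    .parseError(paste0("metadata for unknown experiments: ",
                       paste(unknown, collapse = ", ")),
                "phaseOrderMetadataMismatchError")
  md <- md[match(colnames(mat), md$experiment_id), , drop = FALSE]
  kap <- if ("kappa" %in% colnames(md)) suppressWarnings(as.numeric(md$kappa))
         else rep(NA_real_, nrow(md))
  if (anyNA(kap)) {
    if (!estimateKappaIfMissing)
      .parseError("missing kappa (supply it or set estimateKappaIfMissing)",
                  "phaseOrderKappaError")
    rad <- if (angleUnit == "degrees") mat * pi / 180 else mat
    center <- apply(rad, 1L, circularMean)
    kap[is.na(kap)] <- vapply(which(is.na(kap)), function(j)
      estimateKappa(rad[, j] - center), numeric(1L))
  }
  if (any(kap <= 0))
    .parseError("kappa must be positive for every experiment",
                "phaseOrderKappaError")
  message("readStudy: ", nrow(mat), " genes, ",
          length(unique(md$group_id)), " group(s), ", ncol(mat),
          " experiments (", angleUnit, ")")
  PhaseStudy(mat, groups = md$group_id, kappa = kap,
             experimentIds = colnames(mat), angleUnit = angleUnit)
}

#' @describeIn readStudy Write a study back to the same two-table format
#'   (losslessly round-trips with \code{readStudy} up to numeric printing).
#' @param study a \linkS4class{PhaseStudy}.
#' @param ... unused.
#' @export
setMethod("writeStudy", "PhaseStudy",
          function(study, phasePath, metadataPath,
                   angleUnit = c("radians", "degrees"), ...) {
  angleUnit <- match.arg(angleUnit)
  mat <- phaseAngles(study)
  if (angleUnit == "degrees") mat <- mat * 180 / pi
  sep <- if (grepl("\\.(tsv|txt)$", phasePath, ignore.case = TRUE)) "\t" else ","
  ph <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(ph, phasePath, sep = sep, row.names = FALSE,
                     quote = FALSE)
  md <- data.frame(experiment_id = colnames(mat),
                   group_id = experimentGroups(study),
                   kappa = kappaValues(study))
  utils::write.table(md, metadataPath, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(c(phasePath, metadataPath))
})

## ---- versioned JSON reports -----------------------------------------------

.blockList <- function(blocks) lapply(blocks, as.list)

#' @describeIn orderReport report for an estimated order.
#' @param object the result object to serialize.
#' @param ... unused.
#' @return a list ready for JSON serialization (schema
#'   \code{phaseOrder-report/1.0}); orders appear as canonical gene-id
#'   cycles starting at the lexicographically smallest gene.
#' @export
setMethod("orderReport", "OrderEstimate", function(object, ...) {
  list(schema = .REPORT_SCHEMA, type = "order_estimate",
       order = as.list(orderCycle(object@order)),
       msce = object@msce,
       pre_refinement_order = as.list(orderCycle(object@preRefinement)),
       pre_refinement_msce = object@preMsce,
       solver = object@solver, alpha = object@alpha)
})

#' @describeIn orderReport report for a common-order test.
#' @export
setMethod("orderReport", "CommonOrderTest", function(object, ...) {
  list(schema = .REPORT_SCHEMA, type = "common_order_test",
       statistic = object@statistic, p_value = object@pValue,
       B = object@B, seed = object@seed,
       global = orderReport(object@globalOrder),
       groups = lapply(object@groupOrders, orderReport),
       global_msce = object@globalMSCE, within_msce = object@withinMSCE)
})

#' @describeIn orderReport report for a partial order with confidence.
#' @export
setMethod("orderReport", "PartialOrderResult", function(object, ...) {
  list(schema = .REPORT_SCHEMA, type = "partial_order",
       blocks = .blockList(object@blocks),
       confidence = object@confidence,
       threshold = object@threshold, total = object@total,
       frequencies = object@frequencies,
       included_orders = as.list(object@includedOrders))
})

#' @describeIn orderReport report for a forward-selection result.
#' @export
setMethod("orderReport", "ForwardSelectionResult", function(object, ...) {
  list(schema = .REPORT_SCHEMA, type = "forward_selection",
       genes = as.list(object@genes), rule = object@rule,
       alpha_level = object@alphaLevel, B = object@B, seed = object@seed,
       path_p_values = object@pathPValues,
       test = if (is.null(object@test)) NULL else orderReport(object@test))
})

#' Write a result object as a versioned JSON report
#'
#' @param object any object with an \code{\link{orderReport}} method.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReport <- function(object, path) {
  jsonlite::write_json(orderReport(object), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
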