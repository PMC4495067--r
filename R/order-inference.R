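## Testing conservation of the circular order across groups: the ANOVA-like
## statistic T, the weighted resampling scheme, partial-order confidence
## aggregation, and forward gene selection.

## One weighted resampling draw of column indices: a group is picked
## uniformly (1/S), then an experiment uniformly within it (1/p_s), so each
## experiment of group s has selection probability 1/(S * p_s); P draws with
## replacement.
.drawResampleIdx <- function(groupCodes) {
  S <- max(groupCodes)
  P <- length(groupCodes)
  idx <- integer(P)
  for (k in seq_len(P)) {
    s <- sample.int(S, 1L)
    pool <- which(groupCodes == s)
    idx[k] <- pool[sample.int(length(pool), 1L)]
  }
  idx
}

## T for one resampling draw (consumes the current RNG stream).
.resampleT <- function(Theta, kappa, groupCodes, alpha, nExact, maxSweeps) {
  idx <- .drawResampleIdx(groupCodes)
  wb <- kappa[idx] / sum(kappa[idx])
  assign <- rep.int(seq_len(max(groupCodes)), tabulate(groupCodes))
  cpp_T_stat(Theta[, idx, drop = FALSE], wb, assign, alpha,
             as.integer(nExact), as.integer(maxSweeps), FALSE)$T
}

.asOrderEstimate <- function(lst, genes, alpha) {
  new("OrderEstimate",
      order = CircularOrder(lst$order + 1L, genes),
      msce = as.numeric(lst$msce),
      preRefinement = CircularOrder(lst$order0 + 1L, genes),
      preMsce = as.numeric(lst$msce0),
      solver = if (isTRUE(lst$exact)) "exact" else "heuristic",
      alpha = alpha)
}

#' ANOVA-like statistic for comparing circular orders
#'
#' \deqn{T = \frac{d(\Theta_{(.)}, \tilde O^*) - \sum_s d(\Theta_{(s)},
#' \tilde O_s)}{d(\Theta_{(.)}, \tilde O^*)}}
#' where \eqn{d} is the weighted MSCE, \eqn{\tilde O^*} the order estimated
#' from all experiments pooled (the analogue of global variability) and
#' \eqn{\tilde O_s} the per-group estimates (within-group variability).
#' Weights are normalized once over all P experiments and used as-is in both
#' terms, which guarantees \eqn{T \in [0, 1]} when the orders are optimized
#' exactly; any heuristic-solver slack below 0 is clamped.  Larger T is
#' stronger evidence against a common order; \eqn{T = 0} by convention when
#' the global fit is perfect.
#'
#' @param study a \linkS4class{PhaseStudy}.
#' @param groupOrders list of per-group orders (\linkS4class{CircularOrder}
#'   or \linkS4class{OrderEstimate}), in order of first appearance of the
#'   group labels.
#' @param globalOrder the pooled-data order.
#' @return T, a scalar in \eqn{[0, 1]}.
#' @export
testStatistic <- function(study, groupOrders, globalOrder) {
  unwrapOrder <- function(o) if (is(o, "OrderEstimate")) o@order else o
  gOrd <- unwrapOrder(globalOrder)
  .checkOrderPanel(gOrd, study)
  Theta <- phaseAngles(study)
  w <- experimentWeights(study)
  gc <- .groupCodes(study)
  S <- max(gc)
  if (length(groupOrders) != S)
    stop("need one group order per group")
  dG <- cpp_msce(Theta, w, gOrd@sequence - 1L)
  dW <- 0
  for (s in seq_len(S)) {
    cols <- which(gc == s)
    os <- unwrapOrder(groupOrders[[s]])
    .checkOrderPanel(os, study)
    dW <- dW + cpp_msce(Theta[, cols, drop = FALSE], w[cols],
                        os@sequence - 1L)
  }
  if (dG <= 1e-12) return(0)
  max(0, (dG - dW) / dG)
}

#' @describeIn resampleStudy Draw one artificial study under the weighted
#'   resampling scheme: P experiments are drawn i.i.d. with replacement
#'   (group uniform at 1/S, experiment uniform within group at 1/p_s, so
#'   each experiment of group s has probability 1/(S p_s) per draw); the
#'   first \eqn{p_1} draws become artificial group 1, the next \eqn{p_2}
#'   artificial group 2, and so on.  Weights are recomputed from the drawn
#'   experiments' kappa.
#' @param study a \linkS4class{PhaseStudy}.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   first (otherwise the current RNG stream is consumed).
#' @param ... unused.
#' @return a new \linkS4class{PhaseStudy} with the original group sizes.
#' @export
setMethod("resampleStudy", "PhaseStudy", function(study, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gc <- .groupCodes(study)
  idx <- .drawResampleIdx(gc)
  glv <- unique(experimentGroups(study))
  PhaseStudy(phaseAngles(study)[, idx, drop = FALSE],
             groups = rep(glv, times = tabulate(gc)),
             kappa = kappaValues(study)[idx],
             experimentIds = make.unique(colnames(study)[idx], sep = "_r"))
})

#' @describeIn testCommonOrder Test the null hypothesis that all groups
#'   share one circular order.  The observed T compares the pooled-data
#'   order with the per-group orders; its null distribution is approximated
#'   by B weighted resamples (see \code{\link{resampleStudy}}), and
#'   \eqn{p = (1 + \#\{T_b \ge T_{obs}\}) / (1 + B)}.  Fully reproducible
#'   given \code{seed}.
#' @param study a \linkS4class{PhaseStudy} with at least 2 groups.
#' @param B number of resamples (default 1000).
#' @param seed integer RNG seed.
#' @param alpha clockwise travel penalty (default 3).
#' @param nExact exact-TSP threshold.
#' @param maxSweeps local-minimization sweep cap.
#' @param ... unused.
#' @return a \linkS4class{CommonOrderTest}.
#' @export
setMethod("testCommonOrder", "PhaseStudy",
          function(study, B = 1000L, seed = 1L, alpha = 3, nExact = 15L,
                   maxSweeps = 50L, ...) {
  if (length(unique(experimentGroups(study))) < 2L)
    stop("need at least 2 groups to compare orders")
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  Theta <- phaseAngles(study)
  w <- experimentWeights(study)
  kappa <- kappaValues(study)
  gc <- .groupCodes(study)
  det <- cpp_T_stat(Theta, w, gc, alpha, as.integer(nExact),
                    as.integer(maxSweeps), TRUE)
  set.seed(seed)
  Tb <- vapply(seq_len(B), function(b)
    .resampleT(Theta, kappa, gc, alpha, nExact, maxSweeps), numeric(1L))
  genes <- geneIds(study)
  glv <- unique(experimentGroups(study))
  groupOrders <- lapply(det$groups, .asOrderEstimate, genes = genes,
                        alpha = alpha)
  names(groupOrders) <- glv
  new("CommonOrderTest",
      statistic = as.numeric(det$T),
      pValue = (1 + sum(Tb >= det$T)) / (1 + B),
      B = B, resampledStats = Tb, seed = as.integer(seed),
      groupOrders = groupOrders,
      globalOrder = .asOrderEstimate(det$global, genes, alpha),
      globalMSCE = as.numeric(det$dGlobal),
      withinMSCE = as.numeric(det$dWithin))
})

setMethod("show", "CommonOrderTest", function(object) {
  cat("Common circular order test (weighted resampling)\n")
  cat("  T = ", format(object@statistic, digits = 5),
      ", p = ", format(object@pValue, digits = 5),
      "  (B = ", object@B, ", seed = ", object@seed, ")\n", sep = "")
  cat("  global order: ",
      paste(orderCycle(object@globalOrder@order), collapse = " -> "),
      " -> ...\n", sep = "")
})

## ---- partial-order aggregation --------------------------------------------

.mergeTwoBlocks <- function(blocks, i, j) {
  lo <- min(i, j)
  hi <- max(i, j)
  blocks[[lo]] <- c(blocks[[lo]], blocks[[hi]])
  blocks[[hi]] <- NULL
  blocks
}

## Reconcile a candidate simple order with the current cyclic block
## sequence: repeatedly merge the offending adjacent blocks until the
## candidate collapses onto the block sequence exactly, or everything would
## collapse into a single block (rejected, NULL).
.mergeCandidate <- function(blocks, candGenes) {
  repeat {
    m <- length(blocks)
    if (m <= 1L) return(NULL)
    map <- setNames(rep(seq_len(m), lengths(blocks)), unlist(blocks))
    ids <- unname(map[candGenes])
    r <- rle(ids)$values
    if (length(r) > 1L && r[1L] == r[length(r)]) r <- r[-length(r)]
    if (anyDuplicated(r)) {
      b <- r[duplicated(r)][1L]
      pos <- which(r == b)[1L]
      blocks <- .mergeTwoBlocks(blocks, b, r[pos + 1L])
      next
    }
    p <- which(r == 1L)
    rot <- r[((seq_along(r) - 1L + p - 1L) %% length(r)) + 1L]
    if (identical(rot, seq_len(m))) return(blocks)
    t <- which(rot != seq_len(m))[1L]
    blocks <- .mergeTwoBlocks(blocks, rot[t], t)
  }
}

## Rotate the cyclic block list so the block holding the lexicographically
## smallest gene comes first (serialization convention).
.rotateBlocks <- function(blocks) {
  allg <- unlist(blocks)
  first <- min(allg)
  p <- which(vapply(blocks, function(b) first %in% b, logical(1L)))[1L]
  m <- length(blocks)
  blocks[((seq_len(m) - 1L + p - 1L) %% m) + 1L]
}

#' Aggregate bootstrap order frequencies into a partial order
#'
#' Seeds the partial order with the modal (most frequent) simple order, then
#' scans the remaining orders in decreasing frequency.  An order is merged
#' iff its relative frequency is at least \code{freqThreshold} and it is
#' coherent with the current blocks: its minimal disagreeing adjacent
#' segments are pooled into tied blocks, and the merge is kept only when
#' both orders become identical after collapsing each block to a single
#' element (a merge that would pool everything into one block is rejected).
#' The confidence coefficient is the summed relative frequency of the
#' merged orders.
#'
#' @param orders list of \linkS4class{CircularOrder}s over one gene panel.
#' @param counts nonnegative counts, one per order.
#' @param freqThreshold relative-frequency threshold in \eqn{(0, 1]}
#'   (default 0.10).
#' @param total total number of resamples (default \code{sum(counts)};
#'   pass explicitly when some resamples are excluded upstream).
#' @return a \linkS4class{PartialOrderResult}.
#' @examples
#' A <- CircularOrder(c(1, 3, 4, 5, 2))
#' B <- CircularOrder(c(1, 3, 4, 2, 5))
#' aggregateOrderFrequencies(list(A, B), c(600, 300), total = 1000)
#' @export
aggregateOrderFrequencies <- function(orders, counts, freqThreshold = 0.10,
                                      total = sum(counts)) {
  if (length(orders) != length(counts) || !length(orders))
    stop("need one count per order")
  if (freqThreshold <= 0 || freqThreshold > 1)
    stop("freqThreshold must be in (0, 1]")
  genes <- orders[[1L]]@genes
  keys <- vapply(orders, function(o) paste(orderedGenes(o), collapse = " -> "),
                 character(1L))
  if (anyDuplicated(keys)) stop("orders must be distinct")
  o <- order(-counts, keys)
  orders <- orders[o]
  counts <- counts[o]
  keys <- keys[o]

  modal <- orders[[1L]]
  blocks <- as.list(orderedGenes(modal))
  included <- 1L
  for (i in seq_along(orders)[-1L]) {
    if (counts[i] / total < freqThreshold) next
    merged <- .mergeCandidate(blocks, orderedGenes(orders[[i]]))
    if (!is.null(merged)) {
      blocks <- merged
      included <- c(included, i)
    }
  }
  new("PartialOrderResult",
      blocks = .rotateBlocks(blocks),
      confidence = sum(counts[included]) / total,
      frequencies = data.frame(order = keys, count = as.numeric(counts),
                               stringsAsFactors = FALSE),
      includedOrders = keys[included],
      threshold = freqThreshold,
      total = as.integer(total),
      modalOrder = modal)
}

setMethod("show", "PartialOrderResult", function(object) {
  fmt <- vapply(object@blocks, function(b)
    if (length(b) == 1L) b else paste0("{", paste(b, collapse = ", "), "}"),
    character(1L))
  cat("Partial circular order: ", paste(fmt, collapse = " -> "),
      " -> ...\n  confidence = ", format(100 * object@confidence,
                                         digits = 4),
      "% of ", object@total, " resamples (threshold ",
      object@threshold, ")\n", sep = "")
})

#' @describeIn confidencePartialOrder Estimate the global order on each of B
#'   weighted resamples, tabulate the canonical order frequencies, and
#'   aggregate them into a partial order with a confidence coefficient via
#'   \code{\link{aggregateOrderFrequencies}}.
#' @param study a \linkS4class{PhaseStudy}.
#' @param B number of resamples.
#' @param seed integer RNG seed.
#' @param freqThreshold merge threshold on relative frequency.
#' @param alpha clockwise travel penalty.
#' @param nExact exact-TSP threshold.
#' @param maxSweeps local-minimization sweep cap.
#' @param ... unused.
#' @return a \linkS4class{PartialOrderResult}.
#' @export
setMethod("confidencePartialOrder", "PhaseStudy",
          function(study, B = 1000L, seed = 1L, freqThreshold = 0.10,
                   alpha = 3, nExact = 15L, maxSweeps = 50L, ...) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  Theta <- phaseAngles(study)
  kappa <- kappaValues(study)
  gc <- .groupCodes(study)
  genes <- geneIds(study)
  set.seed(seed)
  keys <- character(B)
  for (b in seq_len(B)) {
    idx <- .drawResampleIdx(gc)
    wb <- kappa[idx] / sum(kappa[idx])
    est <- cpp_estimate_order(Theta[, idx, drop = FALSE], wb, alpha,
                              as.integer(nExact), as.integer(maxSweeps))
    keys[b] <- .orderKey(est$order + 1L)
  }
  tab <- table(keys)
  orders <- lapply(names(tab), function(k)
    CircularOrder(.keyToSequence(k), genes))
  aggregateOrderFrequencies(orders, as.integer(tab),
                            freqThreshold = freqThreshold, total = B)
})

## ---- forward gene selection -----------------------------------------------

#' @describeIn forwardSelection Greedy forward search for a maximum-size
#'   gene subset sharing a common order across groups.  All
#'   \eqn{\binom{n}{3}} gene triples are tested first; greedy completions
#'   are then run from the passing triples in decreasing p-value order
#'   (up to \code{maxSeeds} seeds), each completion adding, one at a time,
#'   the candidate gene that maximizes the p-value as long as that p-value
#'   stays at or above \code{alphaLevel}.  The largest subset found wins
#'   (ties: larger final p, then earlier seed); the search stops early when
#'   a completion covers the whole panel.  Multiple seeds matter because
#'   concordant data tie many triples at p = 1, and a single seed can stall
#'   below the maximal subset.  The returned subset passes the test at
#'   \code{alphaLevel} by construction.  (The greedy rule is this package's
#'   own operationalization and is recorded in the result.)
#' @param study a \linkS4class{PhaseStudy} with n >= 4 genes and >= 2 groups.
#' @param alphaLevel level in \eqn{(0, 1]} a subset must attain to be kept.
#' @param B resamples per test.
#' @param seed integer RNG seed (one stream drives the whole search; each
#'   distinct subset is tested once and cached).
#' @param alpha clockwise travel penalty.
#' @param nExact exact-TSP threshold.
#' @param maxSweeps local-minimization sweep cap.
#' @param maxSeeds number of seed triples to complete (default 10).
#' @param ... unused.
#' @return a \linkS4class{ForwardSelectionResult}; empty (with a message)
#'   when no triple attains \code{alphaLevel}.
#' @export
setMethod("forwardSelection", "PhaseStudy",
          function(study, alphaLevel = 0.05, B = 1000L, seed = 1L,
                   alpha = 3, nExact = 15L, maxSweeps = 50L,
                   maxSeeds = 10L, ...) {
  n <- nrow(study)
  if (n < 4L) stop("need at least 4 genes for forward selection")
  if (alphaLevel <= 0 || alphaLevel > 1)
    stop("alphaLevel must be in (0, 1]")
  if (length(unique(experimentGroups(study))) < 2L)
    stop("need at least 2 groups")
  B <- as.integer(B)
  Theta <- phaseAngles(study)
  w <- experimentWeights(study)
  kappa <- kappaValues(study)
  gc <- .groupCodes(study)
  assign <- rep.int(seq_len(max(gc)), tabulate(gc))
  rule <- "multi-seed greedy: best-p triples, max-p additions"

  cache <- new.env(parent = emptyenv())
  evalSubset <- function(idx) {
    key <- paste(idx, collapse = ".")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    Th <- Theta[idx, , drop = FALSE]
    Tobs <- cpp_T_stat(Th, w, gc, alpha, as.integer(nExact),
                       as.integer(maxSweeps), FALSE)$T
    Tb <- vapply(seq_len(B), function(b) {
      ridx <- .drawResampleIdx(gc)
      wb <- kappa[ridx] / sum(kappa[ridx])
      cpp_T_stat(Th[, ridx, drop = FALSE], wb, assign, alpha,
                 as.integer(nExact), as.integer(maxSweeps), FALSE)$T
    }, numeric(1L))
    res <- list(p = (1 + sum(Tb >= Tobs)) / (1 + B), Tobs = Tobs, Tb = Tb)
    cache[[key]] <- res
    res
  }

  set.seed(seed)
  triples <- combn(n, 3L)
  tripleP <- vapply(seq_len(ncol(triples)), function(t)
    evalSubset(triples[, t])$p, numeric(1L))
  if (max(tripleP) < alphaLevel) {
    message("forward selection: no gene triple attains alphaLevel = ",
            alphaLevel, " (best p = ", format(max(tripleP), digits = 4),
            ")")
    return(new("ForwardSelectionResult", genes = character(),
               geneIndices = integer(), test = NULL,
               pathPValues = max(tripleP), alphaLevel = alphaLevel, B = B,
               seed = as.integer(seed), rule = rule))
  }
  seedOrder <- order(-tripleP, seq_len(ncol(triples)))
  seedOrder <- seedOrder[tripleP[seedOrder] >= alphaLevel]
  seedOrder <- seedOrder[seq_len(min(length(seedOrder),
                                     as.integer(maxSeeds)))]

  complete <- function(startIdx, startP) {
    sel <- sort(startIdx)
    selRes <- evalSubset(sel)
    path <- startP
    repeat {
      cands <- setdiff(seq_len(n), sel)
      if (!length(cands)) break
      candP <- -1
      candRes <- NULL
      candG <- NULL
      for (g in cands) {
        r <- evalSubset(sort(c(sel, g)))
        if (r$p > candP + 1e-15) {
          candP <- r$p
          candRes <- r
          candG <- g
        }
      }
      if (candP < alphaLevel) break
      sel <- sort(c(sel, candG))
      selRes <- candRes
      path <- c(path, candP)
    }
    list(sel = sel, res = selRes, path = path)
  }

  best <- NULL
  for (t in seedOrder) {
    run <- complete(triples[, t], tripleP[t])
    if (is.null(best) ||
        length(run$sel) > length(best$sel) ||
        (length(run$sel) == length(best$sel) &&
         run$res$p > best$res$p + 1e-15))
      best <- run
    if (length(best$sel) == n) break
  }
  sel <- best$sel
  selRes <- best$res
  path <- best$path

  ## detailed observed part is deterministic; reuse the selection's
  ## resampled statistics so the recorded test is the one used to select
  sub <- study[sel, ]
  det <- cpp_T_stat(Theta[sel, , drop = FALSE], w, gc, alpha,
                    as.integer(nExact), as.integer(maxSweeps), TRUE)
  genes <- geneIds(sub)
  glv <- unique(experimentGroups(study))
  groupOrders <- lapply(det$groups, .asOrderEstimate, genes = genes,
                        alpha = alpha)
  names(groupOrders) <- glv
  test <- new("CommonOrderTest", statistic = as.numeric(det$T),
              pValue = selRes$p, B = B, resampledStats = selRes$Tb,
              seed = as.integer(seed), groupOrders = groupOrders,
              globalOrder = .asOrderEstimate(det$global, genes, alpha),
              globalMSCE = as.numeric(det$dGlobal),
              withinMSCE = as.numeric(det$dWithin))
  new("ForwardSelectionResult", genes = genes,
      geneIndices = as.integer(sel), test = test, pathPValues = path,
      alphaLevel = alphaLevel, B = B, seed = as.integer(seed),
      rule = rule)
})

setMethod("show", "ForwardSelectionResult", function(object) {
  cat("Forward selection (", object@rule, ")\n", sep = "")
  if (!length(object@genes)) {
    cat("  no subset attains alphaLevel = ", object@alphaLevel, "\n",
        sep = "")
  } else {
    cat("  selected ", length(object@genes), " genes: ",
        paste(object@genes, collapse = ", "), "\n  final p = ",
        format(object@test@pValue, digits = 4), " (alphaLevel = ",
        object@alphaLevel, ", B = ", object@B, ")\n", sep = "")
  }
})
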