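## Synthetic-data generation with the statistical structure the method
## assumes (von Mises phase observations around gene-specific mean
## directions), plus type-I-error / power harnesses.

#' Draw from the von Mises distribution
#'
#' Best-Fisher rejection sampling from \eqn{M(\mu, \kappa)}; reduces to the
#' circular uniform as \eqn{\kappa \to 0}.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return angles in \eqn{[0, 2\pi)}.
#' @examples
#' set.seed(1)
#' rvonmises(5, pi, 10)
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3L)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3L] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrapAngle(out)
}

#' Describe a synthetic study
#'
#' Fixes the study conditions for \code{\link{simulateStudy}}: n genes with
#' true phases on the unit circle (default equally spaced -- the
#' well-separated case), S groups of experiments, per-experiment von Mises
#' concentrations, and an optional per-group perturbation of the true
#' phases: \code{list(type = "swap", genes = c(i, j))} exchanges two genes'
#' phases, \code{list(type = "shift", gene = i, delta = d)} moves one phase
#' by \code{d} radians, and \code{list(type = "shuffle", gene = i)} replaces
#' one gene's phase with a uniform random angle (drawn once per group from
#' its own substream).
#'
#' @param nGenes number of genes.
#' @param groupSizes integer vector \eqn{p_1, \ldots, p_S}.
#' @param kappas per-experiment concentrations (scalar recycled to P).
#' @param phases true phases (radians); default \code{2*pi*(0:(n-1))/n}.
#' @param perturbations \code{NULL} (no group perturbed) or a list with one
#'   element per group (\code{NULL} or a perturbation spec as above).
#' @param seed master seed; split into one substream per experiment so that
#'   one group's draws do not depend on another group's configuration.
#' @param genes,groupIds labels (defaults \code{g1..gn}, \code{s1..sS}).
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nGenes, groupSizes, kappas, phases = NULL,
                            perturbations = NULL, seed = 1L,
                            genes = paste0("g", seq_len(nGenes)),
                            groupIds = paste0("s", seq_along(groupSizes))) {
  nGenes <- as.integer(nGenes)
  groupSizes <- as.integer(groupSizes)
  P <- sum(groupSizes)
  if (is.null(phases)) phases <- 2 * pi * (seq_len(nGenes) - 1L) / nGenes
  if (is.null(perturbations))
    perturbations <- vector("list", length(groupSizes))
  new("SyntheticConfig", nGenes = nGenes, phases = wrapAngle(phases),
      groupSizes = groupSizes, kappas = rep_len(as.numeric(kappas), P),
      perturbations = perturbations, seed = as.integer(seed),
      genes = as.character(genes), groupIds = as.character(groupIds))
}

#' @describeIn syntheticConfig the cyclic arrangement of the configured
#'   true phases (the generating order).
#' @param config a \linkS4class{SyntheticConfig}.
#' @export
trueOrder <- function(config) {
  CircularOrder(order(config@phases), config@genes)
}

.applyPerturbation <- function(phases, pert, groupSeed) {
  if (is.null(pert)) return(phases)
  switch(pert$type,
    swap = {
      ij <- pert$genes
      phases[ij] <- phases[rev(ij)]
      phases
    },
    shift = {
      phases[pert$gene] <- wrapAngle(phases[pert$gene] + pert$delta)
      phases
    },
    shuffle = {
      ## redraw the gene's phase uniformly among cyclic positions displaced
      ## from the original by at least one full slot on either side.  A draw
      ## landing back in its own arc would leave the circular order intact
      ## (the "alternative" would silently be the null), and a draw in a
      ## segment adjacent to the original arc creates a planted gene that is
      ## not identifiable even in principle: removing either of two genes
      ## restores a common order.  With fewer than 5 genes only the
      ## position-change condition can be enforced.
      i <- pert$gene
      r <- sort(wrapAngle(phases[-i] - phases[i]))
      m <- length(r)
      if (m >= 4L) {
        lo <- r[2L]
        hi <- r[m - 1L]
      } else {
        lo <- r[1L]
        hi <- r[m]
      }
      old <- get(".Random.seed", envir = globalenv())
      set.seed(groupSeed)
      repeat {
        u <- runif(1L, 0, 2 * pi)
        rel <- wrapAngle(u - phases[i])
        if (rel > lo && rel < hi) break
      }
      assign(".Random.seed", old, envir = globalenv())
      phases[i] <- u
      phases
    },
    stop("unknown perturbation type: ", pert$type))
}

#' Simulate a study from a synthetic configuration
#'
#' Each experiment j of group s draws its gene angles independently as
#' \eqn{\theta_{ij} \sim M(\phi_i^{(s)}, \kappa_j)}, where
#' \eqn{\phi^{(s)}} is the group's (possibly perturbed) phase vector.
#' Sampling is organized as \eqn{\phi^{(s)}} plus zero-mean von Mises
#' noise from a per-experiment substream, so identical seeds give
#' bitwise-identical studies and perturbing one group leaves the other
#' groups' data unchanged.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{PhaseStudy}.
#' @examples
#' simulateStudy(syntheticConfig(nGenes = 5, groupSizes = c(4, 4),
#'                               kappas = 20, seed = 11))
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  S <- length(config@groupSizes)
  P <- sum(config@groupSizes)
  n <- config@nGenes
  set.seed(config@seed)
  expSeeds <- sample.int(.Machine$integer.max, P)
  groupSeeds <- sample.int(.Machine$integer.max, S)
  groupOf <- rep.int(seq_len(S), config@groupSizes)
  theta <- matrix(0, n, P, dimnames = list(config@genes, NULL))
  for (j in seq_len(P)) {
    s <- groupOf[j]
    phi <- .applyPerturbation(config@phases, config@perturbations[[s]],
                              groupSeeds[s])
    set.seed(expSeeds[j])
    theta[, j] <- wrapAngle(phi + rvonmises(n, 0, config@kappas[j]))
  }
  PhaseStudy(theta, groups = config@groupIds[groupOf],
             kappa = config@kappas,
             experimentIds = paste0("e", seq_len(P)))
}

.runOperatingCharacteristics <- function(config, nReps, B, alphaLevel,
                                         seed, ...) {
  nReps <- as.integer(nReps)
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max %/% 2L, nReps)
  testSeeds <- sample.int(.Machine$integer.max %/% 2L, nReps)
  pv <- numeric(nReps)
  for (r in seq_len(nReps)) {
    cfg <- config
    cfg@seed <- repSeeds[r]
    study <- simulateStudy(cfg)
    pv[r] <- testCommonOrder(study, B = B, seed = testSeeds[r], ...)@pValue
  }
  rate <- mean(pv <= alphaLevel)
  new("OperatingCharacteristics", nReps = nReps,
      alphaLevel = as.numeric(alphaLevel), rejectionRate = rate,
      standardError = sqrt(rate * (1 - rate) / nReps), pValues = pv)
}

#' Type-I error of the common-order test under a null configuration
#'
#' Simulates \code{nReps} fresh studies from \code{config} (which must have
#' no perturbation, so the null of a common order holds), runs
#' \code{\link{testCommonOrder}} with B resamples on each, and reports the
#' rejection rate at \code{alphaLevel} with its Monte-Carlo standard error
#' \eqn{\sqrt{r(1-r)/\mathrm{nReps}}}.
#'
#' @param config a null \linkS4class{SyntheticConfig} (no perturbations).
#' @param nReps number of simulated studies.
#' @param B resamples per test.
#' @param alphaLevel nominal level (default 0.05).
#' @param seed master seed for the harness.
#' @param ... passed to \code{\link{testCommonOrder}}.
#' @return an \linkS4class{OperatingCharacteristics}.
#' @export
type1Error <- function(config, nReps = 200L, B = 200L, alphaLevel = 0.05,
                       seed = 1L, ...) {
  if (!all(vapply(config@perturbations, is.null, logical(1L))))
    stop("type-I error requires a null configuration (no perturbation)")
  .runOperatingCharacteristics(config, nReps, B, alphaLevel, seed, ...)
}

#' Power of the common-order test under a perturbed configuration
#'
#' As \code{\link{type1Error}}, but \code{config} must perturb at least one
#' group, so the rejection rate estimates power under that alternative.
#'
#' @inheritParams type1Error
#' @param config a perturbed \linkS4class{SyntheticConfig}.
#' @return an \linkS4class{OperatingCharacteristics}.
#' @export
testPower <- function(config, nReps = 100L, B = 200L, alphaLevel = 0.05,
                      seed = 1L, ...) {
  if (all(vapply(config@perturbations, is.null, logical(1L))))
    stop("power requires a perturbed configuration")
  .runOperatingCharacteristics(config, nReps, B, alphaLevel, seed, ...)
}

setMethod("show", "OperatingCharacteristics", function(object) {
  cat("Operating characteristics over ", object@nReps, " replicates\n",
      "  rejection rate at alpha = ", object@alphaLevel, ": ",
      format(object@rejectionRate, digits = 4), " (SE ",
      format(object@standardError, digits = 3), ")\n", sep = "")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: ", object@nGenes, " genes, groups (",
      paste(object@groupSizes, collapse = ", "), "), kappa in [",
      format(min(object@kappas), digits = 4), ", ",
      format(max(object@kappas), digits = 4), "], seed ", object@seed,
      "\n", sep = "")
  pert <- which(!vapply(object@perturbations, is.null, logical(1L)))
  if (length(pert))
    cat("  perturbed group(s): ", paste(pert, collapse = ", "), "\n",
        sep = "")
})
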