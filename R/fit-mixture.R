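#' Fitting configuration
#'
#' Control parameters shared by all maximum-likelihood fits. Optimisation
#' is carried out by Nelder-Mead in an unconstrained space
#' (`log alpha1`, `log alpha2`, `logit pi` per group); fitted `alpha`
#' values are clipped to `alphaBounds`, beyond which the pmf is numerically
#' indistinguishable from its limits, and boundary hits are reported.
#'
#' @param minReads minimum total allele-mapped reads for an observation to
#'   enter a fit (default 2).
#' @param minObs minimum observations for a pooled or per-sample fit
#'   (default 20).
#' @param minGroupN minimum observations per genotype group for the
#'   genotype-dependent model (default 10).
#' @param alphaBounds admissible range for fitted dispersion parameters.
#' @param nStarts number of starting points from the default start grid
#'   (at most 6); cross-initialisation between the null and alternative
#'   models is always added on top.
#' @param reltol,maxit Nelder-Mead relative convergence tolerance and
#'   iteration cap per start.
#' @return a list of class `"fitControl"`.
#' @export
fitControl <- function(minReads = 2L, minObs = 20L, minGroupN = 10L,
                       alphaBounds = c(1e-3, 1e6), nStarts = 6L,
                       reltol = 1e-8, maxit = 2000L) {
  stopifnot(minReads >= 1, minObs >= 1, minGroupN >= 1,
            length(alphaBounds) == 2L, alphaBounds[1] > 0,
            alphaBounds[1] < alphaBounds[2],
            nStarts >= 1, reltol > 0, maxit >= 1)
  structure(list(minReads = as.integer(minReads),
                 minObs = as.integer(minObs),
                 minGroupN = as.integer(minGroupN),
                 alphaBounds = as.numeric(alphaBounds),
                 nStarts = as.integer(nStarts),
                 reltol = reltol, maxit = as.integer(maxit)),
            class = "fitControl")
}

# Default start grid (alpha1, alpha2, pi): six diverse points drawn from
# {2, 20, 200}^2 x {0.2, 0.5, 0.8}, covering separated, collapsed and
# label-swapped component configurations.
.startGrid <- function(control) {
  g <- matrix(c(
    200,   2, 0.8,
     20,   2, 0.5,
    200,  20, 0.5,
    100, 100, 0.5,
    200,   2, 0.2,
      2, 200, 0.3
  ), ncol = 3, byrow = TRUE)
  g[seq_len(min(control$nStarts, nrow(g))), , drop = FALSE]
}

.clampAlpha <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

# Nelder-Mead fit of the k-group mixture. grp is 0-based; k = 1 is the
# null (shared-weight) model. starts is a matrix (alpha1, alpha2, pi);
# extraTheta is a list of ready-made parameter vectors in the transformed
# space (used for cross-initialisation). Deterministic given inputs.
.fitGrouped <- function(a, n, grp, k, starts, control,
                        extraTheta = list()) {
  lc <- .lchooseSym(a, n)
  bounds <- control$alphaBounds
  negll <- function(theta) {
    a1 <- .clampAlpha(exp(theta[1L]), bounds)
    a2 <- .clampAlpha(exp(theta[2L]), bounds)
    -.groupedLogLikCpp(a, n, lc, grp, a1, a2, plogis(theta[-(1:2)]))
  }
  thetas <- c(
    if (!is.null(starts)) lapply(seq_len(nrow(starts)), function(i)
      c(log(starts[i, 1L]), log(starts[i, 2L]),
        rep(qlogis(starts[i, 3L]), k))),
    extraTheta
  )
  best <- NULL
  for (theta0 in thetas) {
    opt <- tryCatch(
      optim(theta0, negll, method = "Nelder-Mead",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    .aiqtlStop("likelihood non-finite at every starting point",
               "aiqtl_fit_failure")
  list(theta = best$par, logLik = -best$value,
       converged = best$convergence == 0L,
       nStarts = length(thetas))
}

# Convert an optimizer result into a MixtureFit, resolving label switching
# so that alpha1 >= alpha2 (pi then weights the more balanced component).
.asMixtureFit <- function(fit, labels, control, nObs, model) {
  bounds <- control$alphaBounds
  a1 <- .clampAlpha(exp(fit$theta[1L]), bounds)
  a2 <- .clampAlpha(exp(fit$theta[2L]), bounds)
  w <- plogis(fit$theta[-(1:2)])
  if (a1 < a2) { tmp <- a1; a1 <- a2; a2 <- tmp; w <- 1 - w }
  tol <- 1e-6
  boundary <- c(alpha1 = a1 <= bounds[1] * (1 + tol) || a1 >= bounds[2] / (1 + tol),
                alpha2 = a2 <= bounds[1] * (1 + tol) || a2 >= bounds[2] / (1 + tol))
  new("MixtureFit", alpha1 = a1, alpha2 = a2,
      weights = setNames(w, labels), logLik = fit$logLik,
      converged = fit$converged, nStartsUsed = as.integer(fit$nStarts),
      boundary = boundary, nObs = as.integer(nObs), model = model)
}

.filterReads <- function(a, n, control, what,
                         minN = control$minObs,
                         tooFewClass = "aiqtl_too_few_obs", ...) {
  if (length(a) != length(n))
    .aiqtlStop(sprintf("%s: a and n must have equal length", what),
               "aiqtl_domain_error")
  # observations below the read-depth filter (including zero-total ones
  # from upstream sources) are excluded here, before validation
  keep0 <- !is.na(n) & n >= max(1L, control$minReads)
  obs <- .checkObs(a[keep0], n[keep0], what, allowEmpty = TRUE)
  keep <- rep(TRUE, length(obs$a))
  if (sum(keep) < minN)
    .aiqtlStop(sprintf(
      "%s: %d observation(s) with total_count >= %d; need at least %d",
      what, sum(keep), control$minReads, minN), tooFewClass, ...)
  list(a = obs$a[keep], n = obs$n[keep])
}

#' Fit the shared-weight (null) mixture
#'
#' Maximises the two-component symmetric beta-binomial mixture likelihood
#' with a single mixing weight over all observations, from multiple
#' Nelder-Mead starts in the unconstrained `(log alpha1, log alpha2,
#' logit pi)` space.
#'
#' @param a,n A-allele and total counts, one observation per sample.
#' @param control a [fitControl()] list.
#' @return a [MixtureFit-class] with a single weight named `"pi"`.
#' @examples
#' gt <- simulateGenotypes(300, maf = 0.3, seed = 7)
#' sim <- simulateNegbinSbb(gt, alphaHom = 100, alphaHet = 100)
#' fitNullMixture(sim$aCount, sim$totalCount)
#' @export
fitNullMixture <- function(a, n, control = fitControl()) {
  obs <- .filterReads(a, n, control, "fitNullMixture")
  fit <- .fitGrouped(obs$a, obs$n, integer(length(obs$a)), 1L,
                     .startGrid(control), control)
  .asMixtureFit(fit, "pi", control, length(obs$a), "null")
}

#' Fit the genotype-dependent (alternative) mixture
#'
#' Maximises the grouped likelihood in which heterozygous and (pooled)
#' homozygous samples have separate mixing weights but share the two
#' component dispersions. The start set always includes the null optimum
#' (`piHom = piHet = pi_null`), so the alternative log-likelihood can
#' never fall below the null's beyond optimizer tolerance.
#'
#' @param aHom,nHom counts for homozygous samples.
#' @param aHet,nHet counts for heterozygous samples.
#' @param control a [fitControl()] list.
#' @param nullFit optionally, the [MixtureFit-class] of the null model on
#'   the pooled data; fitted internally when omitted.
#' @return a [MixtureFit-class] with weights named `"hom"` and `"het"`.
#' @export
fitAltMixture <- function(aHom, nHom, aHet, nHet, control = fitControl(),
                          nullFit = NULL) {
  hom <- .filterReads(aHom, nHom, control, "hom group",
                      minN = control$minGroupN,
                      tooFewClass = "aiqtl_group_too_small", group = "hom")
  het <- .filterReads(aHet, nHet, control, "het group",
                      minN = control$minGroupN,
                      tooFewClass = "aiqtl_group_too_small", group = "het")
  if (is.null(nullFit))
    nullFit <- fitNullMixture(c(hom$a, het$a), c(hom$n, het$n), control)
  a <- c(hom$a, het$a); n <- c(hom$n, het$n)
  grp <- c(integer(length(hom$a)), rep(1L, length(het$a)))
  fit <- .fitGrouped(a, n, grp, 2L, .startGrid(control), control,
                     extraTheta = .nullThetaStarts(nullFit, 2L))
  .asMixtureFit(fit, c("hom", "het"), control, length(a), "alt")
}

# Cross-initialisation: the null optimum replicated across the k group
# weights, plus weight-perturbed versions to escape the ridge pi_hom = pi_het.
.nullThetaStarts <- function(nullFit, k) {
  la <- log(c(nullFit@alpha1, nullFit@alpha2))
  q <- qlogis(min(max(nullFit@weights[[1L]], 1e-8), 1 - 1e-8))
  base <- c(la, rep(q, k))
  out <- list(base)
  if (k == 2L) {
    # logit-shifted and interior-weight perturbations: the former explore
    # near the null optimum, the latter rescue cases where the null weight
    # sits on a boundary and shifted starts would stay pinned there
    out <- c(out,
             list(c(la, q + 1, q - 1)), list(c(la, q - 1, q + 1)),
             list(c(la, q, 0)), list(c(la, 0, q)))
  } else if (k > 2L) {
    for (j in seq_len(k)) {
      th <- base; th[2L + j] <- q + 1.5
      out <- c(out, list(th))
    }
  }
  out
}
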