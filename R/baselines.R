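# Comparator aiQTL tests. Each classifies or scores per-sample imbalance
# and compares the two genotype groups; all are sensitive, to varying
# degrees, to read depth and expression level, which is the failure mode
# the mixture model is designed to avoid.

.checkGroups <- function(aHom, nHom, aHet, nHet) {
  # zero-total observations carry no allele information and are dropped;
  # shallow-but-nonzero samples are deliberately retained (their depth
  # bias is intrinsic to these methods)
  kHom <- !is.na(nHom) & nHom >= 1L
  kHet <- !is.na(nHet) & nHet >= 1L
  if (sum(kHom) == 0L || sum(kHet) == 0L)
    .aiqtlStop("both genotype groups must be non-empty",
               "aiqtl_group_too_small")
  list(hom = .checkObs(aHom[kHom], nHom[kHom], "hom group"),
       het = .checkObs(aHet[kHet], nHet[kHet], "het group"))
}

# Exact two-sided binomial p-value against p = 0.5, vectorised. For the
# symmetric null this equals the minimum-likelihood-sum definition used by
# binom.test: both tails at least as extreme as the observed count.
.binomTwoSidedP <- function(a, n) {
  m <- pmin(a, n - a)
  p <- 2 * pbinom(m, n, 0.5)
  p[2L * m == n] <- 1
  pmin(p, 1)
}

.classifiedResult <- function(method, imbHet, imbHom, nHet, nHom, groupTest) {
  tab <- matrix(as.integer(c(sum(imbHet), nHet - sum(imbHet),
                             sum(imbHom), nHom - sum(imbHom))),
                nrow = 2L,
                dimnames = list(c("imbalanced", "balanced"),
                                c("het", "hom")))
  p <- if (groupTest == "fisher") fisher.test(tab)$p.value
       else suppressWarnings(chisq.test(tab)$p.value)
  new("BaselineResult", method = method,
      statistic = mean(imbHet) - mean(imbHom),
      pValue = min(max(p, .Machine$double.xmin), 1),
      nHet = as.integer(nHet), nHom = as.integer(nHom),
      contingency = tab)
}

#' Binomial comparator test
#'
#' Classifies each sample as imbalanced when its two-sided exact binomial
#' test of `a/n` against 0.5 is below `perSampleLevel`, then compares the
#' imbalanced proportion between heterozygotes and homozygotes (Fisher's
#' exact test by default). Samples whose depth can never reach
#' significance (e.g. `n = 4` cannot beat 0.05 two-sided) are deliberately
#' retained: that depth-driven bias is intrinsic to the approach.
#'
#' @param aHom,nHom,aHet,nHet counts for the two genotype groups.
#' @param perSampleLevel per-sample classification level.
#' @param groupTest `"fisher"` (default) or `"chisq"`.
#' @return a [BaselineResult-class]; `statistic` is the difference in
#'   imbalanced proportion (het minus hom).
#' @export
binomialMethod <- function(aHom, nHom, aHet, nHet, perSampleLevel = 0.05,
                           groupTest = c("fisher", "chisq")) {
  groupTest <- match.arg(groupTest)
  g <- .checkGroups(aHom, nHom, aHet, nHet)
  imbHet <- .binomTwoSidedP(g$het$a, g$het$n) < perSampleLevel
  imbHom <- .binomTwoSidedP(g$hom$a, g$hom$n) < perSampleLevel
  .classifiedResult("binomial", imbHet, imbHom,
                    length(g$het$a), length(g$hom$a), groupTest)
}

#' Allele-fraction threshold comparator test
#'
#' Classifies a sample as imbalanced when its A-allele fraction falls
#' strictly below `lo` or strictly above `hi` (defaults 0.35/0.65), then
#' compares group proportions as in [binomialMethod()].
#'
#' @inheritParams binomialMethod
#' @param lo,hi allele-fraction thresholds, `lo < hi`; a fraction of
#'   exactly `hi` (or `lo`) is *not* classified as imbalanced.
#' @return a [BaselineResult-class].
#' @export
thresholdMethod <- function(aHom, nHom, aHet, nHet, lo = 0.35, hi = 0.65,
                            groupTest = c("fisher", "chisq")) {
  groupTest <- match.arg(groupTest)
  if (lo >= hi)
    .aiqtlStop("need lo < hi", "aiqtl_domain_error")
  g <- .checkGroups(aHom, nHom, aHet, nHet)
  fr <- function(o) o$a / o$n
  imbHet <- fr(g$het) < lo | fr(g$het) > hi
  imbHom <- fr(g$hom) < lo | fr(g$hom) > hi
  .classifiedResult("threshold", imbHet, imbHom,
                    length(g$het$a), length(g$hom$a), groupTest)
}

#' Wilcoxon rank-sum comparator test
#'
#' Compares the absolute departure of the allele fraction from 0.5,
#' `|a/n - 0.5|`, between heterozygotes and homozygotes by a two-sided
#' Wilcoxon rank-sum test. Exact p-values are used for combined group
#' sizes up to `exactMax` without ties; otherwise the tie-corrected
#' normal approximation. Invariant to flipping any sample's allele label.
#'
#' @inheritParams binomialMethod
#' @param exactMax largest combined sample size for exact p-values.
#' @return a [BaselineResult-class]; `statistic` is the rank-sum W.
#' @export
wilcoxMethod <- function(aHom, nHom, aHet, nHet, exactMax = 20L) {
  g <- .checkGroups(aHom, nHom, aHet, nHet)
  dHet <- abs(g$het$a / g$het$n - 0.5)
  dHom <- abs(g$hom$a / g$hom$n - 0.5)
  if (length(unique(c(dHet, dHom))) == 1L) {
    # degenerate: all departures identical; no evidence either way
    return(new("BaselineResult", method = "wilcox",
               statistic = length(dHet) * length(dHom) / 2,
               pValue = 1, nHet = length(dHet), nHom = length(dHom),
               contingency = NULL))
  }
  if (length(dHet) + length(dHom) <= exactMax) {
    res <- .wilcoxExactPerm(dHet, dHom)
  } else {
    wt <- suppressWarnings(
      wilcox.test(dHet, dHom, alternative = "two.sided", exact = FALSE))
    res <- list(W = unname(wt$statistic), p = wt$p.value)
  }
  new("BaselineResult", method = "wilcox",
      statistic = res$W,
      pValue = min(max(res$p, .Machine$double.xmin), 1),
      nHet = length(dHet), nHom = length(dHom), contingency = NULL)
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments; ties handled by midranks. Used for small combined n, where
# the normal approximation is poor.
.wilcoxExactPerm <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  idx <- utils::combn(nx + ny, nx)
  w <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
  p <- mean(abs(w - mu) >= abs(wObs - mu) - 1e-12)
  list(W = wObs, p = p)
}

# Single-alpha symmetric beta-binomial ML fit; returns list(alpha, logLik).
.fitSingleAlpha <- function(a, n, control) {
  lc <- .lchooseSym(a, n)
  interval <- log(control$alphaBounds)
  opt <- optimize(function(la) -.sbbLogLikCpp(a, n, lc, exp(la)),
                  interval = interval, tol = 1e-8)
  list(alpha = exp(opt$minimum), logLik = -opt$objective)
}

#' Independent beta-binomial comparator test
#'
#' Fits a single symmetric beta-binomial dispersion separately to each
#' genotype group and compares the summed log-likelihood to a
#' shared-dispersion fit by a likelihood-ratio test on 1 degree of
#' freedom. This rejected alternative to the mixture approach is provided
#' because it is instructively fragile: a single sample with very deep
#' coverage and strong imbalance can dominate its group's likelihood and
#' produce a significant result that reflects one outlier rather than a
#' genotype-dependent tendency, whereas the mixture test reweights such a
#' sample through the mixing proportion.
#'
#' @inheritParams binomialMethod
#' @param control a [fitControl()] list.
#' @return a [BaselineResult-class]; `statistic` is the LRT statistic.
#' @export
indepBbTest <- function(aHom, nHom, aHet, nHet, control = fitControl()) {
  hom <- .filterReads(aHom, nHom, control, "hom group",
                      minN = control$minGroupN,
                      tooFewClass = "aiqtl_group_too_small", group = "hom")
  het <- .filterReads(aHet, nHet, control, "het group",
                      minN = control$minGroupN,
                      tooFewClass = "aiqtl_group_too_small", group = "het")
  fitHom <- .fitSingleAlpha(hom$a, hom$n, control)
  fitHet <- .fitSingleAlpha(het$a, het$n, control)
  fitShared <- .fitSingleAlpha(c(hom$a, het$a), c(hom$n, het$n), control)
  lrt <- max(0, 2 * (fitHom$logLik + fitHet$logLik - fitShared$logLik))
  new("BaselineResult", method = "indep_bb", statistic = lrt,
      pValue = pchisq(lrt, df = 1, lower.tail = FALSE),
      nHet = length(het$a), nHom = length(hom$a), contingency = NULL)
}
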