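#' Likelihood-ratio test for an allelic-imbalance QTL
#'
#' Compares a null model in which the mixing weight of the balanced
#' beta-binomial component is shared by all samples to an alternative in
#' which heterozygotes and (pooled) homozygotes at the candidate variant
#' have separate weights. Twice the log-likelihood difference is referred
#' to chi-squared with 1 degree of freedom. Optimisations are
#' cross-initialised in both directions: the alternative starts from the
#' null optimum, and the null is additionally restarted from the
#' alternative optimum with the group weights replaced by their
#' group-size-weighted average. The statistic is clamped at zero.
#'
#' @param aHom,nHom A-allele and total counts for homozygous samples.
#' @param aHet,nHet counts for heterozygous samples.
#' @param control a [fitControl()] list.
#' @return an [AiqtlTest-class] object.
#' @examples
#' gt <- simulateGenotypes(400, maf = 0.3, seed = 11)
#' sim <- simulateNegbinSbb(gt, alphaHom = 100, alphaHet = 5)
#' het <- sim$cls == "HET"
#' aiqtlTest(sim$aCount[!het], sim$totalCount[!het],
#'           sim$aCount[het], sim$totalCount[het])
#' @export
aiqtlTest <- function(aHom, nHom, aHet, nHet, control = fitControl()) {
  hom <- .filterReads(aHom, nHom, control, "hom group",
                      minN = control$minGroupN,
                      tooFewClass = "aiqtl_group_too_small", group = "hom")
  het <- .filterReads(aHet, nHet, control, "het group",
                      minN = control$minGroupN,
                      tooFewClass = "aiqtl_group_too_small", group = "het")
  groups <- list(hom = hom, het = het)
  res <- .lrtGrouped(groups, control)
  new("AiqtlTest", lrtStat = res$lrt, df = res$df, pValue = res$p,
      nullFit = res$null, altFit = res$alt,
      nHet = as.integer(length(het$a)), nHom = as.integer(length(hom$a)))
}

#' Dosage-stratified variant of the aiQTL test
#'
#' Instead of pooling the two homozygous classes, fits one mixing weight
#' per genotype dosage class present (0, 1, 2 copies of the alternative
#' allele), giving a likelihood-ratio test on `k - 1` degrees of freedom
#' (2 when all three classes are present). The pooled het/hom form of
#' [aiqtlTest()] is the default analysis; this variant targets settings
#' where the two homozygous classes are suspected to differ.
#'
#' @param a,n A-allele and total counts, one observation per sample.
#' @param dosage integer vector in `{0, 1, 2}`, alternative-allele count
#'   per sample.
#' @param control a [fitControl()] list.
#' @return an [AiqtlTest-class]; `nHet`/`nHom` refer to dosage 1 vs 0 + 2.
#' @export
aiqtlTestDosage <- function(a, n, dosage, control = fitControl()) {
  if (length(dosage) != length(a))
    .aiqtlStop("dosage must match observations in length", "aiqtl_domain_error")
  if (!all(dosage %in% 0:2))
    .aiqtlStop("dosage must contain only 0, 1 or 2", "aiqtl_domain_error")
  lev <- sort(unique(dosage))
  if (length(lev) < 2L)
    .aiqtlStop("need at least two genotype classes", "aiqtl_group_too_small",
               group = "dosage")
  groups <- lapply(lev, function(d) {
    .filterReads(a[dosage == d], n[dosage == d], control,
                 sprintf("dosage %d group", d), minN = control$minGroupN,
                 tooFewClass = "aiqtl_group_too_small",
                 group = paste0("dosage", d))
  })
  names(groups) <- paste0("dosage", lev)
  res <- .lrtGrouped(groups, control)
  new("AiqtlTest", lrtStat = res$lrt, df = res$df, pValue = res$p,
      nullFit = res$null, altFit = res$alt,
      nHet = as.integer(sum(dosage == 1L)),
      nHom = as.integer(sum(dosage != 1L)))
}

# Shared engine: null vs per-group-weight LRT over k >= 2 groups.
.lrtGrouped <- function(groups, control) {
  k <- length(groups)
  a <- unlist(lapply(groups, `[[`, "a"), use.names = FALSE)
  n <- unlist(lapply(groups, `[[`, "n"), use.names = FALSE)
  sizes <- vapply(groups, function(g) length(g$a), integer(1))
  grp <- rep(seq_len(k) - 1L, sizes)

  null1 <- .fitGrouped(a, n, integer(length(a)), 1L,
                       .startGrid(control), control)
  nullFit <- .asMixtureFit(null1, "pi", control, length(a), "null")

  alt <- .fitGrouped(a, n, grp, k, .startGrid(control), control,
                     extraTheta = .nullThetaStarts(nullFit, k))

  # reverse-direction start: group-size-weighted average of the
  # alternative's mixing weights
  piBar <- weighted.mean(plogis(alt$theta[-(1:2)]), w = sizes)
  piBar <- min(max(piBar, 1e-8), 1 - 1e-8)
  null2 <- .fitGrouped(a, n, integer(length(a)), 1L, NULL, control,
                       extraTheta = list(c(alt$theta[1:2], qlogis(piBar))))
  if (null2$logLik > null1$logLik) {
    null1 <- null2
    nullFit <- .asMixtureFit(null1, "pi", control, length(a), "null")
  }
  # if the improved null now beats the alternative, give the alternative
  # one more chance from the improved null optimum
  if (alt$logLik < null1$logLik) {
    alt2 <- .fitGrouped(a, n, grp, k, NULL, control,
                        extraTheta = .nullThetaStarts(nullFit, k))
    if (alt2$logLik > alt$logLik) alt <- alt2
  }
  altFit <- .asMixtureFit(alt, names(groups), control, length(a), "alt")

  lrt <- max(0, 2 * (alt$logLik - null1$logLik))
  df <- k - 1L
  list(lrt = lrt, df = as.integer(df),
       p = pchisq(lrt, df = df, lower.tail = FALSE),
       null = nullFit, alt = altFit)
}
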