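#' Simulate genotype classes at a candidate variant
#'
#' Draws an alternative-allele dosage for each individual under
#' Hardy-Weinberg equilibrium at the given minor allele frequency, so each
#' individual is heterozygous with probability `2 * maf * (1 - maf)`. To
#' bypass the HWE assumption, construct the data frame directly (columns
#' `sampleId`, `dosage`, `cls`) with whatever class counts are wanted.
#'
#' @param n number of individuals.
#' @param maf minor allele frequency, in `(0, 0.5]`.
#' @param seed optional integer seed; when given, the genotype vector is
#'   reproducible.
#' @return a data.frame with columns `sampleId`, `dosage` (0/1/2) and
#'   `cls` (factor, `"HOM"`/`"HET"`; both homozygous classes pooled).
#' @examples
#' g <- simulateGenotypes(670, maf = 0.1, seed = 1)
#' mean(g$cls == "HET")  # close to 2 * 0.1 * 0.9 = 0.18
#' @export
simulateGenotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    .aiqtlStop("maf must lie in (0, 0.5]", "aiqtl_domain_error")
  if (!is.null(seed)) set.seed(seed)
  dosage <- rbinom(n, 2L, maf)
  data.frame(
    sampleId = sprintf("S%04d", seq_len(n)),
    dosage = dosage,
    cls = factor(ifelse(dosage == 1L, "HET", "HOM"), levels = c("HOM", "HET")),
    stringsAsFactors = FALSE
  )
}

.simFrame <- function(genotypes, aCount, totalCount, truth, params) {
  out <- data.frame(
    sampleId = genotypes$sampleId,
    geneId = "gene1",
    aCount = as.integer(aCount),
    totalCount = as.integer(totalCount),
    cls = genotypes$cls,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- truth
  attr(out, "trueParams") <- params
  out
}

#' Simulate allele counts as two independent negative binomials
#'
#' Each haplotype's read count is an independent negative binomial; in
#' heterozygotes one haplotype's mean is multiplied by `foldChange`
#' (the cis effect), in homozygotes both haplotypes share the base mean.
#' The A allele is a randomly chosen haplotype, so the over-expressed
#' allele is not consistent across samples. `foldChange = 1` is a null
#' design. Deliberately mismatched to the fitted model (no conditioning on
#' the total), which probes robustness: at small `negbinSize` the two
#' haplotypes can differ wildly for reasons unrelated to genotype.
#'
#' Negative binomial parameterisation throughout: `(mean, size)` with
#' variance `mean + mean^2 / size`; small `size` = strong overdispersion.
#'
#' @param genotypes data.frame from [simulateGenotypes()] (columns
#'   `sampleId`, `cls`).
#' @param foldChange ratio (`>= 1`) of the higher to the lower haplotype
#'   mean in heterozygotes.
#' @param negbinMean mean *total* count; each haplotype has base mean
#'   `negbinMean / 2`.
#' @param negbinSize negative-binomial size (dispersion) parameter.
#' @param seed optional integer seed.
#' @return a data.frame of observations (`sampleId`, `geneId`, `aCount`,
#'   `totalCount`, `cls`) with attributes `truth` (`"NULL"` or `"CIS"`)
#'   and `trueParams`.
#' @export
simulateTwoNegbin <- function(genotypes, foldChange = 1, negbinMean = 30,
                              negbinSize = 5, seed = NULL) {
  stopifnot(foldChange >= 1, negbinMean > 0, negbinSize > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  het <- genotypes$cls == "HET"
  mu <- negbinMean / 2
  h1 <- rnbinom(n, mu = mu, size = negbinSize)
  h2 <- rnbinom(n, mu = ifelse(het, mu * foldChange, mu), size = negbinSize)
  swap <- runif(n) < 0.5
  aCount <- ifelse(swap, h2, h1)
  .simFrame(genotypes, aCount, h1 + h2,
            if (foldChange == 1) "NULL" else "CIS",
            list(design = "two_negbin", foldChange = foldChange,
                 negbinMean = negbinMean, negbinSize = negbinSize))
}

#' Simulate a negative-binomial total with a beta-binomial allelic split
#'
#' The total allele-mapped count is negative binomial; given the total,
#' the A-allele count is symmetric beta-binomial with dispersion
#' `alphaHom` in homozygotes and `alphaHet` in heterozygotes. This matches
#' the structure of the fitted model (the two alleles share their sample).
#' The more highly expressed allele is automatically random, by symmetry.
#' `alphaHet = alphaHom` is a null design; smaller `alphaHet` simulates a
#' cis effect of increasing strength.
#'
#' @inheritParams simulateTwoNegbin
#' @param alphaHom,alphaHet symmetric beta-binomial dispersions for the
#'   two genotype classes.
#' @return as [simulateTwoNegbin()]; truth is `"NULL"` when the two
#'   dispersions are equal, else `"CIS"`.
#' @export
simulateNegbinSbb <- function(genotypes, alphaHom = 100, alphaHet = 100,
                              negbinMean = 30, negbinSize = 5, seed = NULL) {
  stopifnot(alphaHom > 0, alphaHet > 0, negbinMean > 0, negbinSize > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  alpha <- ifelse(genotypes$cls == "HET", alphaHet, alphaHom)
  totalCount <- rnbinom(n, mu = negbinMean, size = negbinSize)
  p <- rbeta(n, alpha, alpha)
  aCount <- rbinom(n, totalCount, p)
  .simFrame(genotypes, aCount, totalCount,
            if (alphaHet == alphaHom) "NULL" else "CIS",
            list(design = "negbin_sbb", alphaHom = alphaHom,
                 alphaHet = alphaHet, negbinMean = negbinMean,
                 negbinSize = negbinSize))
}

#' Simulate a trans-acting eQTL (null for the aiQTL test)
#'
#' A trans effect changes total expression with genotype but acts on both
#' alleles equally, so the allelic split stays balanced. The total count
#' is negative binomial with a mean that scales with alternative-allele
#' dosage; given the total, the A-allele count is symmetric beta-binomial
#' with a single shared dispersion. A correctly calibrated aiQTL test must
#' *not* reject under this design, whereas methods whose imbalance signal
#' depends on expression level can.
#'
#' @inheritParams simulateTwoNegbin
#' @param foldChange expression factor per alternative allele (default 1.5).
#' @param alpha shared symmetric beta-binomial dispersion.
#' @param dosageModel `"multiplicative"`: mean is
#'   `negbinMean * foldChange^dosage`; `"linear"`: mean is
#'   `negbinMean * (1 + (foldChange - 1) * dosage)`.
#' @return as [simulateTwoNegbin()], truth `"TRANS"`; `trueParams` records
#'   the dosage model.
#' @export
simulateTransEqtl <- function(genotypes, foldChange = 1.5, alpha = 100,
                              negbinMean = 30, negbinSize = 5,
                              dosageModel = c("multiplicative", "linear"),
                              seed = NULL) {
  dosageModel <- match.arg(dosageModel)
  stopifnot(foldChange >= 1, alpha > 0, negbinMean > 0, negbinSize > 0)
  if (is.null(genotypes$dosage))
    .aiqtlStop("trans simulation needs a 'dosage' column (0/1/2)",
               "aiqtl_domain_error")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  mu <- switch(dosageModel,
    multiplicative = negbinMean * foldChange^genotypes$dosage,
    linear = negbinMean * (1 + (foldChange - 1) * genotypes$dosage))
  totalCount <- rnbinom(n, mu = mu, size = negbinSize)
  p <- rbeta(n, alpha, alpha)
  aCount <- rbinom(n, totalCount, p)
  .simFrame(genotypes, aCount, totalCount, "TRANS",
            list(design = "trans", foldChange = foldChange, alpha = alpha,
                 negbinMean = negbinMean, negbinSize = negbinSize,
                 dosageModel = dosageModel))
}
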