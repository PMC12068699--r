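# Shared builders for test datasets. Everything is generated in code at
# fixed seeds; nothing is read from disk unless a test writes it first.

# Reduced-start control for Monte-Carlo loops (full default elsewhere).
mcControl <- fitControl(nStarts = 2L, reltol = 1e-7)

# One simulated gene under the conditioned (negative-binomial total +
# symmetric beta-binomial split) design, split into genotype groups.
simGroups <- function(n = 670, maf = 0.3, alphaHom = 100, alphaHet = 100,
                      negbinMean = 30, negbinSize = 5, seed = 1) {
  gt <- simulateGenotypes(n, maf, seed = seed)
  sim <- simulateNegbinSbb(gt, alphaHom = alphaHom, alphaHet = alphaHet,
                           negbinMean = negbinMean, negbinSize = negbinSize)
  het <- sim$cls == "HET"
  pos <- sim$totalCount >= 1L   # group vectors exclude zero-read samples
  list(aHom = sim$aCount[!het & pos], nHom = sim$totalCount[!het & pos],
       aHet = sim$aCount[het & pos], nHet = sim$totalCount[het & pos],
       sim = sim, genotypes = gt)
}

# Gene-variant covariate table whose detection outcomes follow a known
# logistic decay in |TSS distance|, for distance-model tests.
makeLogisticData <- function(n = 400, b0 = 1.2, bDist = -4e-6, seed = 71) {
  set.seed(seed)
  d <- data.frame(
    variantId = sprintf("v%04d", seq_len(n)),
    geneId = sprintf("g%04d", seq_len(n)),
    tssDistance = as.integer(round(runif(n, -1e6, 1e6))),
    nInformativeSamples = sample(100:700, n, replace = TRUE),
    medianReads = round(runif(n, 10, 60)),
    maf = runif(n, 0.05, 0.5),
    eqtlLog10P = -runif(n, 5, 40))
  eta <- b0 + bDist * abs(d$tssDistance) +
    0.002 * (d$nInformativeSamples - 400) - 0.02 * (d$eqtlLog10P + 20)
  d$detected <- runif(n) < plogis(eta)
  attr(d, "bDist") <- bDist
  d
}

# A multi-gene dataset for scan-level tests: nCis genes with a strong
# genotype-dependent imbalance, the rest null, all sharing one cohort.
makeScanData <- function(nSamples = 120, nCis = 10, nNull = 40,
                         alphaHetCis = 3, seed = 1) {
  set.seed(seed)
  gtList <- list(); counts <- list(); pairs <- list()
  nGenes <- nCis + nNull
  for (g in seq_len(nGenes)) {
    gene <- sprintf("gene%03d", g)
    variant <- sprintf("var%03d", g)
    gt <- simulateGenotypes(nSamples, maf = 0.3)
    isCis <- g <= nCis
    sim <- simulateNegbinSbb(gt, alphaHom = 100,
                             alphaHet = if (isCis) alphaHetCis else 100,
                             negbinMean = 50, negbinSize = 20)
    counts[[g]] <- data.frame(sampleId = sim$sampleId, geneId = gene,
                              aCount = sim$aCount,
                              totalCount = sim$totalCount)
    gtList[[g]] <- data.frame(variantId = variant, sampleId = gt$sampleId,
                              cls = as.character(gt$cls))
    pairs[[g]] <- data.frame(variantId = variant, geneId = gene,
                             tssDistance = sample(-5e5:5e5, 1),
                             maf = 0.3,
                             eqtlLog10P = -runif(1, 5, 30),
                             nInformativeSamples = sum(sim$totalCount >= 2),
                             medianReads = median(sim$totalCount),
                             truthCis = isCis)
  }
  list(counts = do.call(rbind, counts),
       genotypes = do.call(rbind, gtList),
       pairs = do.call(rbind, pairs))
}
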