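# Dataset-level orchestration: top-eQTL selection, scanning, the distance
# model, per-sample summaries and downsampling.

test_that("strongest eQTL per gene is selected with deterministic ties", {
  rec <- data.frame(
    variantId = c("v1", "v2", "v3", "w1", "t1", "t2"),
    geneId = c("g1", "g1", "g1", "g2", "g3", "g3"),
    eqtlLog10P = c(-8, -20, -12, -5, -9, -9),
    tssDistance = c(100L, 5000L, 10L, 0L, 5000L, 100L))
  top <- selectTopEqtlPerGene(rec)
  expect_identical(nrow(top), 3L)
  expect_identical(top$variantId[top$geneId == "g1"], "v2")
  expect_identical(top$variantId[top$geneId == "g3"], "t2")  # closer tie-break
  # tie on p and distance: lexicographic variant id
  rec2 <- data.frame(variantId = c("vb", "va"), geneId = "g",
                     eqtlLog10P = -7, tssDistance = 100L)
  expect_identical(selectTopEqtlPerGene(rec2)$variantId, "va")
  expect_identical(nrow(selectTopEqtlPerGene(rec[0, ])), 0L)
})

scanData <- makeScanData(nSamples = 120, nCis = 10, nNull = 40, seed = 33)

test_that("the scan recovers strong cis genes and conserves records", {
  sc <- runAiqtlScan(scanData$counts, scanData$genotypes, scanData$pairs,
                     control = mcControl, level = 0.01)
  expect_identical(nrow(sc), nrow(scanData$pairs))
  expect_true(all(sc$status %in% c("ok", "skipped")))
  truePos <- sum(sc$detected & sc$truthCis)
  falsePos <- sum(sc$detected & !sc$truthCis)
  expect_gte(truePos, 8L)
  expect_lte(falsePos, 3L)
  # holm detects no more than unadjusted
  scHolm <- runAiqtlScan(scanData$counts, scanData$genotypes,
                         scanData$pairs, control = mcControl,
                         level = 0.01, adjust = "holm")
  expect_lte(sum(scHolm$detected), sum(sc$detected))
})

test_that("scan results are invariant to row order and allele labels", {
  small <- makeScanData(nSamples = 100, nCis = 2, nNull = 2, seed = 35)
  sc <- runAiqtlScan(small$counts, small$genotypes, small$pairs,
                     control = mcControl)
  perm <- sample(nrow(small$counts))
  scPerm <- runAiqtlScan(small$counts[perm, ], small$genotypes,
                         small$pairs, control = mcControl)
  expect_identical(sc$pValue, scPerm$pValue)
  flipped <- small$counts
  set.seed(1)
  fl <- runif(nrow(flipped)) < 0.5
  flipped$aCount <- ifelse(fl, flipped$totalCount - flipped$aCount,
                           flipped$aCount)
  scFlip <- runAiqtlScan(flipped, small$genotypes, small$pairs,
                         control = mcControl)
  expect_identical(sc$pValue, scFlip$pValue)
})

test_that("untestable pairs carry reason codes instead of vanishing", {
  small <- makeScanData(nSamples = 60, nCis = 1, nNull = 1, seed = 37)
  # variant with only 3 heterozygous samples
  gt <- small$genotypes
  hetIdx <- which(gt$variantId == "var001" & gt$cls == "HET")
  gt$cls[hetIdx[-(1:3)]] <- "HOM"
  sc <- runAiqtlScan(small$counts, gt, small$pairs, control = mcControl)
  expect_identical(sc$status[sc$variantId == "var001"], "skipped")
  expect_identical(sc$reason[sc$variantId == "var001"], "insufficient_het")
  # unknown gene: join failure
  pairs2 <- rbind(small$pairs[, c("variantId", "geneId")],
                  data.frame(variantId = "var001", geneId = "nosuch"))
  sc2 <- runAiqtlScan(small$counts, small$genotypes, pairs2,
                      control = mcControl)
  expect_identical(sc2$reason[sc2$geneId == "nosuch"], "join_failure")
  # empty pair list in, empty result out
  expect_identical(nrow(runAiqtlScan(small$counts, small$genotypes,
                                     small$pairs[0, ])), 0L)
})

test_that("distance logistic model recovers a known decay", {
  d <- makeLogisticData()
  fit <- fitDistanceLogistic(d)
  cf <- fit$coefficients
  for (side in c("absDistance:sidedownstream", "absDistance:sideupstream")) {
    row <- cf[cf$term == side, ]
    expect_lt(row$estimate, 0)
    expect_lt(abs(row$estimate - attr(d, "bDist")), 2 * row$se)
  }
  # calibration identity: mean fitted equals observed detection rate
  expect_equal(mean(fitted(fit$model)), mean(d$detected), tolerance = 1e-6)
})

test_that("degenerate logistic inputs abort with diagnostics", {
  d <- makeLogisticData(n = 120)
  d$detected <- TRUE
  expect_error(fitDistanceLogistic(d), class = "aiqtl_separation")
  expect_error(fitDistanceLogistic(makeLogisticData(n = 30)),
               class = "aiqtl_too_few_obs")
})

test_that("permuted detection outcomes kill the distance coefficient", {
  d <- makeLogisticData(n = 300, seed = 73)
  set.seed(74)
  sig <- 0L
  for (i in 1:50) {
    dp <- d
    dp$detected <- sample(dp$detected)
    fit <- tryCatch(fitDistanceLogistic(dp), aiqtl_error = function(e) NULL)
    if (is.null(fit)) next
    cf <- fit$coefficients
    pd <- cf$pValue[cf$term == "absDistance:sidedownstream"]
    pu <- cf$pValue[cf$term == "absDistance:sideupstream"]
    if (min(pd, pu) < 0.05) sig <- sig + 1L
  }
  expect_lte(sig, 10L)   # both slopes tested, so allow 2 x 0.05 x 50
})

test_that("predicted probabilities behave like an inverse logit", {
  d <- makeLogisticData(seed = 75)
  fit <- fitDistanceLogistic(d)
  cov <- list(nInformativeSamples = 500, medianReads = 30, maf = 0.05,
              eqtlLog10P = -20)
  grid <- seq(0, 1e6, length.out = 21)
  pr <- predictAiqtlProbability(fit, cov, distance = grid)
  expect_true(all(pr > 0 & pr < 1))
  expect_true(all(diff(pr) < 1e-12))   # monotone decay with distance
  # prediction at 500 kb close to the generating model's value
  etaTrue <- 1.2 + attr(d, "bDist") * 5e5 + 0.002 * (500 - 400) -
    0.02 * (-20 + 20)
  expect_lt(abs(predictAiqtlProbability(fit, cov, 5e5) - plogis(etaTrue)),
            0.15)
  expect_error(predictAiqtlProbability(fit, list(maf = 0.1), 0),
               class = "aiqtl_domain_error")
})

makeTissueCounts <- function(nPerTissue = 10, nGenes = 250,
                             alphas = c(tissueA = 10, tissueB = 40),
                             seed = 81) {
  set.seed(seed)
  counts <- list(); meta <- list()
  for (ts in names(alphas)) {
    for (s in seq_len(nPerTissue)) {
      id <- sprintf("%s_S%02d", ts, s)
      n <- rnbinom(nGenes, mu = 30, size = 10)
      keep <- n >= 2
      a <- rbinom(sum(keep), n[keep],
                  rbeta(sum(keep), alphas[[ts]], alphas[[ts]]))
      counts[[id]] <- data.frame(sampleId = id,
                                 geneId = sprintf("g%04d", which(keep)),
                                 aCount = a, totalCount = n[keep])
      meta[[id]] <- data.frame(sampleId = id, tissue = ts,
                               age = runif(1, 20, 70))
    }
  }
  list(counts = do.call(rbind, counts), metadata = do.call(rbind, meta))
}

test_that("per-sample summaries separate tissues simulated apart", {
  td <- makeTissueCounts()
  sm <- summarizeSampleAlpha(td$counts, td$metadata)
  s <- sm$samples
  expect_identical(nrow(s), 20L)
  medA <- median(s$alpha[s$tissue == "tissueA"])
  medB <- median(s$alpha[s$tissue == "tissueB"])
  expect_lt(medA, medB)
  expect_lt(abs(log(medA / 10)), log(2))
  expect_lt(abs(log(medB / 40)), log(2))
  # age was independent of alpha: Holm-adjusted p stays unremarkable
  expect_true(all(is.na(sm$associations$pHolm) |
                    sm$associations$pHolm > 0.01))
})

test_that("a single sample yields a one-row summary without associations", {
  td <- makeTissueCounts(nPerTissue = 1, alphas = c(tissueA = 15))
  sm <- summarizeSampleAlpha(td$counts)
  expect_identical(nrow(sm$samples), 1L)
  expect_identical(nrow(sm$associations), 0L)
})

test_that("downsampling reproduces the full scan at full size", {
  small <- makeScanData(nSamples = 80, nCis = 3, nNull = 2, seed = 91)
  ds <- downsampleScan(small$counts, small$genotypes, small$pairs,
                       sizes = c(40L, 80L), nDraws = 2L, seed = 7,
                       control = mcControl)
  full <- ds$summary[ds$summary$size == 80L, ]
  expect_true(all(full$detectedFraction ==
                    mean(ds$fullScan$detected)))
  expect_true(all(full$fractionOfFull == 1))
  # monotone (strong effect): smaller cohorts detect no more
  m40 <- mean(ds$summary$detectedFraction[ds$summary$size == 40L])
  m80 <- mean(ds$summary$detectedFraction[ds$summary$size == 80L])
  expect_lte(m40, m80 + 1e-9)
  # determinism and bounds checking
  ds2 <- downsampleScan(small$counts, small$genotypes, small$pairs,
                        sizes = c(40L, 80L), nDraws = 2L, seed = 7,
                        control = mcControl)
  expect_identical(ds$summary, ds2$summary)
  expect_error(downsampleScan(small$counts, small$genotypes, small$pairs,
                              sizes = 81L), class = "aiqtl_domain_error")
})
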