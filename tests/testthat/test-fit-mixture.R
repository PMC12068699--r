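# Maximum-likelihood fitting of the mixture and of per-sample dispersion.

test_that("single-component data collapse the null mixture fit", {
  set.seed(101)
  n <- rnbinom(500, mu = 30, size = 10) + 2L
  a <- rbinom(500, n, rbeta(500, 50, 50))
  fit <- fitNullMixture(a, n)
  single <- fitSampleAlpha(a, n)
  # the richer model cannot do worse, and its three extra parameters buy
  # only the chi-squared-scale overfit expected under nesting
  expect_gte(fit@logLik, single@logLik - 1e-6)
  expect_lt(fit@logLik - single@logLik, 3)
  # and the implied count distribution is indistinguishable from the
  # single component at a typical read depth
  pi <- mixtureWeights(fit)[["pi"]]
  N <- 30L
  pMix <- pi * exp(sbbLogPmf(0:N, N, fit@alpha1)) +
    (1 - pi) * exp(sbbLogPmf(0:N, N, fit@alpha2))
  pSingle <- exp(sbbLogPmf(0:N, N, single@alpha))
  expect_lt(max(abs(pMix - pSingle)), 0.01)
})

test_that("the null fit recovers two-component mixture parameters", {
  # read depth 200: the balanced component's dispersion (100) is only
  # identifiable when depths are comparable to it
  set.seed(202)
  nObs <- 1000
  n <- rnbinom(nObs, mu = 200, size = 10) + 2L
  comp1 <- runif(nObs) < 0.6
  alpha <- ifelse(comp1, 100, 2)
  a <- rbinom(nObs, n, rbeta(nObs, alpha, alpha))
  fit <- fitNullMixture(a, n)
  expect_lt(abs(mixtureWeights(fit)[["pi"]] - 0.6), 0.05)
  expect_lt(abs(log(fit@alpha1) - log(100)), 0.5)
  expect_lt(abs(log(fit@alpha2) - log(2)), 0.5)
  expect_true(fit@alpha1 >= fit@alpha2)  # canonical label order
})

test_that("fits reject empty or undersized input", {
  expect_error(fitNullMixture(integer(), integer()),
               class = "aiqtl_too_few_obs")
  expect_error(fitNullMixture(c(1L, 2L), c(4L, 5L)),
               class = "aiqtl_too_few_obs")
  g <- simGroups(n = 100, seed = 5)
  expect_error(fitAltMixture(g$aHom[1:3], g$nHom[1:3], g$aHet, g$nHet),
               class = "aiqtl_group_too_small")
})

test_that("alternative fit agrees across start strategies and null input", {
  g <- simGroups(n = 300, alphaHet = 20, seed = 7)
  nullFit <- fitNullMixture(c(g$aHom, g$aHet), c(g$nHom, g$nHet))
  withNull <- fitAltMixture(g$aHom, g$nHom, g$aHet, g$nHet,
                            nullFit = nullFit)
  without <- fitAltMixture(g$aHom, g$nHom, g$aHet, g$nHet)
  expect_equal(withNull@logLik, without@logLik, tolerance = 1e-4)
})

test_that("identically distributed groups give near-equal weights", {
  g <- simGroups(n = 500, alphaHom = 100, alphaHet = 100, seed = 9)
  nullFit <- fitNullMixture(c(g$aHom, g$aHet), c(g$nHom, g$nHet))
  alt <- fitAltMixture(g$aHom, g$nHom, g$aHet, g$nHet, nullFit = nullFit)
  expect_lt(alt@logLik - nullFit@logLik, 2)
})

test_that("pure-component groups push the weights to opposite ends", {
  set.seed(11)
  nHomN <- 300; nHetN <- 200
  nh <- rnbinom(nHomN, mu = 40, size = 20) + 2L
  ah <- rbinom(nHomN, nh, rbeta(nHomN, 100, 100))
  nt <- rnbinom(nHetN, mu = 40, size = 20) + 2L
  at <- rbinom(nHetN, nt, rbeta(nHetN, 5, 5))
  alt <- fitAltMixture(ah, nh, at, nt)
  w <- mixtureWeights(alt)
  expect_gt(w[["hom"]], 0.9)   # hom samples sit in the balanced component
  expect_lt(w[["het"]], 0.1)   # het samples in the imbalanced one
})

test_that("alternative log-likelihood never falls below the null's", {
  for (seed in 1:8) {
    g <- simGroups(n = 120, maf = 0.3,
                   alphaHet = sample(c(5, 20, 100), 1), seed = seed)
    res <- aiqtlTest(g$aHom, g$nHom, g$aHet, g$nHet, mcControl)
    expect_gte(altFit(res)@logLik, nullFit(res)@logLik - 1e-6)
    expect_gte(lrtStat(res), 0)
  }
})

test_that("per-sample alpha hits its boundary cases with a flag", {
  balanced <- fitSampleAlpha(rep(100L, 30), rep(200L, 30))
  expect_true(balanced@boundary)
  expect_gt(balanced@alpha, 1e5)
  mono <- fitSampleAlpha(rep(c(0L, 150L), 15), rep(150L, 30))
  expect_true(mono@boundary)
  expect_lt(mono@alpha, 1e-2)
})

test_that("per-sample alpha is recovered from simulated genes", {
  set.seed(303)
  n <- rnbinom(800, mu = 30, size = 10)
  keep <- n >= 2
  n <- n[keep]
  a <- rbinom(length(n), n, rbeta(length(n), 20, 20))
  fit <- fitSampleAlpha(a, n, sampleId = "S1")
  expect_gt(fit@alpha, 16)
  expect_lt(fit@alpha, 25)
  expect_false(fit@boundary)
  # deterministic for fixed input
  fit2 <- fitSampleAlpha(a, n, sampleId = "S1")
  expect_identical(fit@alpha, fit2@alpha)
})

test_that("fitted objects pass their validity checks and accessors", {
  g <- simGroups(n = 200, alphaHet = 5, seed = 13)
  res <- aiqtlTest(g$aHom, g$nHom, g$aHet, g$nHet)
  expect_true(validObject(res))
  expect_true(validObject(nullFit(res)))
  expect_s4_class(altFit(res), "MixtureFit")
  expect_named(mixtureWeights(altFit(res)), c("hom", "het"))
  expect_named(alphaParams(nullFit(res)), c("alpha1", "alpha2"))
  ll <- logLik(altFit(res))
  expect_s3_class(ll, "logLik")
  expect_identical(attr(ll, "df"), 4L)
})
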