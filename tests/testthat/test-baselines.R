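# Comparator tests: binomial, threshold, wilcox, independent beta-binomial.

test_that("binomial method classifies by exact binomial test and Fisher-combines", {
  # perfectly balanced data: nobody is imbalanced, nothing to compare
  nHet <- rep(20L, 12); nHom <- rep(20L, 15)
  res <- binomialMethod(nHom / 2, nHom, nHet / 2, nHet)
  expect_identical(pValue(res), 1)
  expect_identical(unname(res@contingency[1, ]), c(0L, 0L))
  # per-sample two-sided p agrees with binom.test on a grid
  for (n in c(4L, 7L, 12L, 30L)) {
    for (a in 0:n) {
      expect_equal(aiqtl:::.binomTwoSidedP(a, n),
                   binom.test(a, n, 0.5)$p.value, tolerance = 1e-12,
                   label = sprintf("binom p a=%d n=%d", a, n))
    }
  }
})

test_that("Fisher group comparison matches the hypergeometric oracle", {
  # construct counts that classify to het {30 imb, 20 bal}, hom {5, 45}
  aHet <- c(rep(0L, 30), rep(10L, 20)); nHet <- rep(20L, 50)
  aHom <- c(rep(0L, 5), rep(10L, 45)); nHom <- rep(20L, 50)
  res <- binomialMethod(aHom, nHom, aHet, nHet)
  tab <- matrix(c(30L, 20L, 5L, 45L), nrow = 2)
  expect_identical(unname(res@contingency), tab)
  expect_equal(pValue(res), fisherEnumeration(tab), tolerance = 1e-10)
  expect_equal(pValue(res), fisher.test(tab)$p.value, tolerance = 1e-12)
})

test_that("shallow samples can never reach binomial significance", {
  # minimum two-sided p at n = 4 is 0.125 > 0.05: the depth bias the
  # mixture model avoids
  expect_equal(aiqtl:::.binomTwoSidedP(0L, 4L), 0.125, tolerance = 1e-12)
  res <- binomialMethod(c(0L, 0L, 0L), c(4L, 4L, 4L),
                        c(0L, 0L, 0L), c(4L, 4L, 4L))
  expect_identical(sum(res@contingency[1, ]), 0L)
})

test_that("threshold method uses strict 0.35/0.65 boundaries", {
  n <- rep(20L, 5)
  a <- c(6L, 10L, 13L, 7L, 14L)   # fractions 0.30 0.50 0.65 0.35 0.70
  res <- thresholdMethod(a, n, a, n)
  expect_identical(unname(res@contingency[1, ]), c(2L, 2L))  # 0.30 and 0.70
  allBal <- thresholdMethod(n / 2, n, n / 2, n)
  expect_identical(pValue(allBal), 1)
  expect_error(thresholdMethod(a, n, a, n, lo = 0.7, hi = 0.3),
               class = "aiqtl_domain_error")
  # mixed table agrees with the enumeration oracle
  aHet <- c(rep(1L, 8), rep(10L, 12)); nHet <- rep(20L, 20)
  aHom <- c(rep(1L, 2), rep(10L, 18)); nHom <- rep(20L, 20)
  res2 <- thresholdMethod(aHom, nHom, aHet, nHet)
  expect_equal(pValue(res2), fisherEnumeration(res2@contingency),
               tolerance = 1e-10)
})

test_that("wilcox method is exact for small groups and tie-robust", {
  # identical multisets of allele fractions: no evidence
  a <- c(2L, 5L, 9L); n <- c(10L, 10L, 10L)
  expect_identical(pValue(wilcoxMethod(a, n, a, n)), 1)
  # strong separation: p equals full 20-arrangement enumeration
  aHet <- c(9L, 8L, 17L); nHet <- c(10L, 10L, 20L)   # 0.9 0.8 0.85
  aHom <- c(10L, 13L, 12L); nHom <- c(20L, 25L, 25L) # 0.50 0.52 0.48
  res <- wilcoxMethod(aHom, nHom, aHet, nHet)
  expect_equal(pValue(res),
               wilcoxEnumeration(abs(aHet / nHet - 0.5),
                                 abs(aHom / nHom - 0.5)),
               tolerance = 1e-12)
  expect_equal(pValue(res), 0.1, tolerance = 1e-12)  # 2/20 arrangements
  # flipping any sample's allele label changes nothing
  resFlip <- wilcoxMethod(nHom - aHom, nHom, aHet, nHet)
  expect_identical(pValue(resFlip), pValue(res))
  # large groups use the tie-corrected normal approximation and agree
  # with wilcox.test
  g <- simGroups(n = 200, alphaHet = 10, seed = 17)
  res2 <- wilcoxMethod(g$aHom, g$nHom, g$aHet, g$nHet)
  ref <- suppressWarnings(
    wilcox.test(abs(g$aHet / g$nHet - 0.5), abs(g$aHom / g$nHom - 0.5),
                exact = FALSE))
  expect_equal(pValue(res2), ref$p.value, tolerance = 1e-12)
})

test_that("independent beta-binomial fits give a null LRT on shared data", {
  set.seed(23)
  n <- rnbinom(120, mu = 40, size = 20) + 2L
  a <- rbinom(120, n, rbeta(120, 30, 30))
  res <- indepBbTest(a[1:60], n[1:60], a[61:120], n[61:120])
  expect_lt(res@statistic, 4)
  expect_gt(pValue(res), 0.04)
  # identical groups: statistic collapses to zero
  resSame <- indepBbTest(a, n, a, n)
  expect_lt(resSame@statistic, 1e-6)
  # the shared fit is the same object fitSampleAlpha computes
  shared <- aiqtl:::.fitSingleAlpha(c(a, a), c(n, n), fitControl())
  pooled <- fitSampleAlpha(c(a, a), c(n, n))
  expect_equal(shared$logLik, pooled@logLik, tolerance = 1e-6)
})

test_that("a single deep outlier fools independent fits but not the mixture", {
  set.seed(29)
  nHomN <- 40; nHetN <- 40
  nh <- rnbinom(nHomN, mu = 30, size = 20) + 2L
  ah <- rbinom(nHomN, nh, rbeta(nHomN, 100, 100))
  nt <- rnbinom(nHetN, mu = 30, size = 20) + 2L
  at <- rbinom(nHetN, nt, rbeta(nHetN, 100, 100))
  # one heterozygote with extreme imbalance at very high coverage
  at <- c(at, 0L); nt <- c(nt, 5000L)
  indep <- indepBbTest(ah, nh, at, nt)
  mix <- aiqtlTest(ah, nh, at, nt)
  expect_lt(pValue(indep), 0.05)
  expect_gt(pValue(mix), 0.05)
})

test_that("all methods return valid objects with conserved margins", {
  g <- simGroups(n = 150, alphaHet = 20, seed = 19)
  for (res in list(binomialMethod(g$aHom, g$nHom, g$aHet, g$nHet),
                   thresholdMethod(g$aHom, g$nHom, g$aHet, g$nHet),
                   wilcoxMethod(g$aHom, g$nHom, g$aHet, g$nHet),
                   indepBbTest(g$aHom, g$nHom, g$aHet, g$nHet))) {
    expect_true(validObject(res))
    expect_gt(pValue(res), 0)
    expect_lte(pValue(res), 1)
  }
  expect_error(binomialMethod(integer(), integer(), g$aHet, g$nHet),
               class = "aiqtl_group_too_small")
})
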