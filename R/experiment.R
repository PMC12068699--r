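#' Test-function factories for simulation experiments
#'
#' `mixtureTestFn()` returns a closure `(aHom, nHom, aHet, nHet) -> p-value`
#' running [aiqtlTest()]; `baselineTestFns()` returns a named list of such
#' closures for the comparator methods. These are the `tests` argument of
#' [runExperiment()].
#'
#' @param control a [fitControl()] list for the model-based tests.
#' @param perSampleLevel per-sample significance level of the binomial
#'   comparator.
#' @return a function, or a named list of functions, mapping the two
#'   genotype groups' counts to a p-value.
#' @export
mixtureTestFn <- function(control = fitControl()) {
  force(control)
  function(aHom, nHom, aHet, nHet) {
    # evaluate before dispatch so classed fit errors propagate intact
    res <- aiqtlTest(aHom, nHom, aHet, nHet, control)
    pValue(res)
  }
}

#' @rdname mixtureTestFn
#' @export
baselineTestFns <- function(perSampleLevel = 0.05) {
  list(
    binomial = function(aHom, nHom, aHet, nHet) {
      res <- binomialMethod(aHom, nHom, aHet, nHet,
                            perSampleLevel = perSampleLevel)
      pValue(res)
    },
    threshold = function(aHom, nHom, aHet, nHet) {
      res <- thresholdMethod(aHom, nHom, aHet, nHet)
      pValue(res)
    },
    wilcox = function(aHom, nHom, aHet, nHet) {
      res <- wilcoxMethod(aHom, nHom, aHet, nHet)
      pValue(res)
    }
  )
}

.simulateDesign <- function(design, genotypes, cfg) {
  switch(design,
    two_negbin = simulateTwoNegbin(genotypes,
      foldChange = cfg$foldChange %||% 1,
      negbinMean = cfg$negbinMean %||% 30,
      negbinSize = cfg$negbinSize %||% 5),
    negbin_sbb = simulateNegbinSbb(genotypes,
      alphaHom = cfg$alphaHom %||% 100,
      alphaHet = cfg$alphaHet %||% 100,
      negbinMean = cfg$negbinMean %||% 30,
      negbinSize = cfg$negbinSize %||% 5),
    trans = simulateTransEqtl(genotypes,
      foldChange = cfg$foldChange %||% 1.5,
      alpha = cfg$alphaHom %||% 100,
      negbinMean = cfg$negbinMean %||% 30,
      negbinSize = cfg$negbinSize %||% 5,
      dosageModel = cfg$dosageModel %||% "multiplicative"),
    .aiqtlStop(sprintf("unknown design '%s'", design), "aiqtl_domain_error")
  )
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x

#' Run a simulation experiment over a parameter grid
#'
#' For each grid row, simulates `nReps` replicate datasets under the given
#' design and applies each test, reporting the fraction of replicates
#' rejected at the nominal `level` with its Monte-Carlo standard error.
#' Per-replicate seeds are derived deterministically from
#' `(seed, grid row, replicate index)`, so identical calls are
#' bit-reproducible. Fitting failures are counted (`nFailed`), never
#' silently dropped.
#'
#' @param design one of `"two_negbin"`, `"negbin_sbb"`, `"trans"`.
#' @param grid data.frame, one row per condition; recognised columns
#'   (all optional): `nIndividuals` (default 670), `maf` (default 0.1),
#'   `foldChange`, `alphaHom`, `alphaHet`, `negbinMean`, `negbinSize`,
#'   `dosageModel`.
#' @param tests named list of functions `(aHom, nHom, aHet, nHet) -> p`;
#'   see [mixtureTestFn()].
#' @param nReps replicates per grid row (at least 50).
#' @param level nominal significance level.
#' @param seed master seed.
#' @param keepPvalues when TRUE the returned table carries an attribute
#'   `"replicates"`, a long data.frame of per-replicate p-values (needed
#'   for calibration diagnostics such as QQ slopes).
#' @return a data.frame with one row per (grid row, test): the grid
#'   columns plus `design`, `test`, `rejectionRate`, `mcSe`, `nOk`,
#'   `nFailed`.
#' @examples
#' runExperiment("negbin_sbb",
#'   data.frame(nIndividuals = 100, maf = 0.3, alphaHet = 5),
#'   tests = list(mixture = mixtureTestFn()), nReps = 50, seed = 1)
#' @export
runExperiment <- function(design, grid, tests = list(mixture = mixtureTestFn()),
                          nReps = 200L, level = 0.05, seed = 1L,
                          keepPvalues = FALSE) {
  nReps <- as.integer(nReps)
  if (nReps < 50L)
    .aiqtlStop("nReps must be at least 50", "aiqtl_domain_error")
  if (is.null(names(tests)) || any(names(tests) == ""))
    .aiqtlStop("tests must be a named list", "aiqtl_domain_error")
  if (nrow(grid) == 0L) {
    out <- data.frame(design = character(), test = character(),
                      rejectionRate = numeric(), mcSe = numeric(),
                      nOk = integer(), nFailed = integer())
    if (keepPvalues) attr(out, "replicates") <- data.frame()
    return(out)
  }
  rows <- list(); reps <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- as.list(grid[g, , drop = FALSE])
    nInd <- cfg$nIndividuals %||% 670L
    maf <- cfg$maf %||% 0.1
    pmat <- matrix(NA_real_, nrow = nReps, ncol = length(tests),
                   dimnames = list(NULL, names(tests)))
    for (r in seq_len(nReps)) {
      set.seed(.deriveSeed(seed, g, r))
      gt <- simulateGenotypes(nInd, maf)
      sim <- .simulateDesign(design, gt, cfg)
      het <- sim$cls == "HET"
      for (tn in names(tests)) {
        pmat[r, tn] <- tryCatch(
          tests[[tn]](sim$aCount[!het], sim$totalCount[!het],
                      sim$aCount[het], sim$totalCount[het]),
          aiqtl_error = function(e) NA_real_)
      }
    }
    for (tn in names(tests)) {
      p <- pmat[, tn]
      ok <- sum(!is.na(p))
      rate <- if (ok > 0) mean(p < level, na.rm = TRUE) else NA_real_
      rows[[length(rows) + 1L]] <- cbind(
        grid[g, , drop = FALSE],
        data.frame(design = design, test = tn, rejectionRate = rate,
                   mcSe = if (ok > 0) sqrt(rate * (1 - rate) / ok) else NA_real_,
                   nOk = ok, nFailed = nReps - ok,
                   row.names = NULL))
    }
    if (keepPvalues) {
      reps[[g]] <- data.frame(gridRow = g,
                              rep = rep(seq_len(nReps), length(tests)),
                              test = rep(names(tests), each = nReps),
                              p = as.vector(pmat))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keepPvalues) attr(out, "replicates") <- do.call(rbind, reps)
  out
}

#' QQ slope of likelihood-ratio p-values against chi-squared
#'
#' Converts p-values back to likelihood-ratio statistics and regresses
#' (through the origin) their empirical quantiles on chi-squared
#' theoretical quantiles over the central 99% of probability points. A
#' well-calibrated test gives a slope near 1.
#'
#' @param p vector of p-values from replicate null tests.
#' @param df chi-squared reference degrees of freedom.
#' @return the QQ slope, a single number.
#' @export
lrtQqSlope <- function(p, df = 1L) {
  p <- p[!is.na(p)]
  stat <- qchisq(p, df = df, lower.tail = FALSE)
  probs <- seq(0.005, 0.995, by = 0.005)
  emp <- quantile(stat, probs, names = FALSE, type = 7)
  theo <- qchisq(probs, df = df)
  unname(coef(lm(emp ~ 0 + theo))[1])
}
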