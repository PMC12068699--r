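#' Write a small example dataset to disk
#'
#' Generates a single-gene, single-variant dataset with recorded ground
#' truth and writes `counts.tsv`, `genotypes.tsv`, `pairs.tsv` and
#' `truth.json` into `dir`. Kinds: `"cis_strong"` (strong genotype-
#' dependent imbalance: heterozygotes drawn with dispersion 3 against 100
#' in homozygotes), `"null"` (shared dispersion 100) and `"trans"` (a
#' trans effect: expression scales with dosage, allelic split balanced).
#'
#' @param kind `"cis_strong"`, `"null"` or `"trans"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n number of individuals.
#' @return invisibly, a named list of the written file paths.
#' @export
makeFixture <- function(kind = c("cis_strong", "null", "trans"),
                        dir, seed = 1L, n = 150L) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gt <- simulateGenotypes(n, maf = 0.3, seed = seed)
  sim <- switch(kind,
    cis_strong = simulateNegbinSbb(gt, alphaHom = 100, alphaHet = 3,
                                   negbinMean = 60, negbinSize = 20),
    null = simulateNegbinSbb(gt, alphaHom = 100, alphaHet = 100,
                             negbinMean = 60, negbinSize = 20),
    trans = simulateTransEqtl(gt, foldChange = 1.5, alpha = 100,
                              negbinMean = 60, negbinSize = 20))
  counts <- sim[, c("sampleId", "geneId", "aCount", "totalCount")]
  genotypes <- data.frame(variantId = "var1", sampleId = gt$sampleId,
                          cls = as.character(gt$cls))
  informative <- counts$totalCount >= 2L
  pairs <- data.frame(
    variantId = "var1", geneId = "gene1",
    tssDistance = 1000L, maf = 0.3, eqtlLog10P = -10,
    nInformativeSamples = sum(informative),
    medianReads = median(counts$totalCount[informative]))
  paths <- list(counts = file.path(dir, "counts.tsv"),
                genotypes = file.path(dir, "genotypes.tsv"),
                pairs = file.path(dir, "pairs.tsv"),
                truth = file.path(dir, "truth.json"))
  writeTsv(counts, paths$counts)
  writeTsv(genotypes, paths$genotypes)
  writeTsv(pairs, paths$pairs)
  jsonlite::write_json(
    c(list(kind = kind, seed = seed, n = n, truth = attr(sim, "truth")),
      attr(sim, "trueParams")),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
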