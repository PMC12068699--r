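#' Keep the strongest eQTL per gene
#'
#' When several variants are associated with one gene, keeps the record
#' with the most extreme (smallest, i.e. most negative `log10` p)
#' association. Ties are broken deterministically by smallest absolute
#' TSS distance, then lexicographic variant identifier.
#'
#' @param records data.frame with at least `variantId`, `geneId`,
#'   `eqtlLog10P`; `tssDistance` is used for tie-breaking when present.
#' @return a data.frame with exactly one row per gene (empty in, empty out).
#' @export
selectTopEqtlPerGene <- function(records) {
  if (nrow(records) == 0L) return(records)
  .checkCols(records, c("variantId", "geneId", "eqtlLog10P"), "eQTL records")
  absDist <- if ("tssDistance" %in% names(records))
    abs(records$tssDistance) else rep(0, nrow(records))
  ord <- order(records$geneId, records$eqtlLog10P, absDist,
               as.character(records$variantId))
  out <- records[ord, , drop = FALSE]
  out <- out[!duplicated(out$geneId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan gene-variant pairs for aiQTLs
#'
#' Runs [aiqtlTest()] for every pair: the gene's counts are joined to the
#' variant's genotype classes on `sampleId` (rows ordered by `sampleId`,
#' so results do not depend on input row order). Pairs that cannot be
#' tested are reported with a reason code (`insufficient_het`,
#' `insufficient_hom`, `insufficient_obs`, `join_failure`, `fit_error`),
#' never dropped: every input pair appears exactly once in the output.
#'
#' @param counts data.frame of observations (`sampleId`, `geneId`,
#'   `aCount`, `totalCount`), as from [readCounts()].
#' @param genotypes data.frame of genotype classes (`variantId`,
#'   `sampleId`, `cls` with values `"HET"`/`"HOM"`), as from
#'   [readGenotypeClasses()].
#' @param pairs data.frame with `variantId` and `geneId`; any further
#'   columns (e.g. the eQTL covariates used by [fitDistanceLogistic()])
#'   are carried through to the output.
#' @param control a [fitControl()] list.
#' @param level significance level for the `detected` flag (default 0.01).
#' @param adjust multiple-testing adjustment applied across tested pairs
#'   before flagging detection: `"none"`, `"holm"` or `"bh"`.
#' @return a data.frame with one row per pair: the `pairs` columns plus
#'   `nHet`, `nHom`, `lrtStat`, `df`, `pValue`, `pAdjusted`, `status`
#'   (`"ok"`/`"skipped"`), `reason` and `detected`. Attributes `level`
#'   and `adjustment` record the detection rule.
#' @export
runAiqtlScan <- function(counts, genotypes, pairs, control = fitControl(),
                         level = 0.01, adjust = c("none", "holm", "bh")) {
  adjust <- match.arg(adjust)
  .checkCols(counts, c("sampleId", "geneId", "aCount", "totalCount"),
             "counts")
  .checkCols(genotypes, c("variantId", "sampleId", "cls"), "genotypes")
  .checkCols(pairs, c("variantId", "geneId"), "pairs")
  out <- pairs
  n <- nrow(pairs)
  out$nHet <- out$nHom <- rep(NA_integer_, n)
  out$lrtStat <- out$pValue <- rep(NA_real_, n)
  out$df <- rep(NA_integer_, n)
  out$status <- rep("skipped", n)
  out$reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cg <- counts[counts$geneId == pairs$geneId[i], , drop = FALSE]
    gt <- genotypes[genotypes$variantId == pairs$variantId[i], , drop = FALSE]
    m <- merge(cg, gt[, c("sampleId", "cls")], by = "sampleId")
    if (nrow(m) == 0L) { out$reason[i] <- "join_failure"; next }
    m <- m[order(m$sampleId), , drop = FALSE]
    het <- m$cls == "HET"
    out$nHet[i] <- sum(het); out$nHom[i] <- sum(!het)
    res <- tryCatch(
      aiqtlTest(m$aCount[!het], m$totalCount[!het],
                m$aCount[het], m$totalCount[het], control),
      aiqtl_group_too_small = function(e)
        paste0("insufficient_", e$group %||% "group"),
      aiqtl_too_few_obs = function(e) "insufficient_obs",
      aiqtl_error = function(e) "fit_error")
    if (is.character(res)) { out$reason[i] <- res; next }
    out$status[i] <- "ok"
    out$lrtStat[i] <- lrtStat(res)
    out$df[i] <- res@df
    out$pValue[i] <- pValue(res)
    out$nHet[i] <- res@nHet; out$nHom[i] <- res@nHom
  }
  method <- c(none = "none", holm = "holm", bh = "BH")[[adjust]]
  out$pAdjusted <- if (method == "none") out$pValue
                   else p.adjust(out$pValue, method = method)
  out$detected <- !is.na(out$pAdjusted) & out$pAdjusted < level
  attr(out, "level") <- level
  attr(out, "adjustment") <- adjust
  rownames(out) <- NULL
  out
}
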