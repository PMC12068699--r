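#' Per-sample imbalance summaries with covariate associations
#'
#' Fits a single symmetric beta-binomial dispersion per sample (see
#' [fitSampleAlpha()]) and, when sample metadata are supplied, tests for
#' association between the per-sample alpha and each covariate within
#' each tissue: Spearman rank correlation for numeric covariates, a
#' Wilcoxon rank-sum test for two-level covariates. P-values are adjusted
#' across tissues within each covariate by the Holm method. Note this
#' summary responds to *all* sources of imbalance — cis-regulatory
#' variation, imprinting and random monoallelic expression alike.
#'
#' @param counts data.frame of observations (`sampleId`, `geneId`,
#'   `aCount`, `totalCount`).
#' @param metadata optional data.frame with `sampleId`, a tissue column,
#'   and covariate columns (age, sex, cell-type proportions, ...).
#' @param control a [fitControl()] list.
#' @param tissueCol name of the tissue column in `metadata`.
#' @param minPerTissue minimum samples in a tissue for association tests.
#' @return a list of class `"sampleAlphaSummary"`: `$samples`, one row
#'   per sample (`sampleId`, `alpha`, `nObs`, `logLik`, `boundary`, plus
#'   metadata columns), and `$associations`, one row per
#'   (tissue, covariate) with `estimate` (Spearman rho or rank-sum W),
#'   `test`, `pValue` and Holm-adjusted `pHolm`. Samples whose fit is not
#'   possible (too few informative genes) are listed with `NA` alpha.
#' @export
summarizeSampleAlpha <- function(counts, metadata = NULL,
                                 control = fitControl(),
                                 tissueCol = "tissue",
                                 minPerTissue = 8L) {
  .checkCols(counts, c("sampleId", "geneId", "aCount", "totalCount"),
             "counts")
  ids <- unique(counts$sampleId)
  rows <- lapply(ids, function(id) {
    cc <- counts[counts$sampleId == id, , drop = FALSE]
    fit <- tryCatch(
      fitSampleAlpha(cc$aCount, cc$totalCount, sampleId = id, control),
      aiqtl_error = function(e) NULL)
    if (is.null(fit))
      data.frame(sampleId = id, alpha = NA_real_, nObs = nrow(cc),
                 logLik = NA_real_, boundary = NA)
    else
      data.frame(sampleId = id, alpha = fit@alpha, nObs = fit@nObs,
                 logLik = fit@logLik, boundary = fit@boundary)
  })
  samples <- do.call(rbind, rows)
  assoc <- data.frame(tissue = character(), covariate = character(),
                      test = character(), estimate = numeric(),
                      pValue = numeric(), pHolm = numeric())
  if (!is.null(metadata)) {
    .checkCols(metadata, "sampleId", "metadata")
    unmatched <- setdiff(samples$sampleId, metadata$sampleId)
    if (length(unmatched))
      message(length(unmatched), " sample(s) missing from metadata")
    samples <- merge(samples, metadata, by = "sampleId", all.x = TRUE,
                     sort = TRUE)
    if (tissueCol %in% names(metadata) && nrow(samples) > 1L) {
      covars <- setdiff(names(metadata), c("sampleId", tissueCol))
      res <- list()
      for (cv in covars) {
        for (ts in sort(unique(samples[[tissueCol]]))) {
          d <- samples[!is.na(samples[[tissueCol]]) &
                         samples[[tissueCol]] == ts &
                         !is.na(samples$alpha) & !is.na(samples[[cv]]), ]
          if (nrow(d) < minPerTissue) next
          x <- d[[cv]]
          if (is.numeric(x) && length(unique(x)) > 2L) {
            ct <- suppressWarnings(
              cor.test(d$alpha, x, method = "spearman"))
            res[[length(res) + 1L]] <- data.frame(
              tissue = ts, covariate = cv, test = "spearman",
              estimate = unname(ct$estimate), pValue = ct$p.value)
          } else if (length(unique(x)) == 2L) {
            f <- factor(x)
            wt <- suppressWarnings(
              wilcox.test(d$alpha[f == levels(f)[1]],
                          d$alpha[f == levels(f)[2]]))
            res[[length(res) + 1L]] <- data.frame(
              tissue = ts, covariate = cv, test = "wilcoxon",
              estimate = unname(wt$statistic), pValue = wt$p.value)
          }
        }
      }
      if (length(res)) {
        assoc <- do.call(rbind, res)
        assoc$pHolm <- NA_real_
        for (cv in unique(assoc$covariate)) {
          sel <- assoc$covariate == cv
          assoc$pHolm[sel] <- p.adjust(assoc$pValue[sel], method = "holm")
        }
      }
    }
  }
  structure(list(samples = samples, associations = assoc),
            class = "sampleAlphaSummary")
}

#' @export
print.sampleAlphaSummary <- function(x, ...) {
  ok <- !is.na(x$samples$alpha)
  cat(sprintf("Per-sample imbalance summary: %d samples (%d fitted)\n",
              nrow(x$samples), sum(ok)))
  if (any(ok)) {
    q <- quantile(x$samples$alpha[ok], c(0.25, 0.5, 0.75))
    cat(sprintf("  alpha quartiles: %.3g / %.3g / %.3g\n", q[1], q[2], q[3]))
  }
  if (nrow(x$associations))
    cat(sprintf("  %d covariate association test(s); %d with Holm p < 0.05\n",
                nrow(x$associations), sum(x$associations$pHolm < 0.05)))
  invisible(x)
}
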