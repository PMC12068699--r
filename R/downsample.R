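#' Downsampling analysis of aiQTL detection
#'
#' Repeatedly subsamples individuals without replacement at each requested
#' size, re-runs the aiQTL scan, and tracks which of the pairs detected in
#' the full scan remain detected. The summary reports the detected
#' fraction with twice its standard error (an approximate 95% band),
#' which shows how detection saturates (or fails to) with cohort size.
#'
#' @inheritParams runAiqtlScan
#' @param sizes integer vector of subsample sizes (each at most the number
#'   of available samples).
#' @param nDraws subsamples drawn per size.
#' @param seed master seed; draw-level seeds are derived deterministically.
#' @return a list of class `"downsampleScan"`: `$fullScan` (the full-data
#'   scan), `$replicates` (one row per size x draw x pair, with `pValue`
#'   and `detected`), and `$summary` (one row per size x draw:
#'   `detectedFraction` over all pairs, `fractionOfFull` over the
#'   full-scan detections, and `se2 = 2 * sqrt(f(1-f)/n)`).
#' @export
downsampleScan <- function(counts, genotypes, pairs, sizes, nDraws = 1L,
                           seed = 1L, control = fitControl(), level = 0.01,
                           adjust = "none") {
  samples <- sort(unique(counts$sampleId))
  if (any(sizes > length(samples)))
    .aiqtlStop(sprintf("sizes must not exceed the %d available samples",
                       length(samples)), "aiqtl_domain_error")
  if (any(sizes < 1L))
    .aiqtlStop("sizes must be positive", "aiqtl_domain_error")
  full <- runAiqtlScan(counts, genotypes, pairs, control, level, adjust)
  fullKey <- paste(full$variantId, full$geneId)
  detectedKey <- fullKey[full$detected]
  repRows <- list(); sumRows <- list()
  for (s in sort(unique(as.integer(sizes)))) {
    for (d in seq_len(nDraws)) {
      set.seed(.deriveSeed(seed, s, d))
      keep <- sample(samples, s)
      sc <- runAiqtlScan(counts[counts$sampleId %in% keep, , drop = FALSE],
                         genotypes[genotypes$sampleId %in% keep, , drop = FALSE],
                         pairs, control, level, adjust)
      key <- paste(sc$variantId, sc$geneId)
      repRows[[length(repRows) + 1L]] <- data.frame(
        size = s, draw = d, variantId = sc$variantId, geneId = sc$geneId,
        pValue = sc$pValue, detected = sc$detected)
      f <- mean(sc$detected)
      fFull <- if (length(detectedKey))
        mean(sc$detected[key %in% detectedKey]) else NA_real_
      sumRows[[length(sumRows) + 1L]] <- data.frame(
        size = s, draw = d, nPairs = nrow(sc),
        detectedFraction = f,
        fractionOfFull = fFull,
        se2 = 2 * sqrt(f * (1 - f) / nrow(sc)))
    }
  }
  structure(list(fullScan = full,
                 replicates = do.call(rbind, repRows),
                 summary = do.call(rbind, sumRows)),
            class = "downsampleScan")
}

#' @export
print.downsampleScan <- function(x, ...) {
  cat(sprintf("Downsampling scan: %d pairs, %d detected at full size\n",
              nrow(x$fullScan), sum(x$fullScan$detected)))
  print(x$summary, digits = 3)
  invisible(x)
}
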