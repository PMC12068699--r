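# Readers and writers for the package's tab-separated formats.
# Dialect: tab-separated, header required, UTF-8, '.' for missing values.

.readTsv <- function(path, what) {
  if (!file.exists(path))
    .aiqtlStop(sprintf("%s: file not found: %s", what, path),
               "aiqtl_io_error")
  read.delim(path, sep = "\t", header = TRUE, na.strings = c("NA", "."),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a counts table
#'
#' Reads per-sample, per-gene allele-specific read counts from a
#' tab-separated file with header columns `sampleId`, `geneId`, `aCount`,
#' `totalCount` and optionally `siteId` (when counts were produced per
#' transcribed SNP rather than per gene). When a (sample, gene) pair has
#' several sites, the default `max_coverage` policy keeps the site with
#' the largest total count — summing sites could double-count fragments,
#' and haplotype-aware summing would require the phasing this method
#' deliberately avoids; dropped rows are reported via `message()`.
#'
#' @param path file path.
#' @param sitePolicy `"max_coverage"` (default) or `"error_on_multi"`.
#' @return a data.frame with columns `sampleId`, `geneId`, `aCount`,
#'   `totalCount` (and `siteId` if present), one row per (sample, gene).
#' @export
readCounts <- function(path, sitePolicy = c("max_coverage", "error_on_multi")) {
  sitePolicy <- match.arg(sitePolicy)
  d <- .readTsv(path, "counts")
  .checkCols(d, c("sampleId", "geneId", "aCount", "totalCount"), "counts")
  bad <- which(!is.finite(d$aCount) | !is.finite(d$totalCount) |
                 d$aCount < 0 | d$totalCount < 1 | d$aCount > d$totalCount)
  if (length(bad))
    .aiqtlStop(sprintf(
      "counts: invalid a_count/total_count at data line(s) %s",
      paste(head(bad, 5L), collapse = ", ")), "aiqtl_format_error")
  d$aCount <- as.integer(d$aCount); d$totalCount <- as.integer(d$totalCount)
  keyCols <- c("sampleId", "geneId", if ("siteId" %in% names(d)) "siteId")
  key <- do.call(paste, c(d[keyCols], sep = "\r"))
  if (anyDuplicated(key))
    .aiqtlStop(sprintf("counts: duplicate (%s) rows",
                       paste(keyCols, collapse = ", ")),
               "aiqtl_format_error")
  pairKey <- paste(d$sampleId, d$geneId, sep = "\r")
  if (anyDuplicated(pairKey)) {
    if (sitePolicy == "error_on_multi")
      .aiqtlStop("counts: multiple sites per (sample, gene)",
                 "aiqtl_format_error")
    ord <- order(pairKey, -d$totalCount,
                 if ("siteId" %in% names(d)) d$siteId else d$aCount)
    d <- d[ord, , drop = FALSE]
    dup <- duplicated(paste(d$sampleId, d$geneId, sep = "\r"))
    message(sum(dup), " multi-site row(s) dropped (max_coverage policy)")
    d <- d[!dup, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Write a counts table
#'
#' @param x data.frame as returned by [readCounts()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path) {
  writeTsv(x, path)
}

#' Write a data.frame as a tab-separated file
#'
#' Tab-separated, header, no quoting, `.` for missing — the package's
#' round-trippable dialect.
#'
#' @param x a data.frame.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read genotype classes at candidate variants
#'
#' Accepts either a VCF (classified from the GT field; requires the
#' VariantAnnotation package) or a tab-separated table. For VCF input,
#' `0/1`, `1/0` and their phased equivalents map to `HET`; `0/0` and
#' `1/1` (phased likewise) to `HOM`; missing genotypes and genotypes
#' involving alleles other than the designated ref/alt pair are excluded
#' with a `message()`. For TSV input the file must have `sampleId` plus
#' either a `cls` column (`HET`/`HOM`) or a `dosage` column (0/1/2, which
#' pools 0 and 2 into `HOM`); a `variantId` column is optional when the
#' file describes a single variant.
#'
#' @param path VCF or TSV file path.
#' @param variantId optional variant identifier(s) to keep; for TSV input
#'   without a `variantId` column it names the single variant described.
#' @return a data.frame with columns `variantId`, `sampleId`, `cls`.
#' @export
readGenotypeClasses <- function(path, variantId = NULL) {
  isVcf <- grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE) ||
    (file.exists(path) &&
       startsWith(readLines(path, n = 1L, warn = FALSE), "##fileformat=VCF"))
  d <- if (isVcf) .readGenotypesVcf(path) else .readGenotypesTsv(path, variantId)
  if (!is.null(variantId)) {
    d <- d[d$variantId %in% variantId, , drop = FALSE]
    if (nrow(d) == 0L)
      .aiqtlStop("variant not found (or all genotypes missing)",
                 "aiqtl_io_error")
  }
  rownames(d) <- NULL
  d
}

.readGenotypesVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    .aiqtlStop("VCF input requires the VariantAnnotation package",
               "aiqtl_io_error")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gtm <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtm))
    .aiqtlStop("VCF has no GT field", "aiqtl_format_error")
  rows <- list()
  excluded <- 0L
  for (v in seq_len(nrow(gtm))) {
    gt <- gsub("\\|", "/", gtm[v, ])
    cls <- ifelse(gt %in% c("0/1", "1/0"), "HET",
                  ifelse(gt %in% c("0/0", "1/1"), "HOM", NA))
    excluded <- excluded + sum(is.na(cls))
    keep <- !is.na(cls)
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      variantId = rownames(gtm)[v], sampleId = colnames(gtm)[keep],
      cls = cls[keep], stringsAsFactors = FALSE)
  }
  if (excluded > 0L)
    message(excluded, " genotype(s) excluded (missing or non ref/alt)")
  if (!length(rows))
    .aiqtlStop("no classifiable genotypes in VCF", "aiqtl_io_error")
  do.call(rbind, rows)
}

.readGenotypesTsv <- function(path, variantId) {
  d <- .readTsv(path, "genotypes")
  .checkCols(d, "sampleId", "genotypes")
  if (!"variantId" %in% names(d)) {
    if (is.null(variantId) || length(variantId) != 1L)
      .aiqtlStop("genotype TSV lacks variantId; supply variantId=",
                 "aiqtl_format_error")
    d$variantId <- variantId
  }
  if ("cls" %in% names(d)) {
    bad <- !is.na(d$cls) & !d$cls %in% c("HET", "HOM")
    if (any(bad))
      .aiqtlStop("genotypes: cls must be HET or HOM", "aiqtl_format_error")
  } else if ("dosage" %in% names(d)) {
    if (!all(is.na(d$dosage) | d$dosage %in% 0:2))
      .aiqtlStop("genotypes: dosage must be 0, 1 or 2", "aiqtl_format_error")
    d$cls <- ifelse(d$dosage == 1L, "HET", "HOM")
  } else {
    .aiqtlStop("genotypes: need a cls or dosage column", "aiqtl_format_error")
  }
  drop <- is.na(d$cls)
  if (any(drop))
    message(sum(drop), " sample(s) excluded (missing genotype)")
  d[!drop, c("variantId", "sampleId", "cls")]
}

#' Read an eQTL pair table
#'
#' Tab-separated table of candidate gene-variant pairs with the optional
#' covariates used by the distance model: `tssDistance` (signed bp,
#' negative = upstream of the TSS), `maf`, `eqtlLog10P` (log10 of the
#' eQTL association p-value), `nInformativeSamples`, `medianReads`.
#'
#' @param path file path.
#' @return a validated data.frame with at least `variantId`, `geneId`.
#' @export
readEqtlPairs <- function(path) {
  d <- .readTsv(path, "eQTL pairs")
  .checkCols(d, c("variantId", "geneId"), "eQTL pairs")
  if ("maf" %in% names(d) &&
      any(!is.na(d$maf) & (d$maf <= 0 | d$maf > 0.5)))
    .aiqtlStop("eQTL pairs: maf must lie in (0, 0.5]", "aiqtl_format_error")
  d
}

# Reproducibility log written next to every CLI output: configuration,
# seed, versions and input digests are enough to re-run the result.
.writeRunLog <- function(outPath, subcommand, opts, inputs = character()) {
  digests <- lapply(inputs[file.exists(inputs)], function(f)
    unname(tools::md5sum(f)))
  names(digests) <- inputs[file.exists(inputs)]
  log <- list(
    subcommand = subcommand,
    options = opts,
    rVersion = as.character(getRversion()),
    packageVersion = as.character(packageVersion("aiqtl")),
    inputDigests = digests,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(log, paste0(outPath, ".run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
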