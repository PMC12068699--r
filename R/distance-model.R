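#' Logistic model for aiQTL detection versus distance to TSS
#'
#' Models the probability that an eQTL is detected as an aiQTL as a
#' function of its distance from the gene's transcription start site and
#' of power-related covariates (number of informative samples, median
#' allele-mapped read depth, minor allele frequency, eQTL association
#' strength). Distance enters as `|tssDistance|` with a separate slope for
#' variants upstream and downstream of the TSS (a signed-distance
#' interaction; the two sides share the intercept so the curve is
#' continuous at the TSS), because long-range cis action need not decay
#' symmetrically.
#'
#' @param scan data.frame with a logical response column (default
#'   `detected`, as produced by [runAiqtlScan()]) and covariates
#'   `tssDistance`, `nInformativeSamples`, `medianReads`, `maf`,
#'   `eqtlLog10P`. Rows with missing values are dropped.
#' @param minRows minimum usable rows (default 50).
#' @return an object of class `"aiqtlDistanceModel"`: a list with the
#'   fitted `glm` (`$model`), a tidy `$coefficients` table, `$n` and any
#'   fitting `$warnings`.
#' @seealso [predictAiqtlProbability()]
#' @export
fitDistanceLogistic <- function(scan, minRows = 50L) {
  .checkCols(scan, c("detected", "tssDistance", "nInformativeSamples",
                     "medianReads", "maf", "eqtlLog10P"),
             "distance model input")
  d <- scan[, c("detected", "tssDistance", "nInformativeSamples",
                "medianReads", "maf", "eqtlLog10P")]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < minRows)
    .aiqtlStop(sprintf("need at least %d complete rows, have %d",
                       minRows, nrow(d)), "aiqtl_too_few_obs")
  if (length(unique(d$detected)) < 2L)
    .aiqtlStop("response is constant: model is inestimable (separation)",
               "aiqtl_separation")
  d$absDistance <- abs(d$tssDistance)
  d$side <- factor(ifelse(d$tssDistance >= 0, "downstream", "upstream"),
                   levels = c("downstream", "upstream"))
  warns <- character()
  fit <- withCallingHandlers(
    glm(detected ~ absDistance:side + nInformativeSamples + medianReads +
          maf + eqtlLog10P,
        family = binomial(), data = d),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    .aiqtlStop("logistic fit did not converge (possible separation)",
               "aiqtl_separation", diagnostics = warns)
  cf <- coef(fit)
  if (anyNA(cf))
    .aiqtlStop(paste("rank-deficient fit; aliased terms:",
                     paste(names(cf)[is.na(cf)], collapse = ", ")),
               "aiqtl_rank_deficient")
  sm <- summary(fit)$coefficients
  structure(list(
    model = fit,
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], z = sm[, 3], pValue = sm[, 4],
                              row.names = NULL),
    n = nrow(d),
    warnings = warns
  ), class = "aiqtlDistanceModel")
}

#' @export
print.aiqtlDistanceModel <- function(x, ...) {
  cat(sprintf("Logistic model of aiQTL detection (%d pairs)\n", x$n))
  print(x$coefficients, digits = 3)
  if (length(x$warnings))
    cat("Fitting warnings:", paste(unique(x$warnings), collapse = "; "), "\n")
  invisible(x)
}

#' Predicted aiQTL detection probability
#'
#' Inverse-logit of the fitted linear predictor at the supplied covariate
#' values, over a grid of signed TSS distances. Used to read off, e.g.,
#' the detection probability at the TSS versus 500 kb away for a strong
#' eQTL in a well-powered study.
#'
#' @param object an `"aiqtlDistanceModel"` from [fitDistanceLogistic()].
#' @param covariates named list or one-row data.frame supplying
#'   `nInformativeSamples`, `medianReads`, `maf`, `eqtlLog10P`.
#' @param distance numeric vector of signed TSS distances (negative =
#'   upstream) at which to predict.
#' @return numeric vector of probabilities in `(0, 1)`, one per distance.
#' @examples
#' \dontrun{
#' predictAiqtlProbability(m,
#'   list(nInformativeSamples = 500, medianReads = 30, maf = 0.05,
#'        eqtlLog10P = -20),
#'   distance = c(0, -5e5))
#' }
#' @export
predictAiqtlProbability <- function(object, covariates, distance = 0) {
  if (!inherits(object, "aiqtlDistanceModel"))
    .aiqtlStop("object must come from fitDistanceLogistic()",
               "aiqtl_domain_error")
  covariates <- as.list(covariates)
  need <- c("nInformativeSamples", "medianReads", "maf", "eqtlLog10P")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    .aiqtlStop(paste("missing covariate(s):", paste(miss, collapse = ", ")),
               "aiqtl_domain_error")
  nd <- data.frame(
    absDistance = abs(distance),
    side = factor(ifelse(distance >= 0, "downstream", "upstream"),
                  levels = c("downstream", "upstream")),
    nInformativeSamples = covariates$nInformativeSamples,
    medianReads = covariates$medianReads,
    maf = covariates$maf,
    eqtlLog10P = covariates$eqtlLog10P
  )
  as.numeric(predict(object$model, newdata = nd, type = "response"))
}
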