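#' @rdname accessors
setMethod("pValue", "AiqtlTest", function(object) object@pValue)

#' @rdname accessors
setMethod("pValue", "BaselineResult", function(object) object@pValue)

#' @rdname accessors
setMethod("lrtStat", "AiqtlTest", function(object) object@lrtStat)

#' @rdname accessors
setMethod("mixtureWeights", "MixtureFit", function(object) object@weights)

#' @rdname accessors
setMethod("alphaParams", "MixtureFit", function(object)
  c(alpha1 = object@alpha1, alpha2 = object@alpha2))

#' @rdname accessors
setMethod("alphaParams", "SampleAlphaFit", function(object)
  c(alpha = object@alpha))

#' @rdname accessors
setMethod("nullFit", "AiqtlTest", function(object) object@nullFit)

#' @rdname accessors
setMethod("altFit", "AiqtlTest", function(object) object@altFit)

#' Log-likelihood of a mixture fit
#'
#' @param object a [MixtureFit-class] or [SampleAlphaFit-class].
#' @param ... ignored.
#' @return an object of class `"logLik"` with `df` and `nobs` attributes.
#' @export
setMethod("logLik", "MixtureFit", function(object, ...) {
  structure(object@logLik,
            df = 2L + length(object@weights),
            nobs = object@nObs, class = "logLik")
})

#' @rdname logLik-MixtureFit-method
#' @export
setMethod("logLik", "SampleAlphaFit", function(object, ...) {
  structure(object@logLik, df = 1L, nobs = object@nObs, class = "logLik")
})

#' @export
setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("Symmetric beta-binomial mixture (%s model), %d observations\n",
              object@model, object@nObs))
  cat(sprintf("  alpha1 (balanced):   %.4g%s\n", object@alpha1,
              if (isTRUE(object@boundary[["alpha1"]])) " [at bound]" else ""))
  cat(sprintf("  alpha2 (imbalanced): %.4g%s\n", object@alpha2,
              if (isTRUE(object@boundary[["alpha2"]])) " [at bound]" else ""))
  w <- paste(sprintf("%s = %.3f", names(object@weights), object@weights),
             collapse = ", ")
  cat(sprintf("  weight of balanced component: %s\n", w))
  cat(sprintf("  logLik %.3f | converged: %s | starts: %d\n",
              object@logLik, object@converged, object@nStartsUsed))
  invisible(NULL)
})

#' @export
setMethod("show", "AiqtlTest", function(object) {
  cat("aiQTL likelihood-ratio test (het vs hom mixing weights)\n")
  cat(sprintf("  n_het = %d, n_hom = %d\n", object@nHet, object@nHom))
  w <- mixtureWeights(object@altFit)
  cat(sprintf("  pi_hat: null %.3f | %s\n",
              mixtureWeights(object@nullFit)[["pi"]],
              paste(sprintf("%s %.3f", names(w), w), collapse = " | ")))
  cat(sprintf("  LRT = %.4f on %d df, p = %.4g\n",
              object@lrtStat, object@df, object@pValue))
  invisible(NULL)
})

#' @export
setMethod("show", "SampleAlphaFit", function(object) {
  cat(sprintf(
    "Sample %s: alpha = %.4g over %d genes%s (logLik %.2f)\n",
    object@sampleId, object@alpha, object@nObs,
    if (object@boundary) " [at bound]" else "", object@logLik))
  invisible(NULL)
})

#' @export
setMethod("show", "BaselineResult", function(object) {
  cat(sprintf("Comparator aiQTL test: %s\n", object@method))
  cat(sprintf("  n_het = %d, n_hom = %d\n", object@nHet, object@nHom))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", object@statistic, object@pValue))
  if (is.matrix(object@contingency)) {
    cat("  contingency (imbalanced/balanced x het/hom):\n")
    print(object@contingency)
  }
  invisible(NULL)
})
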