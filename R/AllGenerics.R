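#' Accessors for fitted aiqtl objects
#'
#' `pValue()` and `lrtStat()` extract the test p-value and
#' likelihood-ratio statistic; `mixtureWeights()` the named mixing
#' weight(s) of the balanced component; `alphaParams()` the dispersion
#' parameter(s); `nullFit()`/`altFit()` the nested mixture fits of a test.
#'
#' @param object a [MixtureFit-class], [AiqtlTest-class],
#'   [SampleAlphaFit-class] or [BaselineResult-class] object.
#' @return a numeric scalar or named numeric vector; `nullFit`/`altFit`
#'   return a [MixtureFit-class].
#' @name accessors
#' @aliases pValue lrtStat mixtureWeights alphaParams nullFit altFit
#' @examples
#' gt <- simulateGenotypes(200, maf = 0.3, seed = 1)
#' sim <- simulateNegbinSbb(gt, alphaHom = 100, alphaHet = 5)
#' het <- sim$cls == "HET"
#' tt <- aiqtlTest(sim$aCount[!het], sim$totalCount[!het],
#'                 sim$aCount[het], sim$totalCount[het])
#' pValue(tt); lrtStat(tt); mixtureWeights(altFit(tt))
NULL

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("lrtStat", function(object) standardGeneric("lrtStat"))

#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))

#' @rdname accessors
#' @export
setGeneric("alphaParams", function(object) standardGeneric("alphaParams"))

#' @rdname accessors
#' @export
setGeneric("nullFit", function(object) standardGeneric("nullFit"))

#' @rdname accessors
#' @export
setGeneric("altFit", function(object) standardGeneric("altFit"))
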