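#' Fitted symmetric beta-binomial mixture
#'
#' Maximum-likelihood fit of the two-component symmetric beta-binomial
#' mixture. Components are label-ordered so that `alpha1 >= alpha2`:
#' component 1 is the more balanced (lower-variance) component and the
#' mixing weights give the probability that an observation is drawn from
#' it. For the null model `weights` is a single value named `"pi"`; for
#' the genotype-dependent alternative it is named by group (`"hom"`,
#' `"het"`, or dosage levels).
#'
#' @slot alpha1 dispersion of the balanced component (`alpha1 >= alpha2`).
#' @slot alpha2 dispersion of the imbalanced component.
#' @slot weights named numeric, mixing weight(s) of component 1, in `[0, 1]`.
#' @slot logLik maximised log-likelihood.
#' @slot converged optimizer status of the best start.
#' @slot nStartsUsed number of optimizer starts evaluated.
#' @slot boundary named logical: did `alpha1`/`alpha2` hit the configured bounds?
#' @slot nObs observations used after read-depth filtering.
#' @slot model `"null"` or `"alt"`.
#'
#' @seealso [fitNullMixture()], [fitAltMixture()]
#' @export
setClass("MixtureFit",
  representation(
    alpha1 = "numeric", alpha2 = "numeric", weights = "numeric",
    logLik = "numeric", converged = "logical", nStartsUsed = "integer",
    boundary = "logical", nObs = "integer", model = "character"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (length(object@alpha1) != 1L || object@alpha1 <= 0)
    msg <- c(msg, "alpha1 must be a single positive value")
  if (length(object@alpha2) != 1L || object@alpha2 <= 0)
    msg <- c(msg, "alpha2 must be a single positive value")
  if (length(object@alpha1) == 1L && length(object@alpha2) == 1L &&
      object@alpha1 < object@alpha2)
    msg <- c(msg, "components must be label-ordered so that alpha1 >= alpha2")
  if (any(object@weights < 0 | object@weights > 1))
    msg <- c(msg, "mixing weights must lie in [0, 1]")
  if (length(object@logLik) != 1L || !is.finite(object@logLik))
    msg <- c(msg, "logLik must be a single finite value")
  if (!object@model %in% c("null", "alt"))
    msg <- c(msg, "model must be 'null' or 'alt'")
  if (length(msg)) msg else TRUE
})

#' Likelihood-ratio test result for one gene-variant pair
#'
#' Result of comparing the shared-weight null mixture to the
#' genotype-dependent alternative. The statistic is
#' `2 * (logLik(alt) - logLik(null))`, clamped at zero (the null is nested
#' in the alternative and the alternative optimisation is always started
#' from the null optimum), and is referred to a chi-squared distribution
#' with `df` degrees of freedom (1 for the heterozygous-vs-homozygous
#' parameterisation).
#'
#' @slot lrtStat likelihood-ratio statistic, non-negative.
#' @slot df degrees of freedom (number of extra mixing weights).
#' @slot pValue upper chi-squared tail probability, in `(0, 1]`.
#' @slot nullFit,altFit the two nested [MixtureFit-class] objects.
#' @slot nHet,nHom group sizes after read-depth filtering.
#'
#' @seealso [aiqtlTest()]
#' @export
setClass("AiqtlTest",
  representation(
    lrtStat = "numeric", df = "integer", pValue = "numeric",
    nullFit = "MixtureFit", altFit = "MixtureFit",
    nHet = "integer", nHom = "integer"
  )
)

setValidity("AiqtlTest", function(object) {
  msg <- character()
  if (object@lrtStat < 0) msg <- c(msg, "lrtStat must be non-negative")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (object@df < 1L) msg <- c(msg, "df must be at least 1")
  if (length(msg)) msg else TRUE
})

#' Per-sample allelic-imbalance summary
#'
#' A single symmetric beta-binomial dispersion parameter estimated across
#' all of one sample's genes. High alpha means allele fractions concentrate
#' near 0.5 (little imbalance); low alpha means a diffuse allele-fraction
#' distribution (much imbalance, from any source: cis-regulatory variation,
#' imprinting, or random monoallelic expression).
#'
#' @slot sampleId sample identifier.
#' @slot alpha estimated dispersion parameter.
#' @slot nObs genes contributing after read-depth filtering.
#' @slot logLik maximised log-likelihood.
#' @slot boundary TRUE when the estimate ran into the configured alpha bounds.
#'
#' @seealso [fitSampleAlpha()], [summarizeSampleAlpha()]
#' @export
setClass("SampleAlphaFit",
  representation(
    sampleId = "character", alpha = "numeric", nObs = "integer",
    logLik = "numeric", boundary = "logical"
  )
)

setValidity("SampleAlphaFit", function(object) {
  if (length(object@alpha) != 1L || object@alpha <= 0)
    "alpha must be a single positive value"
  else TRUE
})

#' Comparator aiQTL test result
#'
#' Result of one of the comparator tests: `binomial` (per-sample exact
#' binomial classification, group proportions compared by Fisher's exact
#' test), `threshold` (allele-fraction thresholds 0.35/0.65), `wilcox`
#' (rank-sum on absolute departure from 0.5), or `indep_bb`
#' (likelihood-ratio test between shared and group-specific single
#' symmetric beta-binomial fits). A 2x2 contingency table
#' (imbalanced/balanced x het/hom) is carried for the two
#' classification-based methods.
#'
#' @slot method one of `"binomial"`, `"threshold"`, `"wilcox"`, `"indep_bb"`.
#' @slot statistic method-specific statistic.
#' @slot pValue p-value in `(0, 1]`.
#' @slot nHet,nHom group sizes.
#' @slot contingency 2x2 integer matrix, or NULL for wilcox/indep_bb.
#'
#' @seealso [binomialMethod()], [thresholdMethod()], [wilcoxMethod()],
#'   [indepBbTest()]
#' @export
setClass("BaselineResult",
  representation(
    method = "character", statistic = "numeric", pValue = "numeric",
    nHet = "integer", nHom = "integer", contingency = "ANY"
  )
)

setValidity("BaselineResult", function(object) {
  msg <- character()
  if (!object@method %in% c("binomial", "threshold", "wilcox", "indep_bb"))
    msg <- c(msg, "unknown method")
  needsTab <- object@method %in% c("binomial", "threshold")
  if (needsTab && !is.matrix(object@contingency))
    msg <- c(msg, "binomial/threshold results must carry a contingency table")
  if (!needsTab && !is.null(object@contingency))
    msg <- c(msg, "wilcox/indep_bb results carry no contingency table")
  if (is.matrix(object@contingency)) {
    cs <- colSums(object@contingency)
    if (!identical(unname(cs), c(object@nHet, object@nHom)) &&
        !identical(as.integer(unname(cs)), c(object@nHet, object@nHom)))
      msg <- c(msg, "contingency margins must equal group sizes")
  }
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
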