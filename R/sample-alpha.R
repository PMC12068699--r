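#' Per-sample allelic-imbalance estimate
#'
#' Estimates a single symmetric beta-binomial dispersion parameter for one
#' sample across all of its genes by one-dimensional maximum likelihood
#' over `log alpha` (golden-section search; deterministic). A high
#' estimate means allele fractions cluster tightly around 0.5 (balanced
#' expression); a low estimate means widespread imbalance. The estimate is
#' insensitive to differences in read depth between samples, which is what
#' makes it comparable across samples and tissues.
#'
#' @param a,n A-allele and total counts, one observation per gene.
#' @param sampleId identifier carried into the result.
#' @param control a [fitControl()] list; observations with fewer than
#'   `minReads` total reads are dropped and at least `minObs` genes must
#'   remain.
#' @return a [SampleAlphaFit-class]. `boundary` is TRUE when the optimum
#'   lies on the configured `alphaBounds` (e.g. perfectly balanced or
#'   fully monoallelic data).
#' @examples
#' gt <- rep("HOM", 400)
#' n <- rnbinom(400, mu = 30, size = 10) + 2
#' a <- rbinom(400, n, rbeta(400, 20, 20))
#' fitSampleAlpha(a, n, sampleId = "S1")
#' @export
fitSampleAlpha <- function(a, n, sampleId = "", control = fitControl()) {
  obs <- .filterReads(a, n, control, "fitSampleAlpha")
  lc <- .lchooseSym(obs$a, obs$n)
  interval <- log(control$alphaBounds)
  negll <- function(la) -.sbbLogLikCpp(obs$a, obs$n, lc, exp(la))
  opt <- optimize(negll, interval = interval, tol = 1e-8)
  la <- opt$minimum
  boundary <- (la - interval[1] < 1e-2) || (interval[2] - la < 1e-2)
  new("SampleAlphaFit", sampleId = as.character(sampleId),
      alpha = exp(la), nObs = length(obs$a), logLik = -opt$objective,
      boundary = boundary)
}
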