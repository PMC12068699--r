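#' Symmetric beta-binomial log probability mass
#'
#' Log pmf of the beta-binomial distribution constrained to `alpha = beta`,
#' the single-parameter family used throughout this package. Its mean
#' allele fraction is exactly 0.5 and its variance decreases with `alpha`:
#' `alpha = 1` gives the uniform distribution on `0..n`, and
#' `alpha -> Inf` recovers `Binomial(n, 0.5)`. Because the distribution is
#' symmetric, `sbbLogPmf(a, n, alpha)` and `sbbLogPmf(n - a, n, alpha)`
#' are bit-identical, so relabelling which allele is "A" never changes a
#' likelihood.
#'
#' @param a integer vector, reads mapped to the A allele (`0 <= a <= n`).
#' @param n integer vector, total allele-specifically mapped reads (`>= 1`).
#'   Recycled against `a`.
#' @param alpha single positive dispersion parameter.
#' @return numeric vector of log probabilities.
#' @examples
#' exp(sbbLogPmf(0:5, 5, alpha = 1))     # uniform: all 1/6
#' sum(exp(sbbLogPmf(0:50, 50, 2.5)))    # sums to 1
#' @export
sbbLogPmf <- function(a, n, alpha) {
  .checkAlpha(alpha)
  m <- max(length(a), length(n))
  a <- rep_len(a, m); n <- rep_len(n, m)
  obs <- .checkObs(a, n, "sbbLogPmf", allowEmpty = TRUE)
  .sbbLogPmfCpp(obs$a, obs$n, alpha)
}

#' Two-component symmetric beta-binomial mixture log-likelihood
#'
#' Sum over observations of the log of
#' `pi * SBB(a; alpha1, n) + (1 - pi) * SBB(a; alpha2, n)`,
#' evaluated with log-sum-exp.
#'
#' @param a,n integer vectors of A-allele and total counts.
#' @param alpha1,alpha2 positive dispersion parameters of the two components.
#' @param pi mixing weight of the first component, in `[0, 1]`.
#' @return a single log-likelihood value.
#' @examples
#' mixtureLogLik(c(2, 5, 9), c(10, 10, 10), 100, 2, 0.7)
#' @export
mixtureLogLik <- function(a, n, alpha1, alpha2, pi) {
  .checkAlpha(alpha1, "alpha1"); .checkAlpha(alpha2, "alpha2")
  .checkProb(pi)
  obs <- .checkObs(a, n, "mixtureLogLik", allowEmpty = TRUE)
  lc <- .lchooseSym(obs$a, obs$n)
  .groupedLogLikCpp(obs$a, obs$n, lc, integer(length(obs$a)),
                    alpha1, alpha2, pi)
}

#' Genotype-grouped mixture log-likelihood
#'
#' The full log-likelihood of the genotype-dependent model: the mixture
#' log-likelihood of the homozygous group with weight `piHom` plus that of
#' the heterozygous group with weight `piHet`, sharing `alpha1`, `alpha2`.
#'
#' @param aHom,nHom counts for samples homozygous at the candidate variant
#'   (both homozygous classes pooled).
#' @param aHet,nHet counts for heterozygous samples.
#' @param alpha1,alpha2 shared component dispersions.
#' @param piHom,piHet group-specific weights of component 1.
#' @return a single log-likelihood value.
#' @export
groupedLogLik <- function(aHom, nHom, aHet, nHet,
                          alpha1, alpha2, piHom, piHet) {
  .checkAlpha(alpha1, "alpha1"); .checkAlpha(alpha2, "alpha2")
  .checkProb(piHom, "piHom"); .checkProb(piHet, "piHet")
  if (length(aHom) == 0L || length(aHet) == 0L)
    .aiqtlStop("both genotype groups must be non-empty",
               "aiqtl_group_too_small")
  hom <- .checkObs(aHom, nHom, "hom group")
  het <- .checkObs(aHet, nHet, "het group")
  a <- c(hom$a, het$a); n <- c(hom$n, het$n)
  grp <- c(integer(length(hom$a)), rep(1L, length(het$a)))
  lc <- .lchooseSym(a, n)
  .groupedLogLikCpp(a, n, lc, grp, alpha1, alpha2, c(piHom, piHet))
}
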