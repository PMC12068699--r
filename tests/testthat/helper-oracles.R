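# Independent oracles used to check the likelihood machinery. These are
# deliberately written against different primitives than the implementation
# (quadrature instead of log-gamma algebra, exhaustive enumeration instead
# of closed-form tests).

# Beta-binomial pmf via numerical quadrature over the latent allele
# fraction: integral of C(n,a) p^a (1-p)^(n-a) Beta(p; alpha, alpha).
# The logit substitution p = plogis(x) (Jacobian p(1-p)) removes the
# endpoint singularities of the beta density for alpha < 1.
sbbQuadrature <- function(a, n, alpha) {
  g <- function(x) {
    p <- plogis(x)
    v <- dbinom(a, n, p, log = TRUE) +
      dbeta(p, alpha, alpha, log = TRUE) +
      plogis(x, log.p = TRUE) + plogis(-x, log.p = TRUE)
    out <- exp(v)
    out[!is.finite(v)] <- 0   # integrand vanishes at the endpoints
    out
  }
  # piecewise integration is more accurate when the mass concentrates far
  # from the origin (e.g. a = n); relax the tolerance if the quadrature
  # reports roundoff trouble. Accurate to ~1e-14 for alpha >= 1 and ~1e-7
  # in the worst alpha < 1 corner (monoallelic counts).
  splits <- c(-Inf, -10, 0, 10, Inf)
  total <- 0
  for (i in seq_len(length(splits) - 1L)) {
    total <- total + tryCatch(
      integrate(g, splits[i], splits[i + 1L], rel.tol = 1e-11,
                subdivisions = 2000L)$value,
      error = function(e)
        integrate(g, splits[i], splits[i + 1L], rel.tol = 1e-9,
                  subdivisions = 2000L)$value)
  }
  total
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# summation (sum of all table probabilities <= observed, at fixed margins).
fisherEnumeration <- function(tab) {
  stopifnot(dim(tab) == c(2L, 2L))
  m <- sum(tab[1, ])          # total "imbalanced"
  n <- sum(tab[2, ])          # total "balanced"
  k <- sum(tab[, 1])          # het group size
  x <- tab[1, 1]
  support <- max(0L, k - n):min(k, m)
  pr <- dhyper(support, m, n, k)
  sum(pr[pr <= dhyper(x, m, n, k) * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by explicit permutation of group labels,
# midranks for ties; statistic is distance of the rank sum from its mean.
wilcoxEnumeration <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  mu <- nx * (length(r) + 1) / 2
  sObs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(r), nx)
  s <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(abs(s - mu) >= abs(sObs - mu) - 1e-12)
}

# Reference mixture log-likelihood evaluated term by term with the
# quadrature pmf (slow; tiny inputs only).
mixtureLogLikQuad <- function(a, n, alpha1, alpha2, pi) {
  sum(vapply(seq_along(a), function(i) {
    log(pi * sbbQuadrature(a[i], n[i], alpha1) +
          (1 - pi) * sbbQuadrature(a[i], n[i], alpha2))
  }, numeric(1)))
}
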