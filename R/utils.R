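# Internal helpers: classed errors and input validation.

.aiqtlStop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "aiqtl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Validate and coerce one set of allele-specific observations.
# Returns list(a = integer, n = integer).
.checkObs <- function(a, n, what = "observations", allowEmpty = FALSE) {
  if (length(a) != length(n))
    .aiqtlStop(sprintf("%s: a and n must have equal length", what),
               "aiqtl_domain_error")
  if (!allowEmpty && length(a) == 0L)
    .aiqtlStop(sprintf("%s: empty input", what), "aiqtl_too_few_obs")
  if (anyNA(a) || anyNA(n))
    .aiqtlStop(sprintf("%s: missing values not allowed", what),
               "aiqtl_domain_error")
  a <- as.integer(round(a)); n <- as.integer(round(n))
  if (any(n < 1L))
    .aiqtlStop(sprintf("%s: total_count must be at least 1", what),
               "aiqtl_domain_error")
  if (any(a < 0L) || any(a > n))
    .aiqtlStop(sprintf("%s: need 0 <= a_count <= total_count", what),
               "aiqtl_domain_error")
  list(a = a, n = n)
}

.checkAlpha <- function(alpha, name = "alpha") {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    .aiqtlStop(sprintf("%s must be a single positive finite value", name),
               "aiqtl_domain_error")
  alpha
}

.checkProb <- function(p, name = "pi") {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    .aiqtlStop(sprintf("%s must be a single value in [0, 1]", name),
               "aiqtl_domain_error")
  p
}

.checkCols <- function(d, cols, what) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    .aiqtlStop(sprintf("%s: missing column(s) %s", what,
                       paste(miss, collapse = ", ")),
               "aiqtl_format_error")
  invisible(d)
}

# Deterministic per-replicate seed below 2^31.
.deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(idx))
    s <- (s * 69621 + idx[k] * 1013904223) %% 2147483647
  as.integer(s)
}
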