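# internal numerical helpers

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# expm1(z)/z with the removable singularity at z = 0 filled in
expm1_ratio <- function(z) {
  out <- ifelse(abs(z) < 1e-12, 1 + z / 2, expm1(z) / z)
  out
}

check_scalar <- function(x, name, lower = -Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (!allow_inf && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (x < lower) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  invisible(x)
}

check_count <- function(x, name) {
  check_scalar(x, name, lower = 1)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", name))
  as.integer(x)
}

# deterministic per-locus substream seed: mixes (seed, index) so that
# extending L leaves earlier loci untouched
mix_seed <- function(seed, index) {
  h <- (as.double(seed) %% 2147483647) + 1
  h <- (h * 48271) %% 2147483647
  h <- (h + as.double(index) * 69621) %% 2147483647
  h <- (h * 16807) %% 2147483647
  as.integer(h)
}
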