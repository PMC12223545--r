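# Shared fixtures built in code at test time.

# small default-condition cohort, cached per session so several test files
# can reuse it without regenerating
lf_cached_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, ...) {
    key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_cohort(seed = seed, ...)
    }
    cache[[key]]
  }
})

# sparse, strongly supergaussian sources for ICA identifiability tests
lf_sparse_sources <- function(k, p, density = 0.05, amp = 5, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(k * p) * (runif(k * p) < density) * amp, k, p)
}

# independent SVD-based classical CCA oracle (whitened cross-covariance)
lf_cca_oracle <- function(X, Y, k) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  svd(crossprod(svd(Xc)$u, svd(Yc)$u))$d[seq_len(k)]
}

# brute-force BH step-up oracle: largest i with p_(i) <= i q / m rejected
lf_bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}
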