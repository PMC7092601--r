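# shared validation helpers

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "mvqol_validation_error")
  }
  as.integer(x)
}

assert_psd <- function(S, name, tol = 1e-10) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    abort(sprintf("`%s` must be a square matrix.", name),
          class = "mvqol_validation_error")
  }
  if (max(abs(S - t(S))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", name),
          class = "mvqol_validation_error")
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf(
      "`%s` must be positive semi-definite (min eigenvalue %.3g).",
      name, min(ev)), class = "mvqol_validation_error")
  }
  invisible(S)
}

# draw from MVN(0, S) allowing singular (even all-zero) S via eigen
rmvn0 <- function(n, S) {
  d <- nrow(S)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * d), n, d)
  Z %*% (t(e$vectors) * sqrt(lam))
}

# per-subject substream seed, kept below 2^31 so cohorts are extensible
# without perturbing already-generated subjects
subject_seed <- function(master_seed, subject_id) {
  as.integer((as.numeric(master_seed) * 48271 + subject_id * 7919) %%
               2147483587)
}

`%theninf%` <- function(x, fallback) if (is.finite(x)) x else fallback
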