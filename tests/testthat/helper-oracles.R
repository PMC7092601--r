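# Brute-force dense-covariance oracle for the marginal likelihood:
# assembles each subject's full covariance entry by entry from the model
# definition (no Kronecker/grouping shortcuts) and evaluates the Gaussian
# log density with base solve()/determinant().
dense_m2ll <- function(design, omega_G, omega_R, beta) {
  K <- design$K
  total <- 0
  for (j in seq_along(design$subjects)) {
    Z <- design$Zg[[design$gidx[j]]]
    n <- nrow(Z)
    tm <- design$times[[j]]
    V <- matrix(0, n, n)
    for (r in seq_len(n)) {
      for (s in seq_len(n)) {
        vr <- (r - 1) %/% K + 1
        vs <- (s - 1) %/% K + 1
        kr <- (r - 1) %% K + 1
        ks <- (s - 1) %% K + 1
        V[r, s] <- drop(Z[r, ] %*% omega_G %*% Z[s, ]) +
          if (vr == vs) omega_R[kr, ks] else 0
      }
    }
    r <- design$y[[j]] - design$X[[j]] %*% beta
    total <- total +
      as.numeric(determinant(V, logarithm = TRUE)$modulus) +
      drop(t(r) %*% solve(V, r)) + n * log(2 * pi)
  }
  total
}

# random PSD matrix with controlled scale
random_psd <- function(d, scale = 1) {
  A <- matrix(stats::rnorm(d * d, 0, scale), d)
  tcrossprod(A) / d + diag(0.1 * scale^2, d)
}

# small cohort without items/panel, ready for model fitting
quick_cohort <- function(n_subjects, times, seed, fixed = character(),
                         slope = character(), beta = list(),
                         omega_G = NULL, omega_R = NULL,
                         complete_prob = 1) {
  cfg <- sim_config(
    n_subjects = n_subjects, times = times, complete_prob = complete_prob,
    fixed = fixed, slope = slope, beta = beta,
    omega_G = omega_G %||% default_omega_G(),
    omega_R = omega_R %||% default_omega_R(),
    emit_items = FALSE, loading_spec = NULL, seed = seed)
  simulate_cohort(cfg)
}

`%||%` <- rlang::`%||%`

# zero 8x8 / scaled identity shortcuts
zero_G <- function() matrix(0, 8, 8)
eye_R <- function(s = 1) diag(s, 4)

# block-diagonal restriction of a full omega_G (keeps within-outcome
# intercept/slope covariances, zeroes cross-outcome blocks)
blockdiag_G <- function(G, K = 4) {
  out <- matrix(0, 2 * K, 2 * K)
  for (k in seq_len(K)) {
    ix <- c(k, K + k)
    out[ix, ix] <- G[ix, ix]
  }
  out
}

# strip non-structural attributes for content comparisons
strip_attrs <- function(d) {
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}

# shared medium-size fitted models, built once per test run
fixture_cache <- new.env()
medium_fits <- function() {
  if (is.null(fixture_cache$fits)) {
    sds <- rep(c(1.5, 0.15), each = 4)  # slope SD raised for BLUP signal
    oG <- diag(sds) %*% default_re_correlations() %*% diag(sds)
    coh <- quick_cohort(60, seq(0, 18, by = 2), seed = 404,
                        fixed = "tb", slope = "tb", omega_G = oG,
                        beta = list(tbno = c(1.5, 0.5, 0.5, 0.5),
                                    "time:tbno" = c(0, 0, 0, 0)))
    spec <- mvml_spec(fixed = "tb", slope = "tb",
                      reference_levels = list(tb = c("yes", "no")))
    des <- build_design(coh, spec)
    fi <- fit_independent(des)
    fr <- fit_mvml(des, related = TRUE)
    fixture_cache$fits <- list(cohort = coh, design = des,
                               independent = fi, related = fr)
  }
  fixture_cache$fits
}
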