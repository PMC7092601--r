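# marginal covariance of one schedule group: V = Z Omega_G Z' + I ⊗ Omega_R
group_V <- function(Z, omega_G, omega_R) {
  K <- nrow(omega_R)
  nv <- nrow(Z) / K
  V <- Z %*% omega_G %*% t(Z)
  for (t in seq_len(nv)) {
    ix <- (t - 1L) * K + seq_len(K)
    V[ix, ix] <- V[ix, ix] + omega_R
  }
  V
}

# lower Cholesky factor per schedule group of a fit (or explicit matrices)
group_chols <- function(design, omega_G, omega_R) {
  lapply(design$Zg, function(Z) t(chol(group_V(Z, omega_G, omega_R))))
}

#' Random-effect correlation matrix of a fit
#'
#' Rescales the estimated `Omega_G` to a correlation matrix
#' `D^-1/2 Omega_G D^-1/2`, labelled baseline/slope by outcome — the
#' matrix summarising how the four domains' starting levels and rates of
#' change co-vary across subjects. Effects whose estimated variance is
#' numerically zero are reported as `NA` rows/columns rather than
#' propagating division by zero.
#'
#' @param fit An [fit_mvml()] object.
#' @param tol Variance below which a component is treated as zero.
#' @return A labelled correlation matrix of class `re_correlations`.
#' @export
random_effect_correlations <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "mvml_fit"))
  G <- fit$omega_G
  v <- diag(G)
  out <- matrix(NA_real_, nrow(G), ncol(G))
  ok <- v > tol
  if (any(!ok)) {
    warn("zero-variance random effects reported as NA rows/columns.")
  }
  d <- sqrt(v[ok])
  out[ok, ok] <- G[ok, ok] / tcrossprod(d)
  diag(out)[ok] <- 1
  labs <- c(paste("baseline", fit$spec$outcomes),
            paste("slope", fit$spec$outcomes))
  dimnames(out) <- list(labs, labs)
  structure(out, class = c("re_correlations", "matrix"))
}

#' @method print re_correlations
#' @export
print.re_correlations <- function(x, digits = 2, ...) {
  cat("Random-effect correlation matrix (baseline and time-slope blocks)\n")
  y <- unclass(x)
  y[upper.tri(y)] <- NA
  print(round(y, digits), na.print = "")
  invisible(x)
}

#' Empirical Bayes predictions of subject random effects
#'
#' BLUPs under the fitted model:
#' `E[b_j | y_j] = Omega_G Z_j' V_j^-1 (y_j - X_j beta)`. Predictions
#' shrink towards the prior mean 0; with `Omega_G = 0` they are exactly
#' zero.
#'
#' @param fit An `mvml_fit`.
#' @param data Optional new visit-level data (defaults to the fitting
#'   data's design).
#' @return Tibble: subject id plus one column per random effect
#'   (intercepts `u_*`, slopes `v_*`).
#' @export
predict_blups <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mvml_fit"))
  if (!fit$converged) warn("fit did not converge; BLUPs may be unreliable.")
  design <- if (is.null(data)) fit$design else build_design(data, fit$spec)
  Ls <- group_chols(design, fit$omega_G, fit$omega_R)
  G <- fit$omega_G
  b <- vapply(seq_along(design$subjects), function(j) {
    L <- Ls[[design$gidx[j]]]
    Z <- design$Zg[[design$gidx[j]]]
    r <- design$y[[j]] - design$X[[j]] %*% fit$beta_vec
    w <- backsolve(t(L), forwardsolve(L, r))
    drop(G %*% crossprod(Z, w))
  }, numeric(2L * design$K))
  bT <- t(b)
  colnames(bT) <- c(paste0("u_", fit$spec$outcomes),
                    paste0("v_", fit$spec$outcomes))
  out <- tibble::as_tibble(bT)
  dplyr::bind_cols(tibble::tibble(subject_id = design$subjects), out)
}

#' Cholesky-transformed residuals and Q-Q table
#'
#' Per subject, `r_j = L_j^-1 (y_j - X_j beta)` with `L_j` the lower
#' Cholesky factor of the fitted marginal covariance `V_j`; under a
#' correctly specified model the concatenated residuals are approximately
#' i.i.d. standard normal, which is the basis of the normal Q-Q check of
#' the joint growth model.
#'
#' @param fit An `mvml_fit`.
#' @param data Optional new data (defaults to the fitting design).
#' @return Tibble with `subject_id`, `index`, `residual`, and normal
#'   quantiles `q_theoretical` matched by rank — ready for a Q-Q plot.
#' @export
transformed_residuals <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mvml_fit"))
  design <- if (is.null(data)) fit$design else build_design(data, fit$spec)
  Ls <- group_chols(design, fit$omega_G, fit$omega_R)
  res <- lapply(seq_along(design$subjects), function(j) {
    L <- Ls[[design$gidx[j]]]
    r <- design$y[[j]] - design$X[[j]] %*% fit$beta_vec
    tibble::tibble(subject_id = design$subjects[j],
                   index = seq_along(r),
                   residual = drop(forwardsolve(L, r)))
  })
  out <- dplyr::bind_rows(res)
  n <- nrow(out)
  out$q_theoretical <- stats::qnorm((rank(out$residual, ties.method =
                                            "first") - 0.5) / n)
  out
}
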