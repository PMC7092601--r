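#' Kaiser retention rule
#'
#' Number of factors whose correlation-matrix eigenvalues strictly exceed
#' 1. When none do, one factor is retained with a warning so downstream
#' stages always have at least one component to work with.
#'
#' @param eigenvalues Eigenvalues sorted in decreasing order.
#' @return Integer count of retained factors (>= 1).
#' @export
kaiser_retain <- function(eigenvalues) {
  if (!length(eigenvalues)) {
    abort("`eigenvalues` must be non-empty.",
          class = "mvqol_validation_error")
  }
  k <- sum(eigenvalues > 1)
  if (k < 1L) {
    warn("no eigenvalue exceeds 1; retaining a single factor.")
    k <- 1L
  }
  as.integer(k)
}

#' Classify loading strength
#'
#' Absolute-value convention: strong above 0.6, moderate in the closed
#' interval `[0.4, 0.6]`, weak below 0.4.
#'
#' @param loading Numeric vector of loadings.
#' @return Character vector in `{"strong", "moderate", "weak"}`.
#' @export
classify_loading <- function(loading) {
  a <- abs(as.numeric(loading))
  dplyr::case_when(a > 0.6 ~ "strong", a >= 0.4 ~ "moderate",
                   TRUE ~ "weak")
}

#' Varimax rotation with a fixed sign and order convention
#'
#' Orthogonal rotation maximising the raw varimax criterion (no Kaiser
#' row normalisation), then ordering factors by explained variance and
#' flipping signs so each factor's largest-magnitude loading is positive.
#' Communalities are preserved exactly by orthogonality. A single factor
#' is returned unrotated.
#'
#' @param loadings Variables x factors loading matrix.
#' @return List with `loadings` and the orthogonal `rotmat` such that
#'   `loadings_in %*% rotmat = loadings`.
#' @export
varimax_rotate <- function(loadings) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  R <- diag(k)
  if (k > 1L) {
    vr <- stats::varimax(L, normalize = FALSE, eps = 1e-10)
    L <- L %*% vr$rotmat
    R <- vr$rotmat
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  sgn <- vapply(seq_len(k), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, 0)
  sgn[sgn == 0] <- 1
  P <- diag(k)[, ord, drop = FALSE] %*% diag(sgn[ord], k)
  list(loadings = L %*% P, rotmat = R %*% P)
}

# raw varimax criterion (gamma = 1, no normalisation)
varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(colSums(L^4) / p - (colSums(L^2) / p)^2)
}

# iterative principal-axis extraction, used when ML fails to converge
principal_axis <- function(R, k, max_iter = 200L, tol = 1e-6) {
  h2 <- 1 - 1 / diag(solve(R))
  for (i in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < tol) return(L)
    h2 <- h2_new
  }
  L
}

#' Fit an exploratory factor model to a clinical panel
#'
#' Standardises the variables, extracts factors from the correlation
#' matrix by maximum likelihood (falling back to principal-axis with a
#' warning when ML does not converge), retains factors by the Kaiser
#' rule, applies varimax rotation, labels loading strengths, and computes
#' regression-method (Thomson) factor scoring weights. A PCA extraction
#' mode is available since eigenvalue-based retention is often described
#' in principal-component terms.
#'
#' @param panel Data frame or matrix of observations x variables.
#' @param group Optional label for the variable group.
#' @param method `"ml"` (default) or `"pca"`.
#' @param scores `"regression"` (default) or `"bartlett"` scoring weights.
#' @return Object of class `qol_factor_model`.
#' @export
fit_factor_model <- function(panel, group = NULL,
                             method = c("ml", "pca"),
                             scores = c("regression", "bartlett")) {
  method <- match.arg(method)
  scores <- match.arg(scores)
  X <- as.matrix(panel)
  p <- ncol(X)
  n <- nrow(X)
  if (p < 3L || n < 50L) {
    abort("need at least 3 variables and 50 observations.",
          class = "mvqol_validation_error")
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("constant columns: ",
                 paste(colnames(X)[sds == 0], collapse = ", ")),
          class = "mvqol_validation_error")
  }
  mns <- colMeans(X)
  R <- stats::cor(X)
  rc <- rcond(R)
  if (rc < 1e-12) {
    vc <- tryCatch(colnames(X)[which(abs(eigen(R)$vectors[, p]) > 0.3)],
                   error = function(e) character())
    abort(paste0("correlation matrix is singular; collinear columns: ",
                 paste(vc, collapse = ", ")),
          class = "mvqol_validation_error")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  k <- kaiser_retain(ev)

  extraction <- method
  if (method == "pca") {
    e <- eigen(R, symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  } else {
    fa <- tryCatch(
      stats::factanal(covmat = R, factors = k, n.obs = n,
                      rotation = "none"),
      error = function(e) NULL)
    if (is.null(fa)) {
      warn("ML factor extraction did not converge; falling back to principal-axis.")
      extraction <- "principal_axis"
      L <- principal_axis(R, k)
    } else {
      L <- unclass(fa$loadings)
    }
  }
  rownames(L) <- colnames(X)

  rot <- varimax_rotate(L)
  Lr <- rot$loadings
  fnames <- paste0("factor", seq_len(k))
  colnames(Lr) <- fnames

  W <- if (scores == "regression") {
    solve(R, Lr)
  } else {
    psi <- pmax(1 - rowSums(Lr^2), 1e-6)
    LP <- Lr / psi
    LP %*% solve(t(Lr) %*% LP)
  }
  dimnames(W) <- dimnames(Lr)

  structure(
    list(loadings = Lr, rotmat = rot$rotmat, eigenvalues = ev,
         retained = k, strength = matrix(classify_loading(Lr), nrow(Lr),
                                         k, dimnames = dimnames(Lr)),
         scoring_weights = W, variable_means = mns, variable_sds = sds,
         correlation = R, group = group %||% "panel", method = extraction,
         scores_method = scores, n_obs = n),
    class = "qol_factor_model")
}

#' @method print qol_factor_model
#' @export
print.qol_factor_model <- function(x, ...) {
  cat(sprintf("<qol_factor_model> group '%s': %d variables, %d factors retained (%s extraction)\n",
              x$group, nrow(x$loadings), x$retained, x$method))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Tidy a factor model into a loadings table
#'
#' @param x A `qol_factor_model`.
#' @param ... Unused.
#' @return Tibble with variable, factor, loading and strength label.
#' @export
tidy.qol_factor_model <- function(x, ...) {
  tibble::tibble(
    group = x$group,
    variable = rep(rownames(x$loadings), ncol(x$loadings)),
    factor = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings),
    strength = as.vector(x$strength))
}

#' Compute factor scores for new (or fitting) observations
#'
#' Standardises the panel with the model's fitting-sample means and
#' standard deviations and applies the stored scoring weights; on the
#' fitting sample the scores have mean zero by construction.
#'
#' @param model A `qol_factor_model`.
#' @param panel Data with exactly the model's variables.
#' @return Tibble of observation x factor scores.
#' @export
compute_factor_scores <- function(model, panel) {
  X <- as.matrix(panel)
  if (!setequal(colnames(X), names(model$variable_means)) ||
      ncol(X) != length(model$variable_means)) {
    abort("panel variables do not match the fitted model.",
          class = "mvqol_validation_error")
  }
  X <- X[, names(model$variable_means), drop = FALSE]
  Xs <- sweep(sweep(X, 2L, model$variable_means), 2L, model$variable_sds,
              "/")
  tibble::as_tibble(Xs %*% model$scoring_weights)
}

#' Eigenvalue (scree) table of a factor model
#'
#' @param model A `qol_factor_model`.
#' @return Tibble of component index, eigenvalue, proportion of variance
#'   and retention flag — the data behind a scree plot.
#' @export
scree_data <- function(model) {
  ev <- model$eigenvalues
  tibble::tibble(component = seq_along(ev), eigenvalue = ev,
                 proportion = ev / sum(ev),
                 retained = seq_along(ev) <= model$retained)
}
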