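test_that("Kaiser retention counts eigenvalues strictly greater than one", {
  expect_equal(kaiser_retain(c(2.5, 1.1, 0.8)), 2L)
  expect_warning(k <- kaiser_retain(c(0.9, 0.6)))
  expect_equal(k, 1L)
  expect_warning(k1 <- kaiser_retain(c(1.0, 0.5)))  # 1.0 is not > 1
  expect_equal(k1, 1L)
  expect_error(kaiser_retain(numeric(0)), class = "mvqol_validation_error")
})

test_that("loading strength labels use absolute value with closed moderate interval", {
  expect_equal(classify_loading(0.925), "strong")
  expect_equal(classify_loading(-0.592), "moderate")
  expect_equal(classify_loading(0.226), "weak")
  expect_equal(classify_loading(c(0.4, 0.6, -0.6, -0.4)),
               rep("moderate", 4))
  expect_equal(classify_loading(c(0.601, -0.399)), c("strong", "weak"))
})

test_that("varimax rotation matches a brute-force grid search for two factors", {
  set.seed(9)
  L <- matrix(rnorm(12), 6, 2)
  vr <- varimax_rotate(L)
  crit <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    mvqol:::varimax_criterion(L %*% R)
  }
  grid_max <- max(vapply(seq(0, pi / 2, length.out = 20001), crit, 0))
  expect_gte(mvqol:::varimax_criterion(vr$loadings),
             mvqol:::varimax_criterion(L))
  expect_equal(mvqol:::varimax_criterion(vr$loadings), grid_max,
               tolerance = 1e-4)
  # orthogonality preserves communalities
  expect_equal(rowSums(vr$loadings^2), rowSums(L^2), tolerance = 1e-8)
  # rotation matrix reproduces the rotated loadings
  expect_equal(L %*% vr$rotmat, vr$loadings, tolerance = 1e-10)
})

test_that("single factors are unrotated and optima are fixed points", {
  L1 <- matrix(c(0.8, 0.7, 0.6), 3, 1)
  vr1 <- varimax_rotate(L1)
  expect_equal(vr1$loadings, L1)
  expect_equal(vr1$rotmat, diag(1))
  # an already varimax-optimal pattern keeps its criterion value
  Ls <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.85), c(0, 0.75))
  vr <- varimax_rotate(Ls)
  expect_equal(mvqol:::varimax_criterion(vr$loadings),
               mvqol:::varimax_criterion(Ls), tolerance = 1e-8)
})

test_that("block structure is recovered from a synthetic two-factor panel", {
  spec2 <- default_loading_spec()[2]  # red blood cell group, 2 factors
  pan <- simulate_clinical_panel(spec2, 2000, seed = 21)
  fm <- fit_factor_model(pan, group = "rbc")
  expect_equal(fm$retained, 2L)
  gen <- apply(abs(spec2[[1]]$loadings), 1, which.max)
  est <- apply(abs(fm$loadings), 1, which.max)
  # same-generating-factor variables share an estimated factor, and
  # different ones do not (permutation invariant)
  for (i in seq_along(gen)) {
    for (j in seq_along(gen)) {
      expect_equal(gen[[i]] == gen[[j]], est[[i]] == est[[j]])
    }
  }
  # estimated scores track the generating factor scores
  sc <- as.matrix(compute_factor_scores(fm, pan))
  truth <- as.matrix(sim_truth(pan))
  cors <- abs(stats::cor(sc, truth))
  expect_true(all(apply(cors, 2, max) > 0.9))
})

test_that("an independent-noise panel produces no strong loadings", {
  set.seed(7)
  pan <- matrix(rnorm(2000 * 6), 2000, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
  fm <- suppressWarnings(fit_factor_model(pan))
  expect_false(any(fm$strength == "strong"))
  expect_true(all(fm$eigenvalues < 1.3))
})

test_that("factor scores are centred on the fitting sample and exact for identity models", {
  pan <- simulate_clinical_panel(default_loading_spec()[4], 500, seed = 2)
  fm <- fit_factor_model(pan)
  sc <- compute_factor_scores(fm, pan)
  expect_true(all(abs(colMeans(as.matrix(sc))) < 1e-8))
  # identity loadings/weights: scores equal the standardised observations
  X <- as.matrix(pan)
  ident <- fm
  ident$scoring_weights <- diag(ncol(X))
  dimnames(ident$scoring_weights) <- list(colnames(X), colnames(X))
  sc_id <- as.matrix(compute_factor_scores(ident, pan))
  expected <- matrix(as.numeric(scale(X)), nrow(X))
  expect_equal(unname(sc_id), expected, tolerance = 1e-10)
  expect_error(compute_factor_scores(fm, pan[, 1:3]),
               class = "mvqol_validation_error")
})

test_that("degenerate panels are rejected with informative errors", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xc <- cbind(X, d = X[, "a"])  # exact collinearity
  expect_error(fit_factor_model(Xc), class = "mvqol_validation_error")
  Xk <- X; Xk[, 2] <- 1
  expect_error(fit_factor_model(Xk), class = "mvqol_validation_error")
  expect_error(fit_factor_model(X[1:10, ]), class = "mvqol_validation_error")
})
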