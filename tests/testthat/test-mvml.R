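test_that("the stacked design has the documented visit-major layout", {
  d <- tibble::tibble(subject_id = 1, time = c(0, 2),
                      ph = 1, psy = 2, ind = 3, soc = 4)
  des <- build_design(d, mvml_spec())
  X <- des$X[[1]]
  expect_equal(dim(X), c(8, 8))
  # row (visit t, outcome k) has 1 and t in outcome k's column pair
  expected <- matrix(0, 8, 8)
  for (t in 1:2) {
    for (k in 1:4) {
      expected[(t - 1) * 4 + k, (k - 1) * 2 + 1] <- 1
      expected[(t - 1) * 4 + k, (k - 1) * 2 + 2] <- c(0, 2)[t]
    }
  }
  expect_equal(X, expected)
  Z <- des$Zg[[des$gidx[1]]]
  expect_equal(dim(Z), c(8, 8))
  expectZ <- matrix(0, 8, 8)
  for (t in 1:2) {
    for (k in 1:4) {
      expectZ[(t - 1) * 4 + k, k] <- 1
      expectZ[(t - 1) * 4 + k, 4 + k] <- c(0, 2)[t]
    }
  }
  expect_equal(Z, expectZ)
  expect_equal(des$y[[1]], c(1, 2, 3, 4, 1, 2, 3, 4))
  expect_equal(des$labels$term, rep(c("(Intercept)", "time"), 4))
})

test_that("row order within subject does not change the design", {
  coh <- quick_cohort(3, c(0, 1, 4, 7), seed = 31, fixed = "viral_load")
  spec <- mvml_spec(fixed = "viral_load")
  a <- build_design(coh, spec)
  set.seed(1)
  b <- build_design(coh[sample(nrow(coh)), ], spec)
  ord <- match(names(a$X), names(b$X))
  expect_equal(a$X, b$X[ord])
  expect_equal(a$y, b$y[ord])
  expect_equal(a$Zg[a$gidx], b$Zg[b$gidx][ord])
})

test_that("design dimensions match hand computation on a 3-subject fixture", {
  d <- tibble::tibble(
    subject_id = rep(1:3, c(2, 3, 4)),
    time = c(0, 1, 0, 1, 2, 0, 1, 2, 3),
    viral_load = rnorm(9), ph = 0, psy = 0, ind = 0, soc = 0)
  des <- build_design(d, mvml_spec(fixed = "viral_load",
                                   slope = "viral_load"))
  p <- 4 * 4  # 4 outcomes x (intercept, viral_load, time, time:viral_load)
  expect_equal(unname(vapply(des$X, nrow, 0L)), c(8L, 12L, 16L))
  expect_true(all(vapply(des$X, ncol, 0L) == p))
  expect_equal(des$n_visits, 9L)
})

test_that("a single standardised observation has log-density -log(2*pi)/2", {
  d <- tibble::tibble(subject_id = c(1, 1), time = c(0, 1), ph = c(5, 5))
  des <- build_design(d, mvml_spec(outcomes = "ph"))
  # one-outcome model, two visits, zero random effects, unit residual:
  # residuals are zero, so each visit contributes -log(2*pi)/2
  ll <- marginal_loglik(des, matrix(0, 2, 2), matrix(1), beta = c(5, 0))
  expect_equal(ll, 2 * (-0.5 * log(2 * pi)), tolerance = 1e-12)
})

test_that("the likelihood kernel matches a dense brute-force oracle", {
  set.seed(55)
  for (rep in 1:3) {
    m <- sample(2:3, 1)
    d <- dplyr::bind_rows(lapply(seq_len(m), function(j) {
      nv <- sample(1:2, 1)
      tibble::tibble(subject_id = j, time = sort(runif(nv, 0, 10)),
                     viral_load = rnorm(nv), ph = rnorm(nv, 10),
                     psy = rnorm(nv, 10), ind = rnorm(nv, 10),
                     soc = rnorm(nv, 10))
    }))
    des <- build_design(d, mvml_spec(fixed = "viral_load"))
    oG <- random_psd(8, 0.5)
    oR <- random_psd(4, 0.8)
    beta <- rnorm(ncol(des$X[[1]]))
    expect_equal(-2 * marginal_loglik(des, oG, oR, beta),
                 dense_m2ll(des, oG, oR, beta), tolerance = 1e-8)
  }
})

test_that("block-diagonal covariances factorise into per-outcome likelihoods", {
  coh <- quick_cohort(4, c(0, 2, 5), seed = 77)
  spec4 <- mvml_spec()
  des4 <- build_design(coh, spec4)
  set.seed(3)
  blocks <- lapply(1:4, function(k) random_psd(2, 0.5))
  oG <- matrix(0, 8, 8)
  for (k in 1:4) oG[c(k, 4 + k), c(k, 4 + k)] <- blocks[[k]]
  sig_e <- c(0.8, 1.1, 0.9, 1.3)
  beta <- rnorm(8)
  joint <- marginal_loglik(des4, oG, diag(sig_e), beta)
  separate <- sum(vapply(1:4, function(k) {
    des1 <- build_design(coh, mvml_spec(outcomes = qol_domains()[k]))
    marginal_loglik(des1, blocks[[k]], matrix(sig_e[k]),
                    beta[c(2 * k - 1, 2 * k)])
  }, 0))
  expect_equal(joint, separate, tolerance = 1e-8)
})

test_that("the independent fit equals four univariate mixed models", {
  skip_if_not_installed("lme4")
  coh <- quick_cohort(40, c(0, 3, 6, 10, 14), seed = 88)
  fi <- fit_independent(coh, mvml_spec())
  dev <- sum(vapply(qol_domains(), function(k) {
    f <- stats::as.formula(paste(k, "~ time + (1 + time | subject_id)"))
    as.numeric(-2 * stats::logLik(
      lme4::lmer(f, data = coh, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE))))
  }, 0))
  expect_equal(fi$neg2_loglik, dev, tolerance = 1e-4)
  expect_equal(fi$n_cov_params, 16L)
})

test_that("the related model never fits worse than the independent restriction", {
  fits <- medium_fits()
  expect_lte(fits$related$neg2_loglik,
             fits$independent$neg2_loglik + 1e-6)
  expect_equal(fits$related$n_cov_params, 46L)
  expect_equal(fits$related$n_params - fits$independent$n_params, 30L)
})

test_that("shifting the time origin leaves the deviance unchanged", {
  coh <- quick_cohort(25, c(0, 2, 5, 9), seed = 19)
  spec <- mvml_spec()
  f1 <- fit_mvml(coh, spec)
  coh2 <- dplyr::mutate(coh, time = time - 5)
  f2 <- fit_mvml(coh2, spec, start = f1$theta)
  expect_equal(f1$neg2_loglik, f2$neg2_loglik, tolerance = 1e-6 *
                 abs(f1$neg2_loglik))
  # intercepts change deterministically: beta0' = beta0 + 5 * slope
  b1 <- f1$beta; b2 <- f2$beta
  for (k in qol_domains()) {
    i0 <- which(b1$outcome == k & b1$term == "(Intercept)")
    it <- which(b1$outcome == k & b1$term == "time")
    expect_equal(b2$estimate[i0], b1$estimate[i0] + 5 * b1$estimate[it],
                 tolerance = 1e-4)
  }
})

test_that("variance components and fixed effects are recovered under a null covariance", {
  coh <- quick_cohort(150, c(0, 3, 6, 9, 12), seed = 101,
                      omega_G = zero_G(), omega_R = eye_R())
  fit <- fit_independent(coh, mvml_spec())
  # slope variances collapse to zero; intercept variance and residual
  # variance trade off along a flat ridge, so their sum is the sharp check
  expect_true(all(diag(fit$omega_G)[5:8] < 0.02))
  expect_true(all(diag(fit$omega_G)[1:4] < 0.2))
  expect_true(all(abs(diag(fit$omega_G)[1:4] + diag(fit$omega_R) - 1)
                  < 0.12))
  truth <- sim_truth(coh)
  z <- abs(fit$beta$estimate - truth$beta$value) / fit$beta$std_error
  expect_true(mean(z < 2) >= 0.9)
})

test_that("BLUPs are zero under a null prior, centred, and track true slopes", {
  fits <- medium_fits()
  des <- fits$design
  # zero random-effect covariance => exact zeros
  ref0 <- mvml_reference_fit(des, fits$related$beta_vec, zero_G(), eye_R())
  b0 <- predict_blups(ref0)
  expect_true(all(as.matrix(b0[, -1]) == 0))
  # fitted model: centred BLUPs that correlate with the generating truth
  bl <- predict_blups(fits$related)
  re <- as.matrix(bl[, -1])
  expect_true(all(abs(colMeans(re)) < 3 * apply(re, 2, stats::sd) /
                    sqrt(nrow(re))))
  truth <- sim_truth(fits$cohort)$ranef
  expect_gt(stats::cor(re[, "v_ph"], truth$v_ph), 0.8)
  expect_gt(stats::cor(re[, "u_ph"], truth$u_ph), 0.8)
})

test_that("transformed residuals are standard normal under the generating model", {
  # identity case: transformed residuals equal raw residuals
  coh <- quick_cohort(20, c(0, 1, 3), seed = 9, omega_G = zero_G(),
                      omega_R = eye_R())
  des <- build_design(coh, mvml_spec())
  truth <- sim_truth(coh)
  ref <- mvml_reference_fit(des, truth$beta$value, zero_G(), eye_R())
  tr <- transformed_residuals(ref)
  raw <- unlist(lapply(seq_along(des$subjects), function(j)
    des$y[[j]] - des$X[[j]] %*% truth$beta$value))
  expect_equal(tr$residual, as.numeric(raw), tolerance = 1e-10)

  # calibration: KS distance below the 5% critical value in >= 90% of reps
  pass <- vapply(1:20, function(r) {
    coh <- quick_cohort(40, c(0, 2, 4, 7, 10), seed = 300 + r)
    des <- build_design(coh, mvml_spec())
    truth <- sim_truth(coh)
    ref <- mvml_reference_fit(des, truth$beta$value, truth$omega_G,
                              truth$omega_R)
    res <- transformed_residuals(ref)$residual
    ks <- suppressWarnings(stats::ks.test(res, "pnorm"))
    ks$statistic < 1.358 / sqrt(length(res))
  }, TRUE)
  expect_gte(mean(pass), 0.9)

  # moment check at large n (>= 5000 stacked observations)
  coh <- quick_cohort(250, c(0, 2, 4, 7, 10), seed = 77)
  des <- build_design(coh, mvml_spec())
  truth <- sim_truth(coh)
  ref <- mvml_reference_fit(des, truth$beta$value, truth$omega_G,
                            truth$omega_R)
  res <- transformed_residuals(ref)$residual
  expect_gte(length(res), 5000)
  expect_true(abs(mean(res)) < 0.05)
  expect_true(stats::var(res) > 0.9 && stats::var(res) < 1.1)
})

test_that("random-effect correlations have unit diagonal and flag zero variances", {
  fits <- medium_fits()
  rc <- random_effect_correlations(fits$related)
  expect_equal(unname(diag(rc)), rep(1, 8))
  expect_true(all(abs(rc) <= 1 + 1e-8))
  ev <- eigen(unclass(rc), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # diagonal omega_G gives the identity
  ref <- mvml_reference_fit(fits$design, fits$related$beta_vec,
                            diag(8), eye_R())
  expect_equal(unname(unclass(random_effect_correlations(ref))), diag(8))
  # zero-variance component reported as NA, not NaN
  G <- diag(c(0, rep(1, 7)))
  ref0 <- mvml_reference_fit(fits$design, fits$related$beta_vec, G, eye_R())
  expect_warning(rc0 <- random_effect_correlations(ref0))
  expect_true(all(is.na(rc0[1, -1])))
  expect_false(any(is.nan(unclass(rc0))))
})

test_that("rank-deficient designs are reported with offending columns", {
  coh <- quick_cohort(5, c(0, 1, 2), seed = 12)
  coh$dup <- coh$time  # collinear with the time effect
  expect_error(
    build_design(coh, mvml_spec(fixed = "dup")),
    class = "mvqol_validation_error")
})
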