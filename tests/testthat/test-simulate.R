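test_that("zero-covariance cohorts equal the fixed-effect surface exactly", {
  coh <- quick_cohort(5, c(0, 2, 5, 9), seed = 3, fixed = "viral_load",
                      slope = "viral_load", omega_G = zero_G(),
                      omega_R = matrix(0, 4, 4))
  truth <- sim_truth(coh)
  des <- build_design(coh, mvml_spec(fixed = "viral_load",
                                     slope = "viral_load"))
  for (j in seq_along(des$subjects)) {
    mu <- des$X[[j]] %*% truth$beta$value
    expect_equal(des$y[[j]], drop(mu), tolerance = 1e-12)
  }
})

test_that("the same configuration and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_subjects = 12, times = c(0, 1, 3, 6),
                    seed = 99, emit_items = TRUE)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(sim_truth(a)$ranef, sim_truth(b)$ranef)
})

test_that("the default configuration emits a 219-subject cohort with valid visit structure", {
  cfg <- sim_config(loading_spec = NULL, emit_items = FALSE)
  coh <- simulate_cohort(cfg)
  expect_equal(dplyr::n_distinct(coh$subject_id), 219L)
  by_subj <- split(coh$time, coh$subject_id)
  expect_true(all(lengths(by_subj) >= 2L))
  expect_true(all(vapply(by_subj, function(t)
    !is.unsorted(t, strictly = TRUE), TRUE)))
})

test_that("random-effect and residual moments are recovered at large n", {
  coh <- quick_cohort(10000, c(0, 6), seed = 17, fixed = character(),
                      slope = character())
  truth <- sim_truth(coh)
  G <- truth$omega_G
  re <- as.matrix(truth$ranef[, -1])
  # slope correlation between physical and psychological domains
  target <- stats::cov2cor(G)[5, 6]
  expect_equal(stats::cor(re[, 5], re[, 6]), target, tolerance = 0.025)
  # entrywise covariance recovery within Monte-Carlo error
  emp <- stats::cov(re)
  mc_se <- sqrt((diag(G) %o% diag(G) + G^2) / nrow(re))
  expect_true(all(abs(emp - G) < pmax(3 * mc_se, 1e-3)))
  # occasion residuals are exchangeable draws from omega_R
  expect_true(all(abs(stats::cov(truth$residuals) -
                        truth$omega_R) < 0.05))
})

test_that("likert emission hits the scoring bounds and round-trips", {
  expect_identical(simulate_likert_items(20, 4), rep(5L, 4))
  expect_identical(simulate_likert_items(4, 7), rep(1L, 7))
  it <- simulate_likert_items(12, 4)
  expect_equal(mean(it), 3)
  expect_equal(score_domain(it), 12)
  # nearest attainable score for arbitrary targets
  set.seed(1)
  for (s in runif(25, 4, 20)) {
    n <- sample(3:8, 1)
    got <- score_domain(simulate_likert_items(s, n))
    nearest <- 4 * round(s / 4 * n) / n
    expect_equal(got, nearest, tolerance = 1e-12)
  }
  expect_error(simulate_likert_items(21, 4), class = "mvqol_validation_error")
  expect_error(simulate_likert_items(3.9, 4), class = "mvqol_validation_error")
})

test_that("clinical panel emission reflects the generating loadings", {
  # identity loadings with zero uniqueness reproduce the factors exactly
  ident <- list(list(name = "id", loadings = {
    L <- diag(3)
    dimnames(L) <- list(c("a", "b", "c"), c("fa", "fb", "fc"))
    L
  }))
  pan <- simulate_clinical_panel(ident, 100, seed = 4)
  expect_equal(pan$a, sim_truth(pan)$f_fa, tolerance = 1e-12)

  pan <- simulate_clinical_panel(default_loading_spec(), 5000, seed = 8)
  truth <- sim_truth(pan)
  expect_equal(stats::cor(pan$leucocyte, truth$f_granulocytes), 0.925,
               tolerance = 0.035)
  pan2 <- simulate_clinical_panel(default_loading_spec(), 5000, seed = 8)
  expect_identical(as.data.frame(pan), as.data.frame(pan2))

  bad <- list(list(name = "x", loadings = matrix(0.9, 3, 2,
    dimnames = list(c("a", "b", "c"), c("f1", "f2")))))
  expect_error(simulate_clinical_panel(bad, 10),
               class = "mvqol_validation_error")
})

test_that("missing-response injection blanks the requested number of visits", {
  coh <- tibble::tibble(subject_id = rep(1:8, each = 1157),
                        time = rep(seq_len(1157), 8),
                        ph = 10, psy = 10, ind = 10, soc = 10)
  expect_identical(inject_missing_responses(coh, 0), coh)
  out <- inject_missing_responses(coh, 0.054, seed = 2)
  n_blank <- sum(!stats::complete.cases(out[c("ph", "psy", "ind", "soc")]))
  expect_equal(n_blank, round(0.054 * 9256))
  expect_equal(n_blank, 500L)
  out2 <- inject_missing_responses(coh, 0.054, seed = 2)
  expect_identical(as.data.frame(out), as.data.frame(out2))
  expect_error(inject_missing_responses(coh, 1),
               class = "mvqol_validation_error")
})

test_that("invalid simulation configurations are rejected by name", {
  bad_G <- diag(8); bad_G[1, 2] <- bad_G[2, 1] <- 2  # indefinite
  expect_error(sim_config(omega_G = bad_G), class = "mvqol_validation_error")
  expect_error(sim_config(min_visits = 1), class = "mvqol_validation_error")
  expect_error(sim_config(times = c(0)), class = "mvqol_validation_error")
  cs <- default_covariate_spec()
  cs$tb$probs <- c(0.5, 0.6)
  expect_error(sim_config(covariate_spec = cs),
               class = "mvqol_validation_error")
})
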