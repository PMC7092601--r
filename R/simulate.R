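#' Configure a synthetic longitudinal QoL cohort
#'
#' Defines the generative model for a seed-reproducible cohort with the
#' structure of an acute-HIV-infection cohort of women followed from
#' seroconversion through cART: four correlated domain-score trajectories
#' per subject (random intercepts and slopes drawn jointly from
#' `omega_G`, occasion residuals from `omega_R`), a mixed
#' weekly/monthly/quarterly visit schedule, Likert item emission, and a
#' 24-variable clinical panel with latent block structure.
#'
#' @param n_subjects Number of subjects (default 219).
#' @param times Scheduled visit times in months since enrolment (default a
#'   41-visit weekly/monthly/quarterly schedule spanning 69 months).
#' @param complete_prob Probability a subject completes the full schedule;
#'   otherwise follow-up truncates uniformly at between `min_visits` and
#'   one visit short of the schedule.
#' @param min_visits Minimum visits per subject (must be >= 2).
#' @param fixed,slope Covariate names entering the baseline and
#'   time-interaction fixed-effect blocks.
#' @param beta Named list mapping design-column names to length-4 numeric
#'   vectors of per-outcome effects (outcome order `ph`, `psy`, `ind`,
#'   `soc`); merged over [default_beta()], unnamed terms are zero.
#' @param omega_G 8 x 8 PSD covariance of (u_ph..u_soc, v_ph..v_soc).
#' @param omega_R 4 x 4 PSD occasion-residual covariance.
#' @param covariate_spec See [default_covariate_spec()].
#' @param loading_spec Clinical-panel loading structure
#'   ([default_loading_spec()]); `NULL` suppresses panel emission.
#' @param emit_items Emit 5-point Likert item responses (`dom1_item1`,
#'   ...) instead of exact domain-score columns.
#' @param likert_items Items per domain when emitting Likert responses.
#' @param likert_noise_sd Emission noise on the latent item mean.
#' @param seed Master seed; each subject draws from a substream derived
#'   from `(seed, subject id)` so cohorts are extensible.
#' @return A validated object of class `mvqol_sim_config`.
#' @export
sim_config <- function(n_subjects = 219, times = default_schedule(),
                       complete_prob = 0.95, min_visits = 2L,
                       fixed = c("age_group", "education", "tb",
                                 "viral_load", "weight"),
                       slope = c("viral_load", "weight", "age_group"),
                       beta = list(),
                       omega_G = default_omega_G(),
                       omega_R = default_omega_R(),
                       covariate_spec = default_covariate_spec(),
                       loading_spec = default_loading_spec(),
                       emit_items = TRUE,
                       likert_items = c(ph = 4L, psy = 5L, ind = 4L,
                                        soc = 4L),
                       likert_noise_sd = 0.5, seed = 1L) {
  n_subjects <- assert_scalar_count(n_subjects, "n_subjects", min = 1L)
  min_visits <- assert_scalar_count(min_visits, "min_visits", min = 2L)
  if (length(times) < min_visits || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be a strictly increasing schedule with at least `min_visits` entries.",
          class = "mvqol_validation_error")
  }
  assert_psd(omega_G, "omega_G")
  assert_psd(omega_R, "omega_R")
  if (nrow(omega_G) != 8L || nrow(omega_R) != 4L) {
    abort("`omega_G` must be 8 x 8 and `omega_R` 4 x 4.",
          class = "mvqol_validation_error")
  }
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    if (cs$type == "categorical") {
      if (abs(sum(cs$probs) - 1) > 1e-12) {
        abort(sprintf("category frequencies of `%s` must sum to 1.", nm),
              class = "mvqol_validation_error")
      }
      if (length(cs$probs) != length(cs$levels)) {
        abort(sprintf("`%s`: probs and levels lengths differ.", nm),
              class = "mvqol_validation_error")
      }
    }
  }
  beta <- utils::modifyList(default_beta(), beta)
  stopifnot(all(vapply(beta, length, 0L) == 4L))
  structure(
    list(n_subjects = n_subjects, times = times,
         complete_prob = complete_prob, min_visits = min_visits,
         fixed = fixed, slope = slope, beta = beta, omega_G = omega_G,
         omega_R = omega_R, covariate_spec = covariate_spec,
         loading_spec = loading_spec, emit_items = emit_items,
         likert_items = likert_items, likert_noise_sd = likert_noise_sd,
         seed = as.integer(seed)),
    class = "mvqol_sim_config")
}

# matrix square root used for all MVN draws; exact zeros allowed
mvn_root <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  t(e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0))))
}

draw_covariates <- function(cs, n_visits) {
  if (cs$type == "categorical") {
    lev <- cs$levels[sample.int(length(cs$levels), 1L, prob = cs$probs)]
    rep(lev, n_visits)
  } else {
    base <- stats::rnorm(1L, cs$mean, cs$sd)
    x <- base + stats::rnorm(n_visits, 0, cs$visit_sd %||% 0)
    if (!is.null(cs$lower)) x <- pmax(x, cs$lower)
    if (!is.null(cs$upper)) x <- pmin(x, cs$upper)
    x
  }
}

#' Simulate a longitudinal QoL cohort
#'
#' Draws, for each subject, one vector of eight random effects from
#' `MVN(0, omega_G)` and, per visit, a four-vector of occasion residuals
#' from `MVN(0, omega_R)`, then emits
#' `y_kjt = x'_tj beta_k + u_kj + v_kj * time + e_kjt` for the four
#' domains. The generating parameters and per-subject random effects are
#' stored in the `truth` attribute for recovery testing. The same config
#' and seed reproduce the cohort exactly.
#'
#' @param config An [sim_config()].
#' @return A tibble, one row per visit, with attributes `truth` (see
#'   [sim_truth()]) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mvqol_sim_config"))
  K <- 4L
  root_G <- mvn_root(config$omega_G)
  root_R <- mvn_root(config$omega_R)
  cs_names <- names(config$covariate_spec)
  n_sched <- length(config$times)

  per_subject <- function(j) {
    set.seed(subject_seed(config$seed, j))
    nv <- if (stats::runif(1) < config$complete_prob) n_sched else
      sample(seq.int(config$min_visits, n_sched - 1L), 1L)
    tm <- config$times[seq_len(nv)]
    cov_df <- lapply(config$covariate_spec, draw_covariates, n_visits = nv)
    b <- drop(stats::rnorm(2L * K) %*% root_G)
    e <- matrix(stats::rnorm(nv * K), nv, K) %*% root_R
    out <- tibble::tibble(subject_id = j, time = tm)
    for (nm in cs_names) out[[nm]] <- cov_df[[nm]]
    list(data = out, b = b, e = e)
  }
  parts <- lapply(seq_len(config$n_subjects), per_subject)
  data <- dplyr::bind_rows(lapply(parts, `[[`, "data"))
  ranef <- do.call(rbind, lapply(parts, `[[`, "b"))
  resid <- do.call(rbind, lapply(parts, `[[`, "e"))
  nv_j <- vapply(parts, function(p) nrow(p$data), 0L)

  spec <- mvml_spec(fixed = config$fixed, slope = config$slope,
                    reference_levels = lapply(
                      config$covariate_spec[vapply(
                        config$covariate_spec,
                        function(x) x$type == "categorical", TRUE)],
                      `[[`, "levels"))
  des <- build_design(data, spec, require_y = FALSE)
  beta_vec <- align_beta(config$beta, des$labels)
  mu <- matrix(do.call(rbind, des$X) %*% beta_vec, ncol = K, byrow = TRUE)

  u <- ranef[rep(seq_len(config$n_subjects), nv_j), 1:K, drop = FALSE]
  v <- ranef[rep(seq_len(config$n_subjects), nv_j), K + 1:K, drop = FALSE]
  y <- mu + u + v * data$time + resid
  colnames(y) <- qol_domains()

  latent <- tibble::as_tibble(y)
  if (config$emit_items) {
    data <- emit_likert(data, y, config)
  } else {
    data <- dplyr::bind_cols(data, latent)
  }

  panel_truth <- NULL
  if (!is.null(config$loading_spec)) {
    pan <- simulate_clinical_panel(config$loading_spec, nrow(data),
                                   seed = subject_seed(config$seed, 0L))
    panel_truth <- attr(pan, "truth")
    data <- dplyr::bind_cols(data, pan)
  }

  truth <- list(
    beta = tibble::tibble(outcome = des$labels$outcome,
                          term = des$labels$term,
                          block = des$labels$block, value = beta_vec),
    omega_G = config$omega_G, omega_R = config$omega_R,
    ranef = tibble::tibble(subject_id = seq_len(config$n_subjects)) |>
      dplyr::bind_cols(tibble::as_tibble(
        `colnames<-`(ranef, rownames(config$omega_G) %||%
                       c(paste0("u_", qol_domains()),
                         paste0("v_", qol_domains()))))),
    residuals = `colnames<-`(resid, qol_domains()),
    latent_scores = latent, factor_scores = panel_truth,
    config = config)
  attr(data, "truth") <- truth
  attr(data, "config") <- config
  data
}

# map the config's named per-term effect vectors onto design columns
align_beta <- function(beta, labels) {
  out <- numeric(nrow(labels))
  kidx <- match(labels$outcome, qol_domains())
  for (i in seq_len(nrow(labels))) {
    bv <- beta[[labels$term[i]]]
    if (!is.null(bv)) out[i] <- bv[kidx[i]]
  }
  out
}

emit_likert <- function(data, y, config) {
  K <- 4L
  ni <- config$likert_items
  for (k in seq_len(K)) {
    items <- t(vapply(pmin(20, pmax(4, y[, k])), simulate_likert_items,
                      numeric(ni[k]), n_items = ni[k],
                      noise_sd = config$likert_noise_sd))
    colnames(items) <- paste0("dom", k, "_item", seq_len(ni[k]))
    data <- dplyr::bind_cols(data, tibble::as_tibble(items))
  }
  data
}

#' Generating truth of a simulated object
#'
#' @param x A cohort from [simulate_cohort()] or panel from
#'   [simulate_clinical_panel()].
#' @return The stored truth (generating parameters, per-subject random
#'   effects, latent scores / factor scores), or `NULL` if absent.
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Emit Likert item responses for a target domain score
#'
#' Inverts the mean-times-four WHOQOL scoring transform: items are chosen
#' so that with `noise_sd = 0` re-scoring returns the nearest attainable
#' domain score, i.e. `4 * round(n * score / 4) / n`; emission noise then
#' perturbs each item before rounding and clipping to 1..5.
#'
#' @param domain_score Target score in `[4, 20]`.
#' @param n_items Number of items in the domain (>= 1).
#' @param noise_sd Standard deviation of per-item Gaussian noise.
#' @param seed Optional seed for the emission noise (`NULL` uses the
#'   current RNG state).
#' @return Integer vector of `n_items` responses in 1..5.
#' @export
simulate_likert_items <- function(domain_score, n_items, noise_sd = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_items <- assert_scalar_count(n_items, "n_items", min = 1L)
  if (!is.numeric(domain_score) || length(domain_score) != 1L ||
      is.na(domain_score) || domain_score < 4 || domain_score > 20) {
    abort("`domain_score` must be a single value in [4, 20].",
          class = "mvqol_validation_error")
  }
  total <- round(domain_score / 4 * n_items)
  q <- total %/% n_items
  r <- total %% n_items
  items <- c(rep(q + 1L, r), rep(q, n_items - r))
  if (noise_sd > 0) {
    items <- round(items + stats::rnorm(n_items, 0, noise_sd))
    items <- pmin(5L, pmax(1L, items))
  }
  as.integer(items)
}

#' Simulate a clinical laboratory panel with latent block structure
#'
#' Draws `x = f Lambda' + eps` with independent standard-normal factors
#' per variable group and Gaussian uniquenesses `1 - communality`, so
#' observed columns have mean 0 and unit variance in expectation.
#'
#' @param loading_spec As [default_loading_spec()].
#' @param n_obs Number of observations.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @return Tibble of observed variables with attribute `truth`: a tibble
#'   of the generating factor scores.
#' @export
simulate_clinical_panel <- function(loading_spec, n_obs, seed = NULL) {
  n_obs <- assert_scalar_count(n_obs, "n_obs", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  obs <- list()
  scores <- list()
  for (grp in loading_spec) {
    L <- grp$loadings
    comm <- rowSums(L^2)
    if (any(comm > 1)) {
      abort(sprintf("communalities exceed 1 in group `%s`.", grp$name),
            class = "mvqol_validation_error")
    }
    f <- matrix(stats::rnorm(n_obs * ncol(L)), n_obs,
                dimnames = list(NULL, colnames(L)))
    eps <- matrix(stats::rnorm(n_obs * nrow(L)), n_obs) %*%
      diag(sqrt(1 - comm), nrow(L))
    x <- f %*% t(L) + eps
    colnames(x) <- rownames(L)
    obs[[grp$name]] <- tibble::as_tibble(x)
    scores[[grp$name]] <- tibble::as_tibble(f) |>
      stats::setNames(paste0("f_", colnames(L)))
  }
  out <- dplyr::bind_cols(obs)
  attr(out, "truth") <- dplyr::bind_cols(scores)
  out
}

#' Blank QoL responses on a random subset of visits
#'
#' Marks exactly `round(fraction * n_visits)` visits as incomplete by
#' blanking at least one domain's responses (all of a domain's items when
#' item columns are present, otherwise the domain-score column), so the
#' completeness filter has droppable visits to act on.
#'
#' @param data A cohort tibble.
#' @param fraction Fraction of visits to blank, in `[0, 1)`.
#' @param seed Seed for the visit/domain selection.
#' @return The cohort with blanked responses.
#' @export
inject_missing_responses <- function(data, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0 ||
      fraction >= 1) {
    abort("`fraction` must be a single value in [0, 1).",
          class = "mvqol_validation_error")
  }
  n <- nrow(data)
  k <- round(fraction * n)
  if (k == 0L) return(data)
  set.seed(seed)
  rows <- sample.int(n, k)
  doms <- sample.int(4L, k, replace = TRUE)
  for (d in 1:4) {
    rd <- rows[doms == d]
    if (!length(rd)) next
    item_cols <- grep(sprintf("^dom%d_item", d), names(data), value = TRUE)
    if (length(item_cols)) {
      data[rd, item_cols] <- NA_integer_
    } else {
      data[rd, qol_domains()[d]] <- NA_real_
    }
  }
  if ("qol_complete" %in% names(data)) {
    data$qol_complete[rows] <- FALSE
  }
  data
}
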