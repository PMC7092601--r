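#' Load a visit-level cohort CSV
#'
#' Long-format schema: a subject identifier, a numeric visit time in
#' months (`time` or `visit_time_months`), and either Likert item columns
#' `dom{1..4}_item{n}` or domain-score columns `ph`, `psy`, `ind`,
#' `soc`, plus covariate and clinical columns by name.
#'
#' @param path CSV path.
#' @return A tibble with the time column normalised to `time`.
#' @export
load_cohort_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(data)) {
    abort("missing required column: subject_id",
          class = "mvqol_validation_error")
  }
  if ("visit_time_months" %in% names(data) && !"time" %in% names(data)) {
    data <- dplyr::rename(data, time = "visit_time_months")
  }
  if (!"time" %in% names(data)) {
    abort("missing required column: time (or visit_time_months)",
          class = "mvqol_validation_error")
  }
  if (!is.numeric(data$time)) {
    abort("column `time` must be numeric.",
          class = "mvqol_validation_error")
  }
  has_items <- any(grepl("^dom[1-4]_item\\d+$", names(data)))
  has_scores <- all(qol_domains() %in% names(data))
  if (!has_items && !has_scores) {
    abort("need item columns dom{k}_item{n} or score columns ph, psy, ind, soc.",
          class = "mvqol_validation_error")
  }
  data
}

pipeline_stage <- function(state, name, expr) {
  if (!is.null(state$failed_stage)) return(state)
  res <- tryCatch(expr(state), error = function(e) e)
  if (inherits(res, "error")) {
    warn(sprintf("pipeline stage `%s` failed: %s", name,
                 conditionMessage(res)))
    state$failed_stage <- name
    state$error <- conditionMessage(res)
    state
  } else res
}

#' Run the full simulate/score/filter/factor/fit/compare workflow
#'
#' Orchestrates the end-to-end analysis: simulate a cohort (or load one
#' from CSV), score the WHOQOL items, drop incomplete visits and
#' under-observed subjects, compress the clinical panel into latent
#' component scores, fit the related- and independent-outcome growth
#' models, compare them, tabulate effects with confidence intervals,
#' compute cross-outcome contrasts and Q-Q residual data, and write the
#' report bundle (CSV tables plus a JSON manifest) to `out_dir`. A stage
#' failure preserves the partial outputs and is recorded in the manifest.
#'
#' @param config A list, or path to a YAML/JSON file, with optional
#'   sections `simulation` (arguments to [sim_config()]) or `input_csv`,
#'   `model` (arguments to [mvml_spec()]), `factor`
#'   (`enabled`, `method`), `contrasts` (list of
#'   `term`/`outcome_a`/`outcome_b`/`block` lists), `fit` (`"both"`,
#'   `"related"` or `"independent"`), `min_visits`, and `seed`.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, the bundle: cohort, factor models, fits,
#'   comparison, tables and manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  if (!is.null(config$input_csv) && !is.null(config$simulation)) {
    abort("give either `input_csv` or a `simulation` section, not both.",
          class = "mvqol_validation_error")
  }
  seed <- config$seed %||% 1L
  fit_which <- config$fit %||% "both"
  state <- list(config = config, seed = seed, stages = character())

  state <- pipeline_stage(state, "data", function(s) {
    if (!is.null(config$input_csv)) {
      s$cohort <- load_cohort_csv(config$input_csv)
    } else {
      sim_args <- config$simulation %||% list()
      sim_args$seed <- sim_args$seed %||% seed
      s$sim_config <- do.call(sim_config, sim_args)
      s$cohort <- simulate_cohort(s$sim_config)
    }
    s
  })

  state <- pipeline_stage(state, "score_filter", function(s) {
    scored <- score_visits(s$cohort)
    scored <- filter_complete_visits(scored)
    s$n_dropped <- attr(scored, "n_dropped")
    s$pct_dropped <- attr(scored, "pct_dropped")
    scored <- filter_min_visits(scored, config$min_visits %||% 2L)
    s$n_subjects_dropped <- attr(scored, "n_subjects_dropped")
    s$scored <- scored
    s
  })

  state <- pipeline_stage(state, "factor", function(s) {
    fcfg <- config$factor %||% list()
    if (identical(fcfg$enabled %||% TRUE, FALSE)) return(s)
    spec_groups <- default_loading_spec()
    models <- list()
    for (grp in spec_groups) {
      vars <- rownames(grp$loadings)
      if (!all(vars %in% names(s$scored))) next
      fm <- fit_factor_model(s$scored[vars], group = grp$name,
                             method = fcfg$method %||% "ml")
      sc <- compute_factor_scores(fm, s$scored[vars])
      names(sc) <- paste0("f_", names(sc), "_", substr(grp$name, 1, 3))
      s$scored <- dplyr::bind_cols(s$scored, sc)
      models[[grp$name]] <- fm
    }
    s$factor_models <- models
    if (length(models)) {
      s$loadings <- dplyr::bind_rows(lapply(models, tidy))
    }
    s
  })

  state <- pipeline_stage(state, "fit", function(s) {
    margs <- config$model %||% list()
    if (is.null(margs$fixed) && !is.null(s$sim_config)) {
      margs$fixed <- s$sim_config$fixed
      margs$slope <- s$sim_config$slope
    }
    spec <- do.call(mvml_spec, margs)
    design <- build_design(s$scored, spec)
    if (fit_which %in% c("both", "independent")) {
      s$fit_independent <- fit_independent(design)
    }
    if (fit_which %in% c("both", "related")) {
      s$fit_related <- fit_mvml(
        design, related = TRUE,
        start = if (!is.null(s$fit_independent))
          encode_theta(s$fit_independent$omega_G,
                       s$fit_independent$omega_R, TRUE, design$K))
    }
    s$fit_main <- s$fit_related %||% s$fit_independent
    s
  })

  state <- pipeline_stage(state, "report_tables", function(s) {
    if (!is.null(s$fit_related) && !is.null(s$fit_independent)) {
      s$comparison <- compare_models(s$fit_related, s$fit_independent)
    } else {
      s$comparison <- fit_statistics(s$fit_main) |>
        tidyr::pivot_longer(c("neg2_loglik", "aic", "aicc", "bic"),
                            names_to = "criterion") |>
        dplyr::select("criterion", "value")
    }
    s$effects <- effect_table(s$fit_main)
    rc <- random_effect_correlations(s$fit_main)
    s$re_correlations <- tibble::as_tibble(unclass(rc)) |>
      dplyr::mutate(effect = rownames(rc), .before = 1L)
    s$qq <- transformed_residuals(s$fit_main)
    cons <- config$contrasts %||% list(
      list(term = "viral_load", outcome_a = "ph", outcome_b = "psy",
           block = "baseline"),
      list(term = "viral_load", outcome_a = "ph", outcome_b = "psy",
           block = "slope"))
    cons <- purrr::keep(cons, function(cn) {
      ft <- if (cn$block == "slope") paste0("time:", cn$term) else cn$term
      any(s$fit_main$beta$term == ft & s$fit_main$beta$block == cn$block)
    })
    s$contrasts <- purrr::map_dfr(cons, function(cn) {
      contrast_effects(s$fit_main, cn$term, cn$outcome_a, cn$outcome_b,
                       cn$block)
    })
    s
  })

  state$manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("mvqol")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = rlang::hash(config),
    n_visits_dropped = state$n_dropped,
    pct_visits_dropped = state$pct_dropped,
    n_subjects_dropped = state$n_subjects_dropped,
    converged = if (!is.null(state$fit_main)) state$fit_main$converged,
    failed_stage = state$failed_stage)

  if (!is.null(out_dir)) write_report(state, out_dir)
  invisible(state)
}

#' Write the pipeline report bundle
#'
#' @param bundle A [run_pipeline()] result (possibly partial).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(dir, name)
    readr::write_csv(obj, p)
    paths[[name]] <<- p
  }
  put(bundle$scored, "cohort_scored.csv")
  put(bundle$loadings, "factor_loadings.csv")
  put(bundle$effects, "effect_table.csv")
  if (!is.null(bundle$comparison)) {
    put(tibble::as_tibble(bundle$comparison), "fit_statistics.csv")
  }
  put(bundle$re_correlations, "re_correlations.csv")
  put(bundle$contrasts, "contrasts.csv")
  put(bundle$qq, "qq_residuals.csv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  paths[["manifest.json"]] <- file.path(dir, "manifest.json")
  invisible(paths)
}
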