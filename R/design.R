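#' Specify a multivariate multilevel growth-curve model
#'
#' Describes the joint linear growth model for `K` outcome columns: each
#' outcome gets its own intercept, covariate effects (`fixed`), time slope
#' and covariate-by-time effects (`slope`), while the random part couples
#' outcomes through a `2K x 2K` covariance of random intercepts and slopes
#' and a `K x K` occasion-level residual covariance.
#'
#' @param outcomes Ordered character vector of outcome column names
#'   (default the four WHOQOL-HIV BREF domains `ph`, `psy`, `ind`, `soc`).
#' @param fixed Covariate names entering every outcome's baseline block.
#' @param slope Covariate names entering every outcome's time-interaction
#'   block (the time main effect is always included).
#' @param time Name of the time column (months since enrolment).
#' @param subject Name of the subject identifier column.
#' @param reference_levels Named list of full level orderings for
#'   categorical covariates; the first level is the reference category.
#' @param related Logical; `TRUE` fits the full cross-outcome covariance,
#'   `FALSE` the independent-outcome restriction.
#' @param estimation `"ML"` (default) or `"REML"`.
#' @return An object of class `mvml_spec`.
#' @export
mvml_spec <- function(outcomes = qol_domains(), fixed = character(),
                      slope = character(), time = "time",
                      subject = "subject_id", reference_levels = list(),
                      related = TRUE, estimation = c("ML", "REML")) {
  estimation <- match.arg(estimation)
  if (length(outcomes) < 1L) {
    abort("`outcomes` must name at least one outcome column.",
          class = "mvqol_validation_error")
  }
  structure(
    list(outcomes = outcomes, fixed = fixed, slope = slope, time = time,
         subject = subject, reference_levels = reference_levels,
         related = related, estimation = estimation),
    class = "mvml_spec")
}

# relevel categorical covariates against the spec's reference levels
apply_reference_levels <- function(data, spec) {
  for (v in union(spec$fixed, spec$slope)) {
    x <- data[[v]]
    if (is.character(x) || is.factor(x)) {
      lv <- spec$reference_levels[[v]] %||%
        (if (is.factor(x)) levels(x) else sort(unique(as.character(x))))
      bad <- setdiff(unique(as.character(x)), lv)
      if (length(bad)) {
        abort(sprintf("covariate `%s` has categories not in the reference schema: %s",
                      v, paste(bad, collapse = ", ")),
              class = "mvqol_validation_error")
      }
      data[[v]] <- factor(as.character(x), levels = lv)
    }
  }
  data
}

# baseline (B) and time-interaction (S) per-visit design blocks shared by
# all outcomes; S includes the time main effect as its first column
design_blocks <- function(data, spec) {
  data <- apply_reference_levels(data, spec)
  fb <- if (length(spec$fixed)) stats::reformulate(spec$fixed) else ~1
  B <- stats::model.matrix(fb, data)
  sb <- if (length(spec$slope)) stats::reformulate(spec$slope) else ~1
  S0 <- stats::model.matrix(sb, data)
  S <- S0 * data[[spec$time]]
  colnames(S) <- c("time", if (ncol(S0) > 1L)
    paste0("time:", colnames(S0)[-1L]))
  list(B = B, S = S)
}

#' Build the stacked per-subject design of the joint growth model
#'
#' Stacks the `K` outcomes visit-major (all outcomes of visit 1, then
#' visit 2, ...): for a subject with `n_j` visits the response has length
#' `K * n_j`, the fixed design is block-diagonal in outcome within visit,
#' and the random design maps the `2K` subject effects (intercepts then
#' slopes, outcome order preserved) onto the outcome-by-visit cells. With
#' this ordering the residual covariance enters as `I ⊗ Omega_R`.
#'
#' Visits are sorted by time within subject. Subjects with a missing
#' covariate, time or outcome value on any visit are excluded with a
#' message. Subjects sharing a visit schedule share one random-design
#' matrix, which the likelihood kernel factorises once per schedule.
#'
#' @param data Scored, filtered visit-level data frame.
#' @param spec An [mvml_spec()].
#' @param require_y Internal; `FALSE` builds covariate designs only.
#' @return An object of class `mvml_design`.
#' @export
build_design <- function(data, spec, require_y = TRUE) {
  stopifnot(inherits(spec, "mvml_spec"))
  need <- c(spec$subject, spec$time, union(spec$fixed, spec$slope),
            if (require_y) spec$outcomes)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("missing required columns: ", paste(miss, collapse = ", ")),
          class = "mvqol_validation_error")
  }
  if (!is.numeric(data[[spec$time]])) {
    abort(sprintf("time column `%s` must be numeric.", spec$time),
          class = "mvqol_validation_error")
  }
  K <- length(spec$outcomes)

  used <- unique(need)
  cc <- stats::complete.cases(data[used])
  bad_subj <- unique(data[[spec$subject]][!cc])
  n_excluded <- length(bad_subj)
  if (n_excluded) {
    message(sprintf("excluding %d subject(s) with missing values in model columns",
                    n_excluded))
    data <- data[!data[[spec$subject]] %in% bad_subj, , drop = FALSE]
  }
  if (!nrow(data)) {
    abort("no complete subjects left to build a design from.",
          class = "mvqol_validation_error")
  }
  ord <- order(match(data[[spec$subject]], unique(data[[spec$subject]])),
               data[[spec$time]])
  data <- data[ord, , drop = FALSE]

  blocks <- design_blocks(data, spec)
  B <- blocks$B
  S <- blocks$S
  terms_k <- c(colnames(B), colnames(S))
  p_k <- length(terms_k)
  n <- nrow(data)
  tm <- data[[spec$time]]

  Xrow <- cbind(B, S)
  Xbig <- matrix(0, K * n, K * p_k)
  ybig <- if (require_y) numeric(K * n) else NULL
  Zbig <- matrix(0, K * n, 2L * K)
  for (k in seq_len(K)) {
    rows <- seq(k, K * n, by = K)
    cols <- ((k - 1L) * p_k + 1L):(k * p_k)
    Xbig[rows, cols] <- Xrow
    if (require_y) ybig[rows] <- data[[spec$outcomes[k]]]
    Zbig[rows, k] <- 1
    Zbig[rows, K + k] <- tm
  }

  sid <- data[[spec$subject]]
  subj <- unique(sid)
  idx <- split(seq_len(n), factor(sid, levels = subj))
  sig <- vapply(idx, function(i) paste(signif(tm[i], 12), collapse = ","), "")
  usig <- unique(sig)
  gidx <- match(sig, usig)
  rows_of <- function(i) rep((i - 1L) * K, each = K) + seq_len(K)
  Zg <- lapply(usig, function(s) {
    i <- idx[[match(s, sig)]]
    Zbig[rows_of(i), , drop = FALSE]
  })
  Xs <- lapply(idx, function(i) Xbig[rows_of(i), , drop = FALSE])
  ys <- if (require_y) lapply(idx, function(i) ybig[rows_of(i)])

  labels <- tibble::tibble(
    outcome = rep(spec$outcomes, each = p_k),
    term = rep(terms_k, K),
    block = rep(c(rep("baseline", ncol(B)), rep("slope", ncol(S))), K))

  qr_chk <- if (require_y) qr(Xbig) else NULL
  if (require_y && qr_chk$rank < ncol(Xbig)) {
    off <- paste(labels$outcome, labels$term, sep = ":")[
      setdiff(seq_len(ncol(Xbig)), qr_chk$pivot[seq_len(qr_chk$rank)])]
    abort(paste0("fixed-effect design is rank deficient; offending columns: ",
                 paste(off, collapse = ", ")),
          class = "mvqol_validation_error")
  }

  structure(
    list(subjects = subj, y = ys, X = Xs, Zg = Zg, gidx = gidx,
         labels = labels, spec = spec, K = K, p_k = p_k,
         n_subjects = length(subj), n_visits = n,
         times = lapply(idx, function(i) tm[i]),
         n_excluded = n_excluded),
    class = "mvml_design")
}

#' @method print mvml_design
#' @export
print.mvml_design <- function(x, ...) {
  cat(sprintf("<mvml_design> %d subjects, %d visits, %d outcomes, %d fixed-effect columns\n",
              x$n_subjects, x$n_visits, x$K, x$K * x$p_k))
  invisible(x)
}
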