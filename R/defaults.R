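#' Reference clinical-panel loading structure
#'
#' Block loading pattern linking 9 latent components to the 24 routinely
#' collected clinical laboratory variables of an HIV cohort: white blood
#' cell, red blood cell, blood chemistry and protein panels, each factored
#' separately. Loadings follow the rotated-factor pattern estimated in the
#' CAPRISA 002 acute-infection cohort; uniquenesses are one minus the row
#' communalities, so every standardized variable has unit variance.
#'
#' @return A list with one element per variable group; each element carries
#'   `name` and a `loadings` matrix (variables x factors, dimnames set).
#' @export
default_loading_spec <- function() {
  wbc <- rbind(
    leucocyte   = c(0.925,  0.282,  0.146),
    neutrophils = c(0.936, -0.158,  0.022),
    lymphocytes = c(0.226,  0.838, -0.109),
    monocytes   = c(0.635,  0.417, -0.032),
    eosinophils = c(0.085,  0.058,  0.947),
    basophils   = c(-0.035, 0.616,  0.339))
  colnames(wbc) <- c("granulocytes", "mononuclear", "eosinophils_comp")

  rbc <- rbind(
    rbc_count   = c(0.946, -0.130),
    hb          = c(0.886,  0.439),
    haematocrit = c(0.919,  0.366),
    mcv         = c(0.075,  0.953),
    mch         = c(0.024,  0.825),
    mchc        = c(0.201,  0.521),
    rdw         = c(-0.382, -0.592))
  colnames(rbc) <- c("hb_haematocrit", "rbc_indices")

  chem <- rbind(
    chloride             = c(-0.023, 0.455),
    alkaline_phosphatase = c(0.174,  0.032),
    alt                  = c(0.829, -0.073),
    ast                  = c(0.967, -0.122),
    sodium               = c(0.103,  0.994),
    calcium              = c(-0.020, 0.213))
  colnames(chem) <- c("liver_abnormality", "electrolyte")

  prot <- rbind(
    cholesterol   = c(0.971,  0.027),
    ldl           = c(0.917, -0.129),
    triglycerides = c(0.360,  0.341),
    ldh           = c(0.052, -0.769),
    total_protein = c(-0.009, 0.670))
  colnames(prot) <- c("lipid", "protein")

  list(
    list(name = "white_blood_cell", loadings = wbc),
    list(name = "red_blood_cell", loadings = rbc),
    list(name = "blood_chemistry", loadings = chem),
    list(name = "protein", loadings = prot))
}

#' Reference random-effect correlation structure
#'
#' The 8 x 8 correlation matrix of the four domains' random intercepts and
#' random time slopes estimated in the CAPRISA 002 cohort, in the canonical
#' order (baseline ph, psy, ind, soc; slope ph, psy, ind, soc). The printed
#' estimates are very slightly indefinite (minimum eigenvalue -0.026), so
#' the matrix returned is the nearest positive semi-definite correlation
#' matrix (maximum entrywise change 0.0094).
#'
#' @param project Project to the nearest PSD correlation matrix (default
#'   `TRUE`). With `FALSE` the raw printed values are returned.
#' @return An 8 x 8 labelled correlation matrix.
#' @export
default_re_correlations <- function(project = TRUE) {
  # printed order: baseline (ind, ph, psy, soc), slope (ind, ph, psy, soc)
  C <- diag(8)
  lt <- rbind(
    c(2, 1,  0.49), c(3, 1,  0.42), c(3, 2,  0.94),
    c(4, 1,  0.60), c(4, 2,  0.61), c(4, 3,  0.58),
    c(5, 1, -0.60), c(5, 2, -0.66), c(5, 3, -0.53), c(5, 4, -0.51),
    c(6, 1, -0.50), c(6, 2, -0.93), c(6, 3, -0.84), c(6, 4, -0.60),
    c(6, 5,  0.84),
    c(7, 1, -0.47), c(7, 2, -0.93), c(7, 3, -0.89), c(7, 4, -0.58),
    c(7, 5,  0.81), c(7, 6,  0.90),
    c(8, 1, -0.48), c(8, 2, -0.65), c(8, 3, -0.56), c(8, 4, -0.69),
    c(8, 5,  0.86), c(8, 6,  0.84), c(8, 7,  0.81))
  C[lt[, 1:2]] <- lt[, 3]
  C[lt[, 2:1]] <- lt[, 3]
  perm <- c(2, 3, 1, 4, 6, 7, 5, 8)  # reorder to (ph, psy, ind, soc)
  C <- C[perm, perm]
  if (project) {
    C <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
  }
  nm <- c(paste0("u_", qol_domains()), paste0("v_", qol_domains()))
  dimnames(C) <- list(nm, nm)
  C
}

# default Omega_G: reference correlations scaled by intercept SD 1.5
# (score points) and slope SD 0.05 (points per month)
default_omega_G <- function() {
  sds <- rep(c(1.5, 0.05), each = 4L)
  C <- default_re_correlations()
  diag(sds) %*% C %*% diag(sds) |>
    structure(dimnames = dimnames(C))
}

# default Omega_R: unit residual variances, 0.3 cross-domain correlation
default_omega_R <- function() {
  R <- matrix(0.3, 4, 4)
  diag(R) <- 1
  dimnames(R) <- list(qol_domains(), qol_domains())
  R
}

#' Default covariate generating distributions
#'
#' Categorical frequencies mirror the enrolment table of the CAPRISA 002
#' cohort (counts over 219 women); reference categories match the fitted
#' model's (age <=20, education <=8 grade, marital status many partners,
#' TB yes, anemia yes, adverse event severe, thrombocytopenia no, sex
#' while drunk no). Weight, viral load and the clinical panel vary from
#' visit to visit; the remaining covariates are drawn once per subject.
#'
#' @return A named list of covariate specifications.
#' @export
default_covariate_spec <- function() {
  list(
    age_group = list(type = "categorical", time_varying = FALSE,
                     levels = c("<=20", "21-39", "40-59"),
                     probs = c(0.10, 0.85, 0.05)),
    education = list(type = "categorical", time_varying = FALSE,
                     levels = c("<=8", "9-10", ">=11"),
                     probs = c(16, 50, 153) / 219),
    marital = list(type = "categorical", time_varying = FALSE,
                   levels = c("many", "single", "stable"),
                   probs = c(11, 34, 174) / 219),
    tb = list(type = "categorical", time_varying = FALSE,
              levels = c("yes", "no"), probs = c(18, 201) / 219),
    anemia = list(type = "categorical", time_varying = FALSE,
                  levels = c("yes", "no"), probs = c(11, 208) / 219),
    thrombocytopenia = list(type = "categorical", time_varying = FALSE,
                            levels = c("no", "yes"), probs = c(0.92, 0.08)),
    adverse_event = list(type = "categorical", time_varying = FALSE,
                         levels = c("severe", "normal", "mild", "advanced"),
                         probs = c(0.10, 0.50, 0.25, 0.15)),
    sex_drunk = list(type = "categorical", time_varying = FALSE,
                     levels = c("no", "yes"), probs = c(197, 22) / 219),
    contraceptive = list(type = "categorical", time_varying = FALSE,
                         levels = c("yes", "no"), probs = c(179, 40) / 219),
    weight = list(type = "continuous", time_varying = TRUE,
                  mean = 70, sd = 12, visit_sd = 1.5),
    viral_load = list(type = "continuous", time_varying = TRUE,
                      mean = 4.45, sd = 0.8, visit_sd = 0.3,
                      lower = 1.47, upper = 6.81))
}

# default fixed-effect values per (term, outcome), outcome order
# (ph, psy, ind, soc); terms use model.matrix dummy naming
default_beta <- function() {
  list(
    "(Intercept)"          = c(10.80,  9.63, 12.80, 13.50),
    "time"                 = c(0.18,  0.21,  0.05,  0.03),
    "viral_load"           = c(-0.21, -0.29, -0.09, -0.06),
    "weight"               = c(0.01,  0.01,  0.01, -0.01),
    "tbno"                 = c(0.38,  0.01,  0.16,  0.05),
    "age_group21-39"       = c(-0.34,  0.26, -1.89, -1.25),
    "age_group40-59"       = c(0.26,  0.79, -1.49, -0.09),
    "education9-10"        = c(0.60,  0.25,  0.53,  0.65),
    "education>=11"        = c(0.22,  1.26,  0.54,  0.20),
    "time:viral_load"      = c(-0.06, -0.01, -0.001, -0.001),
    "time:weight"          = c(0.01,  0.01,  0.001,  0.001),
    "time:age_group21-39"  = c(0.02,  0.00,  0.07,  0.06),
    "time:age_group40-59"  = c(-0.01, -0.01,  0.07,  0.01))
}

# CAPRISA-like visit schedule (months): weekly to month 3, monthly to
# month 12, quarterly thereafter up to ~6 years (41 scheduled visits)
default_schedule <- function() {
  c(seq(0, 3, by = 0.25), 4:12, seq(15, 69, by = 3))
}
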