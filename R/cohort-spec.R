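#' Declare one candidate predictor for cohort simulation
#'
#' A predictor is declared by its measurement kind and, for the generator, an
#' optional ground-truth effect on the natural-log age at onset per unit of the
#' *encoded* variable (0/1 for a binary predictor or dummy level, one standard
#' deviation for a numeric predictor).
#'
#' @param name Identifier (syntactic column name).
#' @param kind One of `"binary"`, `"categorical"`, `"numeric"`.
#' @param levels Character vector of level labels (categorical only, length
#'   >= 2; the first level is the dummy-coding reference).
#' @param prevalence Probability in (0, 1) that a binary predictor equals 1.
#'   Defined iff `kind == "binary"`.
#' @param block Optional correlation-block tag (documentation only; the
#'   correlation structure itself lives in [cohort_spec()]).
#' @param true_effect Signed finite effect on log age-at-onset per unit of the
#'   encoded variable; scalar, or for a categorical predictor a vector of
#'   length `length(levels) - 1` (one per non-reference level).  Defaults to 0
#'   (a null predictor).
#' @param level_weights Optional probabilities for categorical levels (must sum
#'   to 1); default is equiprobable levels.
#' @return A `predictor_spec` list.
#' @export
predictor_spec <- function(name, kind = c("binary", "categorical", "numeric"),
                           levels = NULL, prevalence = NULL, block = NULL,
                           true_effect = 0, level_weights = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2L)
      stop("categorical predictor '", name, "' needs >= 2 levels", call. = FALSE)
    k <- length(levels)
    if (length(true_effect) == 1L) true_effect <- rep(true_effect, k - 1L)
    if (length(true_effect) != k - 1L)
      stop("true_effect for '", name, "' must have length 1 or K-1", call. = FALSE)
    if (!is.null(level_weights)) {
      stopifnot(length(level_weights) == k, all(level_weights > 0),
                abs(sum(level_weights) - 1) < 1e-8)
    }
  } else {
    if (!is.null(levels)) stop("levels are for categorical predictors only", call. = FALSE)
    if (length(true_effect) != 1L)
      stop("true_effect for '", name, "' must be scalar", call. = FALSE)
  }
  if (kind == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("binary predictor '", name, "' needs prevalence in (0,1)", call. = FALSE)
  } else if (!is.null(prevalence)) {
    stop("prevalence is defined only for binary predictors", call. = FALSE)
  }
  if (!all(is.finite(true_effect)))
    stop("true_effect for '", name, "' must be finite", call. = FALSE)
  structure(list(name = name, kind = kind, levels = levels,
                 prevalence = prevalence, block = block,
                 true_effect = true_effect, level_weights = level_weights),
            class = "predictor_spec")
}

#' Declare a synthetic cohort
#'
#' @param n Participant count (>= 1).
#' @param predictors List of [predictor_spec()] objects.
#' @param latent_correlation Symmetric unit-diagonal positive-semidefinite
#'   matrix over predictors on the Gaussian-copula (latent) scale; default
#'   identity.
#' @param intercept_log_age Mean of log age-at-onset at the predictor baseline.
#' @param noise_sd_log Positive standard deviation of the log-normal outcome
#'   noise.
#' @param missing_rate Per-cell predictor missingness probability in [0, 1),
#'   applied by [inject_missingness()] (the generator itself emits a complete
#'   table).
#' @param era_fraction_pre_cutoff Fraction of participants given a collection
#'   year before the era cutoff (2008).
#' @param truncate_aao_65 If `TRUE`, rows with simulated age at onset >= 65
#'   years are dropped (mirrors a cohort inclusion criterion); off by default
#'   because truncation distorts the log-linear generative model.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n, predictors, latent_correlation = NULL,
                        intercept_log_age = 3.1, noise_sd_log = 0.35,
                        missing_rate = 0, era_fraction_pre_cutoff = 0,
                        truncate_aao_65 = FALSE) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  ok <- vapply(predictors, inherits, logical(1), "predictor_spec")
  if (!all(ok)) stop("predictors must be a list of predictor_spec objects", call. = FALSE)
  nms <- vapply(predictors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate predictor names", call. = FALSE)
  p <- length(predictors)
  if (is.null(latent_correlation)) latent_correlation <- diag(p)
  R <- as.matrix(latent_correlation)
  if (!isTRUE(all.equal(dim(R), c(p, p))))
    stop("latent_correlation must be ", p, " x ", p, call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8) stop("latent_correlation must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8) stop("latent_correlation must have unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("latent_correlation is not positive semidefinite (smallest eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  if (!(noise_sd_log > 0)) stop("noise_sd_log must be > 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)", call. = FALSE)
  if (era_fraction_pre_cutoff < 0 || era_fraction_pre_cutoff > 1)
    stop("era_fraction_pre_cutoff must be in [0,1]", call. = FALSE)
  structure(list(n = as.integer(n), predictors = predictors,
                 latent_correlation = R,
                 intercept_log_age = intercept_log_age,
                 noise_sd_log = noise_sd_log, missing_rate = missing_rate,
                 era_fraction_pre_cutoff = era_fraction_pre_cutoff,
                 truncate_aao_65 = isTRUE(truncate_aao_65)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  kinds <- table(vapply(x$predictors, `[[`, character(1), "kind"))
  cat("cohort_spec: n =", x$n, "|", length(x$predictors), "predictors (",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), ")\n")
  cat("  intercept_log_age =", x$intercept_log_age,
      " noise_sd_log =", x$noise_sd_log,
      " missing_rate =", x$missing_rate, "\n")
  invisible(x)
}

# Latent correlation matrix for the default 28-predictor cohort.  The seven
# personality/temperament traits form a correlated block (the field's trait
# clustering), spanning pairwise r from -0.21 to 0.68; substance-use measures
# share mild correlations.  All other predictors are latently independent.
default_latent_correlation <- function(names) {
  p <- length(names)
  R <- diag(p)
  dimnames(R) <- list(names, names)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  trait <- c("neuroticism", "schizotypy", "cyclothymic_temperament",
             "depressive_temperament", "irritable_temperament",
             "hyperthymic_temperament", "anxious_temperament")
  if (all(trait %in% names)) {
    set_r("neuroticism", "schizotypy", 0.40)
    set_r("neuroticism", "cyclothymic_temperament", 0.45)
    set_r("neuroticism", "depressive_temperament", 0.50)
    set_r("neuroticism", "irritable_temperament", 0.30)
    set_r("neuroticism", "hyperthymic_temperament", -0.21)
    set_r("neuroticism", "anxious_temperament", 0.68)
    set_r("schizotypy", "cyclothymic_temperament", 0.35)
    set_r("schizotypy", "depressive_temperament", 0.30)
    set_r("schizotypy", "irritable_temperament", 0.30)
    set_r("schizotypy", "hyperthymic_temperament", 0.05)
    set_r("schizotypy", "anxious_temperament", 0.35)
    set_r("cyclothymic_temperament", "depressive_temperament", 0.55)
    set_r("cyclothymic_temperament", "irritable_temperament", 0.45)
    set_r("cyclothymic_temperament", "hyperthymic_temperament", 0.25)
    set_r("cyclothymic_temperament", "anxious_temperament", 0.40)
    set_r("depressive_temperament", "irritable_temperament", 0.35)
    set_r("depressive_temperament", "hyperthymic_temperament", -0.21)
    set_r("depressive_temperament", "anxious_temperament", 0.50)
    set_r("irritable_temperament", "hyperthymic_temperament", 0.15)
    set_r("irritable_temperament", "anxious_temperament", 0.30)
    set_r("hyperthymic_temperament", "anxious_temperament", -0.10)
  }
  subst <- c("alcohol_units_per_week", "cannabis_use_pre_onset",
             "other_drug_use_pre_onset")
  if (all(subst %in% names)) {
    set_r("alcohol_units_per_week", "cannabis_use_pre_onset", 0.25)
    set_r("cannabis_use_pre_onset", "other_drug_use_pre_onset", 0.35)
    set_r("alcohol_units_per_week", "other_drug_use_pre_onset", 0.20)
  }
  R
}

#' Default 28-predictor cohort specification
#'
#' Emulates the structure of a UK bipolar-disorder research cohort: 28
#' candidate psychosocial predictors (family history, childhood abuse,
#' substance use, education, premorbid adjustment, seven personality/
#' temperament trait scores forming a correlated block, and eleven yes/no life
#' events), a positive age-at-onset outcome generated log-normally, and a
#' sparse ground-truth signal: 11 predictors carry the published signed
#' effects on log age at onset (six negative, from childhood abuse -0.2855 to
#' irritable temperament -0.0685; five positive, from weekly alcohol units
#' +0.1385 to a major financial crisis +0.4575) and the remaining 17 are null.
#'
#' Binary prevalences are fixed at values typical of such cohorts; the
#' intercept (3.1 on the log scale) and noise (0.35 log-years) give a mean
#' simulated onset age of about 23 years.
#'
#' @param n Participant count (default 1022).
#' @param noise_sd_log Outcome noise s.d. on the log scale (default 0.35).
#' @param missing_rate Per-cell predictor missingness (default 0).
#' @param era_fraction_pre_cutoff Fraction of participants collected before
#'   the 2008 era cutoff (default 0).
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n = 1022, noise_sd_log = 0.35,
                                missing_rate = 0,
                                era_fraction_pre_cutoff = 0) {
  ps <- list(
    predictor_spec("family_history_affective", "binary", prevalence = 0.45),
    predictor_spec("family_history_psychiatric", "binary", prevalence = 0.35),
    predictor_spec("family_history_suicide", "binary", prevalence = 0.20,
                   true_effect = -0.1385),
    predictor_spec("childhood_abuse", "binary", prevalence = 0.30,
                   true_effect = -0.2855),
    predictor_spec("alcohol_units_per_week", "numeric", block = "substance",
                   true_effect = 0.1385),
    predictor_spec("cannabis_use_pre_onset", "binary", prevalence = 0.20,
                   block = "substance", true_effect = -0.2765),
    predictor_spec("other_drug_use_pre_onset", "binary", prevalence = 0.15,
                   block = "substance"),
    predictor_spec("education_level", "categorical",
                   levels = c("no_qualifications", "secondary", "further", "degree")),
    predictor_spec("poor_premorbid_work_adjustment", "binary", prevalence = 0.25),
    predictor_spec("poor_premorbid_social_adjustment", "binary", prevalence = 0.25),
    predictor_spec("neuroticism", "numeric", block = "trait"),
    predictor_spec("schizotypy", "numeric", block = "trait", true_effect = -0.1055),
    predictor_spec("cyclothymic_temperament", "numeric", block = "trait"),
    predictor_spec("depressive_temperament", "numeric", block = "trait"),
    predictor_spec("irritable_temperament", "numeric", block = "trait",
                   true_effect = -0.0685),
    predictor_spec("hyperthymic_temperament", "numeric", block = "trait"),
    predictor_spec("anxious_temperament", "numeric", block = "trait"),
    predictor_spec("le_marital_separation", "binary", prevalence = 0.12),
    predictor_spec("le_serious_illness_self", "binary", prevalence = 0.10),
    predictor_spec("le_serious_illness_relative", "binary", prevalence = 0.15),
    predictor_spec("le_death_parent_partner_child_sibling", "binary",
                   prevalence = 0.10, true_effect = 0.3125),
    predictor_spec("le_death_close_friend_or_relative", "binary",
                   prevalence = 0.15, true_effect = -0.2435),
    predictor_spec("le_birth_of_child", "binary", prevalence = 0.08,
                   true_effect = 0.2755),
    predictor_spec("le_seeking_work_unsuccessfully", "binary", prevalence = 0.10,
                   true_effect = 0.3505),
    predictor_spec("le_major_financial_crisis", "binary", prevalence = 0.08,
                   true_effect = 0.4575),
    predictor_spec("le_sacked_from_job", "binary", prevalence = 0.08),
    predictor_spec("le_police_contact", "binary", prevalence = 0.08),
    predictor_spec("le_something_stolen", "binary", prevalence = 0.10)
  )
  nms <- vapply(ps, `[[`, character(1), "name")
  cohort_spec(n = n, predictors = ps,
              latent_correlation = default_latent_correlation(nms),
              intercept_log_age = 3.1, noise_sd_log = noise_sd_log,
              missing_rate = missing_rate,
              era_fraction_pre_cutoff = era_fraction_pre_cutoff)
}

#' Names of the predictors carrying a nonzero ground-truth effect
#'
#' @param spec A `cohort_spec`.
#' @return Character vector of predictor names with any nonzero `true_effect`.
#' @export
true_effect_predictors <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  keep <- vapply(spec$predictors, function(p) any(p$true_effect != 0), logical(1))
  vapply(spec$predictors[keep], `[[`, character(1), "name")
}

#' Ground-truth effects of a cohort spec on the encoded scale
#'
#' @param spec A `cohort_spec`.
#' @return Named numeric vector, one entry per encoded column (binary and
#'   numeric predictors contribute one column; a K-level categorical
#'   contributes K-1 named `<name>.<level>` columns).
#' @export
true_effect_vector <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- numeric(0)
  for (p in spec$predictors) {
    if (p$kind == "categorical") {
      nm <- paste(p$name, p$levels[-1L], sep = ".")
      v <- setNames(p$true_effect, nm)
    } else {
      v <- setNames(p$true_effect, p$name)
    }
    out <- c(out, v)
  }
  out
}
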