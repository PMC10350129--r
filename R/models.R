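# The library of confirmatory factor models over the standard
# symptom-by-cohort-class label set.
#
# Labels are "<class>_<symptom>" with classes clin (clinical meta-analysis),
# comm (community meta-analysis) and ukbt (UK Biobank touchscreen), and the
# directional symptom abbreviations of the bundled prevalence table.

#' Standard indicator label set for the model library
#'
#' The symptom-by-cohort-class traits that pass the inclusion rule
#' (positive SNP heritability and sufficient effective sample size):
#' clinical cohorts lose the cardinal and fatigue/concentration symptoms
#' (negative heritability under strong ascertainment), community cohorts
#' lose the psychomotor symptoms (insufficient N), and the touchscreen
#' assessment contributes the two cardinal symptoms only.
#'
#' @return character vector of 20 labels.
#' @export
standard_model_labels <- function() {
  c(paste0("clin_", c("AppDec", "AppInc", "SleDec", "SleInc", "MotoInc",
                      "MotoDec", "Guilt", "Sui")),
    paste0("comm_", c("Dep", "Anh", "AppDec", "AppInc", "SleDec", "SleInc",
                      "Fatig", "Guilt", "Conc", "Sui")),
    paste0("ukbt_", c("Dep", "Anh")))
}

label_class <- function(labels) sub("_.*$", "", labels)
label_symptom <- function(labels) sub("^[^_]*_", "", labels)
symptom_base <- function(symptoms) sub("(Dec|Inc)$", "", symptoms)

GATING_LABELS <- c("comm_Dep", "comm_Anh", "ukbt_Dep", "ukbt_Anh")

# Symptom groupings used by the two/three-factor models. Groups are over
# collapsed base names unless directional names are listed explicitly.
MODEL_GROUPS <- list(
  E = list(Psychological = c("Dep", "Anh", "Guilt", "Sui", "Conc"),
           Somatic = c("App", "Sle", "Moto", "Fatig")),
  F = list(Psychological = c("Dep", "Anh", "Guilt", "Sui"),
           Neurovegetative = c("App", "Sle", "Moto", "Fatig", "Conc")),
  G = list(Affective = c("Dep", "Guilt", "Sui"),
           Neurovegetative = c("App", "Sle", "Moto", "Fatig", "Conc", "Anh")),
  H = list(Cognitive = c("Guilt", "Conc", "Sui"),
           Mood = c("Dep", "Anh", "Guilt"),
           Neurovegetative = c("App", "Sle", "Moto", "Fatig")),
  I = list(Appetite = c("AppDec", "AppInc"),
           Vegetative = c("SleInc", "MotoDec", "Fatig", "Conc"),
           CognitiveMood = c("Dep", "Anh", "SleDec", "MotoInc", "Guilt", "Sui")),
  J = list(Melancholic = c("Anh", "SleDec", "MotoInc", "AppDec", "Guilt"),
           Atypical = c("SleInc", "AppInc", "MotoDec", "Fatig"),
           AffectiveCognitive = c("Dep", "Sui", "Conc")))

# Directional-only groups cannot be compiled against collapsed labels.
DIRECTIONAL_MODELS <- c("I", "J")

#' Build a library model (A-J)
#'
#' * A: one common factor on all indicators.
#' * B: correlated Clinical and Community factors (touchscreen indicators
#'   grouped with Community).
#' * C: common factor plus an orthogonal Gating factor on the community and
#'   touchscreen cardinal symptoms (low mood, anhedonia), absorbing the
#'   variance induced by their use as gating items.
#' * D: B plus the orthogonal Gating factor.
#' * E-H: symptom-content groupings (psychological/somatic,
#'   psychological/neurovegetative, affective/neurovegetative, and the
#'   cognitive/mood/neurovegetative three-factor model), each with the
#'   Gating factor.
#' * I: Appetite, Vegetative and Cognitive/Mood factors over directional
#'   symptoms, with Gating.
#' * J: Melancholic, Atypical and Affective/Cognitive factors, with Gating.
#'
#' @param key model letter "A".."J".
#' @param labels indicator label set (default [standard_model_labels()]);
#'   factors compile against the labels actually present.
#' @param residual_cohort_cors add free residual correlations between the
#'   clinical and community versions of appetite decrease/increase,
#'   insomnia, hypersomnia and suicidality.
#' @param gating include the Gating factor in the symptom models E-J
#'   (default TRUE, as in the best-measurement-model workflow); ignored for
#'   A and B (no gating) and C and D (always gating).
#' @return [model_spec()].
#' @export
model_library <- function(key, labels = standard_model_labels(),
                          residual_cohort_cors = FALSE, gating = TRUE) {
  if (!is.character(key) || length(key) != 1L || !key %in% LETTERS[1:10])
    stop("unknown model key; valid keys: ", paste(LETTERS[1:10], collapse = ", "))
  k <- length(labels)
  cls <- label_class(labels)
  sym <- label_symptom(labels)
  fac <- list()
  orthogonal <- character()
  if (key == "A") {
    fac$General <- labels
  } else if (key %in% c("B", "D")) {
    fac$Clinical <- labels[cls == "clin"]
    fac$Community <- labels[cls %in% c("comm", "ukbt")]
  } else if (key == "C") {
    fac$General <- labels
  } else {
    if (key %in% DIRECTIONAL_MODELS && !any(grepl("(Dec|Inc)$", sym)))
      stop("model ", key, " needs directional symptom labels")
    groups <- MODEL_GROUPS[[key]]
    # group entries are either directional symptom names or collapsed base
    # names; an indicator matches on its own name or its base name
    for (g in names(groups)) {
      sel <- sym %in% groups[[g]] | symptom_base(sym) %in% groups[[g]]
      fac[[g]] <- labels[sel]
    }
  }
  use_gating <- key %in% c("C", "D") || (gating && !key %in% c("A", "B"))
  if (use_gating) {
    gl <- intersect(GATING_LABELS, labels)
    if (length(gl) >= 2L) {
      fac$Gating <- gl
      orthogonal <- "Gating"
    }
  }
  empty <- names(fac)[vapply(fac, length, integer(1)) == 0L]
  if (length(empty)) {
    warning("dropping factor(s) with no indicators in this label set: ",
            paste(empty, collapse = ", "))
    fac <- fac[setdiff(names(fac), empty)]
  }
  build_factor_spec(fac, labels, orthogonal = orthogonal,
                    resid_cov = if (residual_cohort_cors)
                      cohort_residual_pairs(labels) else NULL)
}

# Free residual correlations of the same symptom across cohort classes.
cohort_residual_pairs <- function(labels,
                                  symptoms = c("AppDec", "AppInc", "SleDec",
                                               "SleInc", "Sui")) {
  prs <- list()
  for (sy in symptoms) {
    a <- paste0("clin_", sy); b <- paste0("comm_", sy)
    if (all(c(a, b) %in% labels)) prs[[sy]] <- c(a, b)
  }
  prs
}

#' Build a [model_spec()] from factor -> indicator lists
#'
#' @param factors named list of indicator label vectors.
#' @param labels full indicator label set (defaults to union of the lists).
#' @param orthogonal factor names whose correlations with all other factors
#'   are fixed to 0.
#' @param resid_cov list of indicator pairs with free residual covariance.
#' @return [model_spec()].
#' @export
build_factor_spec <- function(factors, labels = NULL, orthogonal = character(),
                              resid_cov = NULL) {
  labels <- labels %||% unique(unlist(factors))
  used <- labels[labels %in% unlist(factors)]
  f <- length(factors)
  L <- matrix(0, length(used), f,
              dimnames = list(used, names(factors)))
  for (g in names(factors)) L[intersect(used, factors[[g]]), g] <- NA_real_
  P <- matrix(NA_real_, f, f, dimnames = list(names(factors), names(factors)))
  diag(P) <- 1
  for (g in orthogonal) {
    P[g, setdiff(names(factors), g)] <- 0
    P[setdiff(names(factors), g), g] <- 0
  }
  model_spec(L, factor_corr = P, resid_cov = resid_cov)
}

#' Model comparison table across library models
#'
#' @param scv `gencov_structure`.
#' @param keys model letters to fit.
#' @param labels indicator set (default: the structure's labels).
#' @param ... passed to [fit_model()] / [model_library()].
#' @return data.table: model, chisq, df, AIC, dAIC, CFI, SRMR, converged.
#' @export
compare_models <- function(scv, keys = c("A", "B", "C", "D"),
                           labels = NULL, ...) {
  labels <- labels %||% scv$labels
  rows <- lapply(keys, function(kk) {
    fit <- tryCatch(fit_model(model_library(kk, labels = labels), scv, ...),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.table::data.table(model = kk, chisq = NA_real_,
                                    df = NA_integer_, AIC = NA_real_,
                                    CFI = NA_real_, SRMR = NA_real_,
                                    converged = FALSE))
    data.table::data.table(model = kk, chisq = fit$chisq, df = fit$df,
                           AIC = fit$aic, CFI = fit$cfi, SRMR = fit$srmr,
                           converged = fit$converged)
  })
  out <- data.table::rbindlist(rows)
  out[, "dAIC" := out$AIC - min(out$AIC, na.rm = TRUE)]
  out[]
}
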