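# The bundled demonstration study: study conditions for the end-to-end
# simulated analyses (and the measurement-design experiment contrasting a
# gated community cohort with a DSM-ascertained clinical cohort).
#
# These defaults define the simulated study; they are documented in the
# methods vignette and are not meant to be tuned per run.

#' Demonstration truth: one genetic factor over nine DSM criteria symptoms
#'
#' A single common factor with loadings 0.7, liability heritability 0.2 for
#' every symptom, and lifetime population prevalences in the 0.10-0.30
#' range (cardinal symptoms most prevalent).
#'
#' @return [true_structure()].
#' @export
demo_truth <- function() {
  labels <- c("Dep", "Anh", "App", "Sle", "Moto", "Fatig", "Guilt", "Conc",
              "Sui")
  true_structure(
    symptom_labels = labels,
    loadings = matrix(0.7, length(labels), 1,
                      dimnames = list(labels, "MDD")),
    h2_liab = rep(0.2, length(labels)),
    prevalence_pop = c(Dep = 0.30, Anh = 0.25, App = 0.20, Sle = 0.25,
                       Moto = 0.15, Fatig = 0.30, Guilt = 0.20, Conc = 0.25,
                       Sui = 0.10))
}

#' Demonstration study configuration
#'
#' A gated community cohort (n = 10,000; low mood and anhedonia as gating
#' symptoms, plus an ungated touchscreen-style second assessment of both,
#' reliability 0.8) and a clinical cohort ascertained by the DSM rule (at
#' least 5 of 9 criteria incl. one cardinal) from a population pool of
#' 16,000, over 1,000 unlinked SNPs with a synthetic LD profile.
#'
#' @param seed integer seed.
#' @param mode "individual" or "sumstat_direct".
#' @param m_snps SNP count (default 1000).
#' @param n_community,n_clinical_pool cohort sizes.
#' @return [simulation_config()].
#' @export
demo_study_config <- function(seed = 1L, mode = "individual",
                              m_snps = 1000L, n_community = 10000L,
                              n_clinical_pool = 16000L) {
  truth <- demo_truth()
  community <- cohort_design(
    "comm", "community", n_community, gate_symptoms = c("Dep", "Anh"),
    repeat_measures = list(
      TSDep = list(symptom = "Dep", reliability = 0.8),
      TSAnh = list(symptom = "Anh", reliability = 0.8)))
  clinical <- cohort_design("clin", "clinical", n_clinical_pool,
                            rule = list(min_total = 5L,
                                        cardinal = c("Dep", "Anh")))
  simulation_config(truth, list(community, clinical), m_snps = m_snps,
                    seed = seed, mode = mode,
                    ld = synthetic_ld_profile(m_snps, seed = seed))
}

#' Run GWAS of every symptom in a simulated cohort
#'
#' @param data `individual_cohort`.
#' @param min_n minimum non-missing phenotypes per symptom (symptoms below
#'   are skipped).
#' @return named list of `sumstat` tables.
#' @export
cohort_gwas <- function(data, min_n = 30L) {
  out <- list()
  for (sy in data$labels) {
    n_ok <- sum(!is.na(data$symptoms[, sy]))
    if (n_ok < min_n) next
    out[[paste(data$cohort, sy, sep = "_")]] <- gwas_symptom(data, sy, min_n)
  }
  out
}

#' One replicate of the measurement-design experiment
#'
#' Simulates the demonstration study at the individual level, runs all
#' symptom GWAS, estimates the joint genetic covariance structure
#' (observed scale), applies the inclusion rule (h2 > 0, N_eff above the
#' scaled threshold), and fits the common-factor model (A) and the
#' common-plus-orthogonal-Gating model (C). The gating factor loads on the
#' community cardinal symptoms, the only indicators measured on the full
#' (ungated) sample.
#'
#' @param seed replicate seed.
#' @param config optional [demo_study_config()] override.
#' @param min_n_eff inclusion threshold on N (500: the paper-scale 5000
#'   criterion rescaled to the desk-scale cohort sizes).
#' @param n_blocks jackknife blocks; default NULL chooses
#'   max(200, u + 30) where u = k(k+1)/2 is the number of unique covariance
#'   moments, so the jointly jackknifed V has full rank.
#' @return list: aic_a, aic_c, fits, included labels, scv.
#' @export
measurement_design_replicate <- function(seed, config = NULL,
                                         min_n_eff = 500, n_blocks = NULL) {
  config <- config %||% demo_study_config(seed = seed)
  tabs <- list()
  for (cohort in config$cohorts) {
    dat <- simulate_individual_cohort(config, cohort)
    tabs <- c(tabs, cohort_gwas(dat))
  }
  # common polymorphic variant set across all traits
  poly <- Reduce(intersect, lapply(tabs, function(t) t$SNP[!t$MONO]))
  tabs <- lapply(tabs, function(t) {
    out <- t[match(poly, t$SNP)]
    new_sumstat(out, attr(t, "cohort"), attr(t, "symptom"))
  })
  lprof <- config$ld %||% rep(1, config$m_snps)
  ld <- ld_scores(poly, lprof[match(poly, paste0("rs", seq_len(config$m_snps)))],
                  M = config$m_snps)
  kk_all <- length(tabs)
  n_blocks <- n_blocks %||% max(200L, kk_all * (kk_all + 1L) / 2 + 30L)
  scv <- build_S_V(tabs, ld, n_blocks = n_blocks)
  wp <- well_powered_filter(scv, min_mean_chi2 = 0, min_n_eff = min_n_eff)
  included <- wp$included
  comm <- config$cohorts[[1L]]
  gates <- intersect(
    paste0(comm$name, "_", c(comm$gate_symptoms, names(comm$repeat_measures))),
    included)
  spec_a <- build_factor_spec(list(General = included), included)
  spec_c <- build_factor_spec(list(General = included, Gating = gates),
                              included, orthogonal = "Gating")
  fit_a <- fit_model(spec_a, scv, seed = seed)
  # warm-start the gating model from the nested common-factor solution
  kk <- length(included)
  start_c <- c(fit_a$theta[seq_len(kk)], rep(0.05, length(gates)),
               fit_a$theta[kk + seq_len(kk)])
  fit_c <- fit_model(spec_c, scv, seed = seed, start = start_c)
  list(aic_a = fit_a$aic, aic_c = fit_c$aic, fit_a = fit_a, fit_c = fit_c,
       included = included, scv = scv)
}
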