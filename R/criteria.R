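# Diagnostic-rule combinatorics, prevalence bookkeeping, and significance
# tiers for symptom-level GWAS meta-analyses.

#' Define a categorical diagnosis rule
#'
#' A rule in the DSM style: a diagnosis requires at least `min_total` of
#' `n_criteria` criteria, of which at least one must come from the cardinal
#' set (for major depression: depressed mood or anhedonia).
#'
#' @param n_criteria total number of criteria (DSM MDD: 9).
#' @param cardinal indices of cardinal criteria (default `1:2`).
#' @param min_total minimum criteria count for diagnosis (DSM MDD: 5).
#' @return object of class `diagnosis_rule`.
#' @export
diagnosis_rule <- function(n_criteria = 9L, cardinal = 1:2, min_total = 5L) {
  n_criteria <- as.integer(n_criteria)
  cardinal <- as.integer(cardinal)
  min_total <- as.integer(min_total)
  stopifnot(n_criteria >= 1L, min_total >= 1L, min_total <= n_criteria,
            all(cardinal >= 1L), all(cardinal <= n_criteria),
            !anyDuplicated(cardinal))
  structure(list(n_criteria = n_criteria, cardinal = cardinal,
                 min_total = min_total),
            class = "diagnosis_rule")
}

#' Count qualifying symptom profiles under a diagnosis rule
#'
#' Exhaustively enumerates all 2^n subsets of criteria and counts those with
#' at least `min_total` members including at least one cardinal criterion.
#' For the DSM major-depression rule (9 criteria, 2 cardinal, >= 5 total)
#' there are 227 qualifying profiles.
#'
#' @param rule a [diagnosis_rule()].
#' @param keep_subsets return the qualifying subsets themselves (only
#'   honoured for n_criteria <= 16).
#' @return list with `count` and, optionally, `subsets` (a logical matrix,
#'   one row per qualifying profile).
#' @export
enumerate_profiles <- function(rule = diagnosis_rule(), keep_subsets = FALSE) {
  stopifnot(inherits(rule, "diagnosis_rule"))
  n <- rule$n_criteria
  if (n > 25L) stop("refusing to enumerate 2^", n, " subsets (n_criteria > 25)")
  card_mask <- sum(bitwShiftL(1L, rule$cardinal - 1L))
  count <- 0L
  subsets <- NULL
  collect <- keep_subsets && n <= 16L
  chunk <- 2^min(n, 20L)
  total <- 2^n
  done <- 0
  while (done < total) {
    m <- done + seq_len(min(chunk, total - done)) - 1
    size <- integer(length(m))
    for (b in 0:(n - 1L)) size <- size + bitwAnd(bitwShiftR(m, b), 1)
    ok <- size >= rule$min_total & bitwAnd(m, card_mask) > 0
    count <- count + sum(ok)
    if (collect && any(ok)) {
      bits <- vapply(0:(n - 1L),
                     function(b) bitwAnd(bitwShiftR(m[ok], b), 1) > 0,
                     logical(sum(ok)))
      subsets <- rbind(subsets, matrix(bits, ncol = n))
    }
    done <- done + length(m)
  }
  list(count = as.integer(count), subsets = subsets)
}

#' Sample prevalence of a symptom from present/absent counts
#'
#' Reproduces published prevalence cells: the exact ratio plus the
#' integer-rounded percentage (round-half-up, the convention of printed
#' cohort tables).
#'
#' @param present,absent non-negative counts; their sum must be positive.
#' @param cohort_class optional label ("clinical", "community", ...).
#' @return list with `present`, `absent`, `prevalence` (proportion) and
#'   `percent` (integer, round-half-up).
#' @export
sample_prevalence <- function(present, absent, cohort_class = NA_character_) {
  if (present < 0 || absent < 0) stop("counts must be non-negative")
  if (present + absent <= 0) stop("present + absent must be positive")
  p <- present / (present + absent)
  list(present = present, absent = absent, prevalence = p,
       percent = as.integer(round_half_up(100 * p)),
       cohort_class = cohort_class)
}

#' Population prevalence implied by a cohort's sample prevalence
#'
#' Clinical cohorts condition symptom data on a depression diagnosis, so the
#' lifetime population prevalence of a symptom is taken as the within-cohort
#' sample prevalence times the population prevalence of MDD (15% by default).
#' Community cohorts gate symptom items on cardinal-symptom endorsement, so
#' the multiplier is the proportion of the population passing the gate.
#'
#' @param sample_prev sample prevalence P in (0,1).
#' @param cohort_class "clinical" or "community".
#' @param mdd_prev population prevalence of MDD (default 0.15).
#' @param gate_proportion proportion endorsing at least one gating symptom
#'   (required for community cohorts).
#' @return population prevalence K.
#' @export
population_prevalence <- function(sample_prev,
                                  cohort_class = c("clinical", "community"),
                                  mdd_prev = 0.15, gate_proportion = NULL) {
  cohort_class <- match.arg(cohort_class)
  if (sample_prev <= 0 || sample_prev >= 1) stop("sample_prev must be in (0,1)")
  if (cohort_class == "clinical") {
    if (mdd_prev <= 0 || mdd_prev > 1) stop("mdd_prev must be in (0,1]")
    return(sample_prev * mdd_prev)
  }
  if (is.null(gate_proportion))
    stop("gate_proportion is required for community cohorts")
  if (gate_proportion <= 0 || gate_proportion > 1)
    stop("gate_proportion must be in (0,1]")
  sample_prev * gate_proportion
}

#' Significance tier of a meta-analysed association
#'
#' "study_wide" applies the Bonferroni-style correction of genome-wide
#' significance across the number of symptom meta-analyses conducted
#' (5e-8 / n_meta); "genome_wide" the conventional 5e-8.
#'
#' @param p p-value(s) in (0, 1].
#' @param n_meta number of meta-analyses (default 22).
#' @return character vector: "study_wide", "genome_wide" or "none".
#' @export
significance_tier <- function(p, n_meta = 22L) {
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  ifelse(p < 5e-8 / n_meta, "study_wide",
         ifelse(p < 5e-8, "genome_wide", "none"))
}

#' Bundled symptom prevalence table
#'
#' Present/absent counts and printed sample prevalences of the twelve
#' directional DSM symptoms in the clinical meta-analysis, community
#' meta-analysis, and UK Biobank touchscreen assessment. The community
#' anhedonia row carries a printed percentage that is inconsistent with its
#' printed counts (see the `note` column); that cell should not be used as a
#' golden value.
#'
#' @return data.table with columns symptom, abbr, cohort_class, present,
#'   absent, printed_pct, note.
#' @export
symptom_prevalence_table <- function() {
  path <- system.file("extdata", "symptom_prevalence.tsv",
                      package = "symfactor", mustWork = TRUE)
  data.table::fread(path, sep = "\t", na.strings = c("NA", ""), fill = TRUE)
}
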