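# Multi-cohort depression-symptom GWAS simulator.
#
# Symptom liabilities follow a genetic factor model: for symptom i,
#   liability_i = sqrt(h2_i) * g_i + sqrt(1 - h2_i) * e_i,
# where the standardized genetic component g_i = sum_k lambda_ik F_k +
# sqrt(theta_i) r_i is built from factor genetic scores F (correlation Psi)
# and a symptom-specific residual, theta_i = 1 - lambda_i' Psi lambda_i.
# The environmental component follows the same factor structure, so the
# total liability correlation matrix equals Lambda Psi Lambda' + diag(theta)
# at every heritability. Genetic effects are infinitesimal: every SNP is
# causal with Gaussian effects (the LDSC polygenic model); SNPs are unlinked
# (LD score 1). A symptom is present when its liability exceeds the
# standard-normal quantile of 1 - K.

#' Ground-truth genetic factor structure
#'
#' @param symptom_labels symptom identifiers.
#' @param loadings symptom x factor matrix Lambda of standardized loadings.
#' @param factor_corr factor correlation matrix Psi (default identity).
#' @param h2_liab per-symptom liability-scale SNP heritability in [0, 1].
#' @param prevalence_pop per-symptom lifetime population prevalence K.
#' @return `true_structure` list; residual variances theta are derived so
#'   the implied correlation matrix has a unit diagonal.
#' @export
true_structure <- function(symptom_labels, loadings, factor_corr = NULL,
                           h2_liab, prevalence_pop) {
  loadings <- as.matrix(loadings)
  k <- length(symptom_labels)
  stopifnot(nrow(loadings) == k, length(h2_liab) == k,
            length(prevalence_pop) == k,
            all(h2_liab >= 0), all(h2_liab <= 1),
            all(prevalence_pop > 0), all(prevalence_pop < 1))
  f <- ncol(loadings)
  if (is.null(factor_corr)) factor_corr <- diag(f)
  factor_corr <- as.matrix(factor_corr)
  stopifnot(nrow(factor_corr) == f, ncol(factor_corr) == f,
            max(abs(factor_corr - t(factor_corr))) < 1e-12,
            max(abs(diag(factor_corr) - 1)) < 1e-12)
  if (min(eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("factor_corr must be positive definite")
  comm <- diag(loadings %*% factor_corr %*% t(loadings))
  if (any(comm > 1 + 1e-10))
    stop("communalities exceed 1; loadings/factor_corr invalid")
  theta <- pmax(1 - comm, 0)
  rownames(loadings) <- symptom_labels
  structure(list(symptom_labels = symptom_labels, loadings = loadings,
                 factor_corr = factor_corr, resid_var = theta,
                 h2_liab = h2_liab, prevalence_pop = prevalence_pop),
            class = "true_structure")
}

#' Implied liability-scale genetic covariance of a truth structure
#'
#' diag(sqrt(h2)) (Lambda Psi Lambda' + diag(theta)) diag(sqrt(h2)): the
#' oracle against which recovered genetic covariance matrices are compared.
#'
#' @param truth [true_structure()].
#' @return k x k matrix; its diagonal equals `h2_liab` exactly.
#' @export
true_gencov <- function(truth) {
  stopifnot(inherits(truth, "true_structure"))
  R <- truth$loadings %*% truth$factor_corr %*% t(truth$loadings) +
    diag(truth$resid_var, length(truth$symptom_labels))
  d <- sqrt(truth$h2_liab)
  D <- diag(d, length(d))
  out <- D %*% R %*% D
  dimnames(out) <- list(truth$symptom_labels, truth$symptom_labels)
  out
}

#' Cohort design
#'
#' @param name cohort identifier.
#' @param ascertainment "clinical" (participants retained only if they meet
#'   the diagnosis rule) or "community" (population sample; non-gate
#'   symptoms recorded only for participants endorsing a gate symptom).
#' @param n_individuals sample size (the population pool for clinical
#'   cohorts, before ascertainment).
#' @param gate_symptoms gating symptom labels (community; possibly empty,
#'   meaning no skip pattern).
#' @param rule a [diagnosis_rule()]-like list interpreted over the symptom
#'   criteria (required for clinical cohorts).
#' @param criteria optional list of label groups, one group per diagnostic
#'   criterion (directional pairs collapse into one group). Defaults to
#'   [dsm_criteria()] over the truth labels at simulation time.
#' @param overlap_group identifier: cohorts sharing a group share
#'   participants across symptom GWAS (within a cohort all symptom GWAS are
#'   run on the same individuals).
#' @param repeat_measures optional named list describing additional, ungated
#'   assessments of existing symptoms by a second instrument (e.g. a
#'   touchscreen screen of the cardinal symptoms administered to the whole
#'   cohort). Each element `list(symptom =, reliability =)` adds a phenotype
#'   whose liability correlates `reliability` with the source symptom's
#'   liability (same genetic component; never masked by gating).
#' @return `cohort_design` list.
#' @export
cohort_design <- function(name, ascertainment = c("community", "clinical"),
                          n_individuals, gate_symptoms = character(),
                          rule = NULL, criteria = NULL,
                          overlap_group = name, repeat_measures = NULL) {
  ascertainment <- match.arg(ascertainment)
  if (ascertainment == "clinical" && is.null(rule))
    stop("clinical cohorts need a diagnosis rule")
  for (rm in repeat_measures)
    stopifnot(is.character(rm$symptom), rm$reliability > 0,
              rm$reliability <= 1)
  structure(list(name = name, ascertainment = ascertainment,
                 n_individuals = as.integer(n_individuals),
                 gate_symptoms = gate_symptoms, rule = rule,
                 criteria = criteria, overlap_group = overlap_group,
                 repeat_measures = repeat_measures),
            class = "cohort_design")
}

#' Group directional symptom labels into DSM criteria
#'
#' Directional pairs (e.g. AppDec/AppInc, SleDec/SleInc, MotoDec/MotoInc)
#' collapse to a single criterion; all other labels form their own
#' criterion. This mirrors the DSM count of 9 criteria over up to 13
#' directional symptoms.
#'
#' @param labels symptom labels.
#' @return named list of label groups.
#' @export
dsm_criteria <- function(labels) {
  base <- sub("(Dec|Inc)$", "", labels)
  split(labels, factor(base, levels = unique(base)))
}

#' Synthetic per-SNP LD-score profile
#'
#' Genotypes are simulated unlinked, but per-SNP effect variances are scaled
#' by a profile l_j that plays the LD-score role exactly:
#' E[chi2_j] = 1 + N h2 l_j / M. A long-tailed profile
#' (l = 0.5 + Exponential(mean 0.5), normalized to mean 1) gives the LDSC
#' regression the leverage to separate slope from intercept, which constant
#' unit scores cannot.
#'
#' @param m number of SNPs.
#' @param seed integer seed.
#' @return numeric vector of length m, mean 1.
#' @export
synthetic_ld_profile <- function(m, seed = 1L) {
  set.seed(seed)
  l <- 0.5 + stats::rexp(m, rate = 2)
  l * m / sum(l)
}

#' Simulation configuration
#'
#' @param truth [true_structure()].
#' @param cohorts list of [cohort_design()]s.
#' @param m_snps number of unlinked SNPs (>= 50).
#' @param maf_range allele-frequency bounds.
#' @param seed integer seed; a fixed seed makes every output bit-identical.
#' @param mode "individual" (genotypes, liabilities, GWAS) or
#'   "sumstat_direct" (z-scores drawn from their sampling distribution).
#' @param ld per-SNP LD-score profile (length m_snps; effect variances are
#'   proportional to it). Default NULL = unit scores (fully unlinked
#'   model); see [synthetic_ld_profile()] for when a free LDSC intercept is
#'   needed.
#' @return `simulation_config` list.
#' @export
simulation_config <- function(truth, cohorts, m_snps = 1000L,
                              maf_range = c(0.05, 0.5), seed = 1L,
                              mode = c("individual", "sumstat_direct"),
                              ld = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "true_structure"), m_snps >= 50L,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(ld)) stopifnot(length(ld) == m_snps, all(ld > 0))
  for (ch in cohorts) {
    stopifnot(inherits(ch, "cohort_design"))
    if (!all(ch$gate_symptoms %in% truth$symptom_labels))
      stop("gate symptoms must be a subset of the symptom labels")
  }
  structure(list(truth = truth, cohorts = cohorts,
                 m_snps = as.integer(m_snps), maf_range = maf_range,
                 seed = as.integer(seed), mode = mode, ld = ld),
            class = "simulation_config")
}

# Count fulfilled criteria per individual from the binary symptom matrix.
criteria_counts <- function(symptoms, criteria) {
  counts <- matrix(0L, nrow(symptoms), length(criteria))
  for (g in seq_along(criteria)) {
    cols <- criteria[[g]]
    counts[, g] <- as.integer(
      rowSums(symptoms[, cols, drop = FALSE], na.rm = TRUE) > 0)
  }
  counts
}

#' Simulate one cohort at the individual level
#'
#' Draws genotypes, factor-model liabilities and binary symptoms, then
#' applies the cohort's observation process: community cohorts mask all
#' non-gate symptoms for individuals endorsing no gate symptom; clinical
#' cohorts retain only individuals meeting the diagnosis rule (at least
#' `min_total` criteria, at least one cardinal).
#'
#' @param config [simulation_config()] with mode "individual".
#' @param cohort a [cohort_design()] from the config.
#' @return `individual_cohort` list: dosages (n x M), maf, symptoms (binary
#'   with NA for masked entries), symptoms_unmasked, liabilities,
#'   genetic_liab (hidden truth), labels.
#' @export
simulate_individual_cohort <- function(config, cohort) {
  stopifnot(config$mode == "individual")
  truth <- config$truth
  labels <- truth$symptom_labels
  k <- length(labels); M <- config$m_snps; n <- cohort$n_individuals
  f <- ncol(truth$loadings)
  set.seed(config$seed + match(cohort$name,
                               vapply(config$cohorts, `[[`, "", "name")))
  maf <- stats::runif(M, config$maf_range[1], config$maf_range[2])
  X <- matrix(stats::rbinom(n * M, 2L, rep(maf, each = n)), n, M)
  storage.mode(X) <- "double"
  sdv <- sqrt(2 * maf * (1 - maf))
  # per-SNP effects on factor genetic scores, Gaussian with cov Psi l_m / M
  lweight <- config$ld %||% rep(1, M)
  cp <- chol(truth$factor_corr)
  U <- (matrix(stats::rnorm(M * f), M, f) %*% cp) * sqrt(lweight / M)
  Ures <- matrix(stats::rnorm(M * k), M, k) * sqrt(lweight / M)
  # standardized-genotype scores without materializing the scaled matrix
  xb <- 2 * maf
  std_score <- function(B) {
    Bs <- B / sdv
    X %*% Bs - matrix(colSums(xb * Bs), n, ncol(B), byrow = TRUE)
  }
  Ffac <- std_score(U)
  Rres <- std_score(Ures)
  g <- Ffac %*% t(truth$loadings) +
    Rres * matrix(sqrt(truth$resid_var), n, k, byrow = TRUE)
  Fenv <- matrix(stats::rnorm(n * f), n, f) %*% cp
  e <- Fenv %*% t(truth$loadings) +
    matrix(stats::rnorm(n * k), n, k) *
      matrix(sqrt(truth$resid_var), n, k, byrow = TRUE)
  h <- sqrt(truth$h2_liab)
  liab <- g %*% diag(h, k) + e %*% diag(sqrt(1 - truth$h2_liab), k)
  colnames(liab) <- colnames(g) <- labels
  thr <- stats::qnorm(1 - truth$prevalence_pop)
  symptoms <- matrix(as.integer(liab > matrix(thr, n, k, byrow = TRUE)), n, k,
                     dimnames = list(NULL, labels))
  unmasked <- symptoms
  keep <- seq_len(n)
  if (cohort$ascertainment == "clinical") {
    criteria <- cohort$criteria %||% dsm_criteria(labels)
    cc <- criteria_counts(symptoms, criteria)
    rule <- cohort$rule
    card_idx <- if (is.character(rule$cardinal))
      match(rule$cardinal, names(criteria)) else rule$cardinal
    if (anyNA(card_idx)) stop("cardinal criteria not found among criteria")
    ok <- rowSums(cc) >= rule$min_total &
      rowSums(cc[, card_idx, drop = FALSE]) > 0
    if (!any(ok)) stop("empty ascertained cohort: no individual meets the diagnosis rule")
    keep <- which(ok)
  } else if (length(cohort$gate_symptoms)) {
    gates <- cohort$gate_symptoms
    pass <- rowSums(symptoms[, gates, drop = FALSE]) > 0
    mask_cols <- setdiff(labels, gates)
    symptoms[!pass, mask_cols] <- NA_integer_
  }
  # second-instrument assessments: ungated, never masked
  if (length(cohort$repeat_measures)) {
    for (nm in names(cohort$repeat_measures)) {
      rm_ <- cohort$repeat_measures[[nm]]
      src <- rm_$symptom
      if (!src %in% labels) stop("repeat measure source unknown: ", src)
      rel <- rm_$reliability
      liab2 <- rel * liab[, src] + sqrt(1 - rel^2) * stats::rnorm(n)
      y2 <- as.integer(liab2 > stats::qnorm(1 - truth$prevalence_pop[
        match(src, labels)]))
      symptoms <- cbind(symptoms, y2)
      unmasked <- cbind(unmasked, y2)
      colnames(symptoms)[ncol(symptoms)] <- nm
      colnames(unmasked)[ncol(unmasked)] <- nm
    }
  }
  all_labels <- colnames(symptoms)
  structure(list(dosages = X[keep, , drop = FALSE], maf = maf,
                 symptoms = symptoms[keep, , drop = FALSE],
                 symptoms_unmasked = unmasked[keep, , drop = FALSE],
                 liabilities = liab[keep, , drop = FALSE],
                 genetic_liab = g[keep, , drop = FALSE],
                 labels = all_labels, cohort = cohort$name,
                 ascertainment = cohort$ascertainment),
            class = "individual_cohort")
}

#' Per-symptom GWAS on simulated individuals
#'
#' Linear-model score test of the binary symptom on allele dosage over the
#' non-missing individuals: beta = cov(x, y)/var(x), se from the residual
#' variance, z = beta/se. Monomorphic SNPs are flagged (`MONO = TRUE`) with
#' undefined effect and should be excluded downstream.
#'
#' @param data an `individual_cohort`.
#' @param symptom symptom label.
#' @param min_n minimum non-missing phenotypes (default 30).
#' @return `sumstat` with SNP, A1, A2, BETA, SE, Z, P, N, FREQ, MONO.
#' @export
gwas_symptom <- function(data, symptom, min_n = 30L) {
  y <- data$symptoms[, symptom]
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < min_n) stop("fewer than ", min_n, " non-missing individuals for ", symptom)
  y <- y[ok]
  X <- data$dosages[ok, , drop = FALSE]
  sx <- colSums(X); sx2 <- colSums(X^2)
  xbar <- sx / n
  Sxx <- sx2 - n * xbar^2
  yc <- y - mean(y)
  Sxy <- as.numeric(crossprod(X, yc))
  mono <- Sxx <= 0
  beta <- ifelse(mono, NA_real_, Sxy / Sxx)
  # residual variance of y given x, df = n - 2
  Syy <- sum(yc^2)
  rss <- pmax(Syy - ifelse(mono, 0, Sxy^2 / Sxx), 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / (n - 2) / Sxx))
  z <- beta / se
  dt <- data.table::data.table(
    SNP = paste0("rs", seq_len(ncol(X))), A1 = "A", A2 = "G",
    BETA = beta, SE = se, Z = z,
    P = 2 * stats::pnorm(-abs(z)), N = n, FREQ = xbar / 2, MONO = mono)
  new_sumstat(dt, cohort = data$cohort, symptom = symptom)
}

#' Draw summary statistics directly from the LDSC sampling model
#'
#' Fast test path: for unlinked SNPs (LD score 1), the z-scores of M SNPs
#' across traits are i.i.d. multivariate normal with
#' E[chi2_aj] = 1 + N_a h2_a / M and
#' E[z_aj z_bj] = sqrt(N_a N_b) cov_g(a,b) / M + rho_ab N_s / sqrt(N_a N_b),
#' the second term being the sample-overlap intercept. Traits are
#' symptom-by-cohort; the genetic covariance across all traits derives from
#' the shared truth (same symptom in two cohorts is genetically identical),
#' and participants overlap fully within a cohort and not at all across
#' cohorts (configurable via `overlap`).
#'
#' @param config [simulation_config()] with mode "sumstat_direct".
#' @param n_eff named numeric: effective sample size per cohort (defaults to
#'   each cohort's `n_individuals`).
#' @param overlap optional function(cohort_a, cohort_b) -> shared N; default
#'   full overlap within a cohort, zero across.
#' @param pheno_corr optional symptom-level phenotypic correlation matrix
#'   for the overlap term; default: the liability-scale correlation implied
#'   by the truth.
#' @return list: `tables` (nested cohort -> symptom -> `sumstat`), `truth`
#'   (the config truth), `trait_gencov`, `trait_labels`, `z` (M x traits).
#' @export
simulate_sumstats_direct <- function(config, n_eff = NULL, overlap = NULL,
                                     pheno_corr = NULL) {
  stopifnot(config$mode == "sumstat_direct")
  set.seed(config$seed)
  truth <- config$truth
  labels <- truth$symptom_labels
  M <- config$m_snps
  cohort_names <- vapply(config$cohorts, `[[`, "", "name")
  if (is.null(n_eff))
    n_eff <- stats::setNames(vapply(config$cohorts, function(c)
      as.numeric(c$n_individuals), numeric(1)), cohort_names)
  traits <- expand.grid(symptom = labels, cohort = cohort_names,
                        stringsAsFactors = FALSE)
  tl <- paste(traits$cohort, traits$symptom, sep = "_")
  nt <- nrow(traits)
  G_sym <- true_gencov(truth)
  R_sym <- pheno_corr %||% (truth$loadings %*% truth$factor_corr %*%
                              t(truth$loadings) +
                              diag(truth$resid_var, length(labels)))
  si <- match(traits$symptom, labels)
  G <- G_sym[si, si]
  Rpheno <- R_sym[si, si]  # liability correlation, used for overlap term
  N <- n_eff[traits$cohort]
  if (is.null(overlap))
    overlap <- function(a, b) if (a == b) min(n_eff[a], n_eff[b]) else 0
  Ns <- outer(seq_len(nt), seq_len(nt), Vectorize(function(i, j)
    overlap(traits$cohort[i], traits$cohort[j])))
  h2 <- truth$h2_liab[si]
  lweight <- config$ld %||% rep(1, M)
  # per-SNP covariance: genetic part scales with l_j, overlap part does not
  Sg <- sqrt(outer(N, N)) * G / M
  diag(Sg) <- N * h2 / M
  Si <- Rpheno * Ns / sqrt(outer(N, N))
  diag(Si) <- 1
  ev <- eigen(Sg + Si, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    off <- abs(Sg + Si); diag(off) <- 0
    bad <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf("implied z covariance not positive definite (worst pair %s / %s)",
                 tl[bad[1]], tl[bad[2]]))
  }
  msqrt <- function(A) {
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  if (stats::var(lweight) < 1e-14) {
    Z <- matrix(stats::rnorm(M * nt), M, nt) %*% msqrt(Sg + Si)
  } else {
    # draw genetic and error parts separately so l_j can scale the former
    Z <- (matrix(stats::rnorm(M * nt), M, nt) %*% msqrt(Sg)) * sqrt(lweight) +
      matrix(stats::rnorm(M * nt), M, nt) %*% msqrt(Si)
  }
  colnames(Z) <- tl
  snps <- paste0("rs", seq_len(M))
  tables <- list()
  for (co in cohort_names) {
    tables[[co]] <- list()
    for (sy in labels) {
      lab <- paste(co, sy, sep = "_")
      tables[[co]][[sy]] <- new_sumstat(
        data.table::data.table(SNP = snps, A1 = "A", A2 = "G",
                               Z = Z[, lab], N = as.numeric(N[match(lab, tl)])),
        cohort = co, symptom = sy, dialect = "ldsc_munged")
    }
  }
  list(tables = tables, truth = truth, trait_gencov = G,
       trait_labels = tl, z = Z, n_eff = n_eff)
}

#' Write a simulated study to disk
#'
#' Per-trait LDSC-munged summary statistics plus a YAML truth sidecar.
#'
#' @param sim result of [simulate_sumstats_direct()].
#' @param dir output directory (created).
#' @param gzip write .sumstats.gz rather than plain files.
#' @return paths, invisibly.
#' @export
write_simulated_study <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (co in names(sim$tables)) for (sy in names(sim$tables[[co]])) {
    p <- file.path(dir, sprintf("%s_%s.sumstats%s", co, sy,
                                if (gzip) ".gz" else ""))
    write_sumstats(sim$tables[[co]][[sy]], p, dialect = "ldsc_munged")
    paths <- c(paths, p)
  }
  truth <- sim$truth
  yaml::write_yaml(list(
    symptom_labels = truth$symptom_labels,
    loadings = apply(truth$loadings, 1, as.numeric, simplify = FALSE),
    factor_corr = apply(truth$factor_corr, 1, as.numeric, simplify = FALSE),
    h2_liab = as.numeric(truth$h2_liab),
    prevalence_pop = as.numeric(truth$prevalence_pop)),
    file.path(dir, "truth.yaml"))
  invisible(c(paths, file.path(dir, "truth.yaml")))
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [simulation_config()] field names; cohorts carry name,
#' ascertainment, n_individuals, gate_symptoms, and optional diagnosis rule
#' (min_total, cardinal).
#'
#' @param path YAML file.
#' @return [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_row_matrix <- function(x) {
    if (!is.list(x)) x <- as.list(x)
    do.call(rbind, lapply(x, unlist))
  }
  truth <- true_structure(
    symptom_labels = y$truth$symptom_labels,
    loadings = as_row_matrix(y$truth$loadings),
    factor_corr = if (!is.null(y$truth$factor_corr))
      as_row_matrix(y$truth$factor_corr) else NULL,
    h2_liab = as.numeric(y$truth$h2_liab),
    prevalence_pop = as.numeric(y$truth$prevalence_pop))
  cohorts <- lapply(y$cohorts, function(c) {
    rule <- if (!is.null(c$diagnosis_rule))
      list(min_total = c$diagnosis_rule$min_total,
           cardinal = c$diagnosis_rule$cardinal) else NULL
    cohort_design(c$name, c$ascertainment, c$n_individuals,
                  gate_symptoms = unlist(c$gate_symptoms) %||% character(),
                  rule = rule, overlap_group = c$overlap_group %||% c$name)
  })
  simulation_config(truth, cohorts, y$m_snps %||% 1000L,
                    maf_range = unlist(y$maf_range) %||% c(0.05, 0.5),
                    seed = y$seed %||% 1L, mode = y$mode %||% "individual")
}
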