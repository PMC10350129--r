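small_truth <- function(k = 4, loading = 0.7, h2 = 0.3, K = 0.3) {
  labs <- paste0("S", seq_len(k))
  true_structure(labs, matrix(loading, k, 1), h2_liab = rep(h2, k),
                 prevalence_pop = rep(K, k))
}

test_that("truth structures validate their invariants", {
  ts <- small_truth()
  R <- ts$loadings %*% ts$factor_corr %*% t(ts$loadings) +
    diag(ts$resid_var, 4)
  expect_equal(unname(diag(R)), rep(1, 4), tolerance = 1e-10)
  expect_error(true_structure("a", matrix(1.2, 1, 1), h2_liab = 0.5,
                              prevalence_pop = 0.3), "communalities")
  expect_error(true_structure(c("a", "b"), matrix(0.5, 2, 2,
                dimnames = list(NULL, c("F1", "F2"))),
                factor_corr = matrix(c(1, 2, 2, 1), 2),
                h2_liab = c(.5, .5), prevalence_pop = c(.3, .3)))
})

test_that("true_gencov matches hand-computed oracles", {
  # perfect correlation: lambda = (1, 1), h2 = 0.1 each
  ts <- true_structure(c("a", "b"), matrix(1, 2, 1), h2_liab = c(0.1, 0.1),
                       prevalence_pop = c(0.3, 0.3))
  G <- true_gencov(ts)
  expect_equal(G[1, 2], 0.1, tolerance = 1e-12)
  # lambda = (0.8, 0.5), unit h2: genetic correlation 0.40
  ts2 <- true_structure(c("a", "b"), matrix(c(0.8, 0.5), 2, 1),
                        h2_liab = c(1, 1), prevalence_pop = c(0.3, 0.3))
  G2 <- true_gencov(ts2)
  expect_equal(stats::cov2cor(G2)[1, 2], 0.4, tolerance = 1e-12)
  # diagonal equals h2 exactly
  ts3 <- small_truth(3, h2 = 0.25)
  expect_equal(unname(diag(true_gencov(ts3))), rep(0.25, 3))
})

test_that("simulation is bit-identical under a fixed seed", {
  ts <- small_truth()
  co <- cohort_design("c", "community", 500, gate_symptoms = "S1")
  cfg <- simulation_config(ts, list(co), m_snps = 100, seed = 99)
  d1 <- simulate_individual_cohort(cfg, co)
  d2 <- simulate_individual_cohort(cfg, co)
  expect_identical(d1$dosages, d2$dosages)
  expect_identical(d1$symptoms, d2$symptoms)
  cfg_d <- simulation_config(ts, list(cohort_design("c", "community", 1000)),
                             m_snps = 100, seed = 7, mode = "sumstat_direct")
  z1 <- simulate_sumstats_direct(cfg_d)$z
  z2 <- simulate_sumstats_direct(cfg_d)$z
  expect_identical(z1, z2)
})

test_that("unmasked symptom prevalence matches K within binomial error", {
  ts <- small_truth(3, K = 0.25)
  co <- cohort_design("c", "community", 20000)
  cfg <- simulation_config(ts, list(co), m_snps = 100, seed = 5)
  d <- simulate_individual_cohort(cfg, co)
  phat <- colMeans(d$symptoms_unmasked[, 1:3])
  ci <- 1.96 * sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(phat - 0.25) < 3 * ci))
})

test_that("gating masks exactly the non-gate symptoms of non-endorsers", {
  ts <- small_truth(4)
  co <- cohort_design("c", "community", 5000,
                      gate_symptoms = c("S1", "S2"))
  cfg <- simulation_config(ts, list(co), m_snps = 100, seed = 11)
  d <- simulate_individual_cohort(cfg, co)
  pass <- d$symptoms_unmasked[, "S1"] | d$symptoms_unmasked[, "S2"]
  # gate symptoms never masked
  expect_false(anyNA(d$symptoms[, c("S1", "S2")]))
  # non-gates masked iff both gates absent
  for (sy in c("S3", "S4")) {
    expect_true(all(is.na(d$symptoms[!pass, sy])))
    expect_false(anyNA(d$symptoms[pass, sy]))
  }
})

test_that("clinical ascertainment enriches cardinal symptoms", {
  ts <- small_truth(9, K = 0.25)
  rule <- list(min_total = 5L, cardinal = c("S1", "S2"))
  clin <- cohort_design("c", "clinical", 8000, rule = rule)
  cfg <- simulation_config(ts, list(clin), m_snps = 100, seed = 13)
  d <- simulate_individual_cohort(cfg, clin)
  pop <- cohort_design("c", "community", 8000)
  cfg_pop <- simulation_config(ts, list(pop), m_snps = 100, seed = 13)
  d_pop <- simulate_individual_cohort(cfg_pop, pop)
  for (sy in c("S1", "S2"))
    expect_gt(mean(d$symptoms[, sy]), mean(d_pop$symptoms[, sy]))
  # every retained individual meets the rule
  counts <- rowSums(d$symptoms_unmasked)
  expect_true(all(counts >= 5))
  expect_true(all(d$symptoms_unmasked[, "S1"] | d$symptoms_unmasked[, "S2"]))
  # impossible rule fails loudly
  bad <- cohort_design("c", "clinical", 200,
                       rule = list(min_total = 10L, cardinal = "S1"))
  cfg_bad <- simulation_config(ts, list(bad), m_snps = 100, seed = 17)
  expect_error(simulate_individual_cohort(cfg_bad, bad),
               "empty ascertained cohort")
})

test_that("repeat measures are ungated second assessments", {
  ts <- small_truth(3)
  co <- cohort_design("c", "community", 4000, gate_symptoms = "S1",
                      repeat_measures = list(
                        TS1 = list(symptom = "S1", reliability = 0.8)))
  cfg <- simulation_config(ts, list(co), m_snps = 100, seed = 19)
  d <- simulate_individual_cohort(cfg, co)
  expect_true("TS1" %in% colnames(d$symptoms))
  expect_false(anyNA(d$symptoms[, "TS1"]))
  # correlates with, but is not a copy of, the source symptom
  agree <- mean(d$symptoms[, "TS1"] == d$symptoms_unmasked[, "S1"])
  expect_gt(agree, 0.7)
  expect_lt(agree, 0.999)
})

test_that("null-heritability GWAS is calibrated", {
  ts <- true_structure(paste0("S", 1:2), matrix(0.7, 2, 1),
                       h2_liab = c(0, 0), prevalence_pop = c(0.3, 0.3))
  co <- cohort_design("c", "community", 2000)
  cfg <- simulation_config(ts, list(co), m_snps = 400, seed = 23)
  d <- simulate_individual_cohort(cfg, co)
  g <- gwas_symptom(d, "S1")
  expect_false(any(g$MONO))
  expect_equal(mean(g$Z^2), 1, tolerance = 3 * sqrt(2 / 400))
  expect_equal(unique(g$N), 2000)
  # permutation oracle: type-I error at alpha = 0.05 in the binomial CI
  set.seed(24)
  d$symptoms[, "S2"] <- sample(d$symptoms[, "S2"])
  gp <- gwas_symptom(d, "S2")
  rej <- mean(gp$P < 0.05)
  expect_gt(rej, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rej, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})

test_that("an injected liability effect inflates that SNP's chi-square", {
  ts <- small_truth(1, h2 = 0.5)
  co <- cohort_design("c", "community", 3000)
  chi2 <- vapply(1:8, function(s) {
    cfg <- simulation_config(ts, list(co), m_snps = 60, seed = 300 + s)
    d <- simulate_individual_cohort(cfg, co)
    # inject a direct dosage effect on the first SNP and rebuild the symptom
    liab <- d$liabilities[, 1] + 0.15 * scale(d$dosages[, 1])
    d$symptoms[, 1] <- as.integer(liab > stats::qnorm(0.7))
    gwas_symptom(d, "S1")$Z[1]^2
  }, numeric(1))
  expect_gt(mean(chi2), 1.5)
})

test_that("GWAS counts non-missing phenotypes and flags monomorphic SNPs", {
  ts <- small_truth(2)
  co <- cohort_design("c", "community", 1000, gate_symptoms = "S1")
  cfg <- simulation_config(ts, list(co), m_snps = 100, seed = 29)
  d <- simulate_individual_cohort(cfg, co)
  g <- gwas_symptom(d, "S2")
  expect_equal(unique(g$N), sum(!is.na(d$symptoms[, "S2"])))
  d$dosages[, 5] <- 2  # force monomorphic
  g2 <- gwas_symptom(d, "S2")
  expect_true(g2$MONO[5])
  expect_true(is.na(g2$BETA[5]))
  # too few non-missing phenotypes is an error
  d$symptoms[-(1:10), "S2"] <- NA_integer_
  expect_error(gwas_symptom(d, "S2"), "non-missing")
})

test_that("direct z-scores satisfy the stated moments", {
  st <- direct_study(seed = 33, k = 2, m = 20000, n = 5e4, h2 = 0.1,
                     loading = 1, overlap_zero = TRUE)
  z <- st$sim$z
  l <- st$ld$L2
  # E[chi2] = 1 + N h2 mean(l) / M with mean(l) = 1
  expect_equal(mean(z[, 1]^2), 1.25, tolerance = 4 * sqrt(2 * 1.25^2 / 20000))
  # unit loadings: rg = 1, E[z_a z_b] = sqrt(NaNb) h2 l / M
  expect_lt(abs(stats::coef(stats::lm(I(z[, 1] * z[, 2]) ~ l))[[2]] -
                  5e4 * 0.1 / 20000), 0.06)
  # non-PD implied covariance fails naming a pair
  ts <- true_structure(c("a", "b"), matrix(1, 2, 1), h2_liab = c(.1, .1),
                       prevalence_pop = c(.3, .3))
  cfg <- simulation_config(ts, list(cohort_design("c1", "community", 1e4)),
                           m_snps = 100, seed = 1, mode = "sumstat_direct")
  expect_error(simulate_sumstats_direct(cfg, pheno_corr = matrix(c(1, 1.5,
                 1.5, 1), 2)), "positive definite")
})

test_that("individual and direct paths agree on LDSC heritability", {
  # individual-level binary GWAS, converted to the liability scale, should
  # match the direct simulator run at the same truth within combined error
  K <- 0.3
  ts <- true_structure("S1", matrix(1, 1, 1), h2_liab = 0.2,
                       prevalence_pop = K)
  co <- cohort_design("c", "community", 20000)
  l <- synthetic_ld_profile(2000, seed = 43)
  cfg <- simulation_config(ts, list(co), m_snps = 2000, seed = 43, ld = l)
  d <- simulate_individual_cohort(cfg, co)
  g <- gwas_symptom(d, "S1")
  ld <- ld_scores(g$SNP, l)
  P <- mean(d$symptoms[, "S1"])
  f_ind <- fit_h2(g, ld, P = P, K = K)
  cfg_d <- simulation_config(ts, list(co), m_snps = 2000, seed = 44,
                             mode = "sumstat_direct", ld = l)
  # direct mode draws observed-scale z; rescale truth h2 to observed scale
  h2_obs <- 0.2 / liability_factor(P, K)
  ts_d <- true_structure("S1", matrix(1, 1, 1), h2_liab = h2_obs,
                         prevalence_pop = K)
  cfg_d$truth <- ts_d
  sim <- simulate_sumstats_direct(cfg_d)
  f_dir <- fit_h2(sim$tables$c$S1, ld, P = P, K = K)
  se <- sqrt(f_ind$se_h2_liab^2 + f_dir$se_h2_liab^2)
  expect_lt(abs(f_ind$h2_liab - f_dir$h2_liab), 3 * se)
})
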