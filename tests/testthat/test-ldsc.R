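toy_h2_inputs <- function() {
  list(dt = data.table::data.table(SNP = c("a", "b", "c"),
                                   Z = sqrt(c(1.2, 1.4, 1.6)), N = 100),
       ld = ld_scores(c("a", "b", "c"), c(1, 2, 3), M = 100))
}

test_that("unweighted LDSC reproduces the closed-form OLS toy", {
  ti <- toy_h2_inputs()
  f <- suppressWarnings(fit_h2(ti$dt, ti$ld, weights = "ols"))
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$h2_obs, 0.2, tolerance = 1e-12)
})

test_that("all chi-square equal to one yields zero heritability", {
  dt <- data.table::data.table(SNP = paste0("s", 1:300), Z = 1,
                               N = 1000)
  ld <- ld_scores(dt$SNP, seq(1, 3, length.out = 300), M = 300)
  f <- fit_h2(dt, ld, weights = "ols")
  expect_equal(f$h2_obs, 0, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$se_h2, 0, tolerance = 1e-10)  # identical blocks: zero SE
})

test_that("cross-trait regression reproduces its closed form and rg", {
  ld <- ld_scores(c("a", "b", "c"), c(1, 2, 3), M = 100)
  a <- data.table::data.table(SNP = c("a", "b", "c"), Z = c(0.1, 0.2, 0.3),
                              N = 100)
  b <- data.table::data.table(SNP = c("a", "b", "c"), Z = rep(1, 3), N = 100)
  g <- suppressWarnings(fit_gencov(a, b, ld, weights = "ols"))
  expect_equal(g$gencov, 0.1, tolerance = 1e-10)
  expect_equal(g$intercept, 0, tolerance = 1e-10)
  # a trait against itself has rg = 1
  set.seed(4)
  z <- stats::rnorm(500, 0, 1.2)
  tt <- data.table::data.table(SNP = paste0("s", 1:500), Z = z, N = 5000)
  ld2 <- ld_scores(tt$SNP, synthetic_ld_profile(500, 9), M = 500)
  gg <- fit_gencov(tt, tt, ld2, weights = "ols")
  expect_equal(gg$rg, 1, tolerance = 1e-8)
})

test_that("liability conversion matches the analytic balanced limit", {
  expect_equal(liability_factor(0.5, 0.5), pi / 2, tolerance = 1e-9)
  # clinical appetite-decrease case: P = 0.5 by convention, K = 0.39 * 0.15
  K <- population_prevalence(0.39, "clinical")
  z <- stats::qnorm(1 - K)
  oracle <- K^2 * (1 - K)^2 / (0.25 * stats::dnorm(z)^2)
  expect_equal(liability_factor(0.5, K), oracle, tolerance = 1e-12)
  expect_error(liability_factor(0, 0.5))
  expect_error(liability_factor(0.5, 1))
})

test_that("h2_obs of zero stays zero on the liability scale", {
  dt <- data.table::data.table(SNP = paste0("s", 1:300), Z = 1, N = 1000)
  ld <- ld_scores(dt$SNP, seq(1, 3, length.out = 300), M = 300)
  f <- fit_h2(dt, ld, weights = "ols", P = 0.5, K = 0.05)
  expect_equal(f$h2_liab, 0, tolerance = 1e-10)
})

test_that("direct-simulation heritability is recovered within jackknife error", {
  st <- direct_study(seed = 21, k = 1, m = 20000, n = 5e4, h2 = 0.1,
                     loading = 1)
  f <- fit_h2(st$tabs[[1]], st$ld)
  expect_lt(abs(f$h2_obs - 0.1), 3 * f$se_h2)
  expect_lt(abs(f$intercept - 1), 3 * f$se_intercept)
  expect_equal(f$mean_chi2, 1 + 5e4 * 0.1 / 20000, tolerance = 0.05)
})

test_that("sample overlap is absorbed by the cross-trait intercept", {
  # rho_g = 0 (orthogonal factors), full overlap, phenotypic rho = 1:
  # the cross-trait intercept converges to rho * N_s / N = 1 and the
  # genetic covariance to 0
  labs <- c("A", "B")
  ts <- true_structure(labs, diag(2), h2_liab = c(0.1, 0.1),
                       prevalence_pop = c(0.3, 0.3))
  co <- cohort_design("c1", "community", 5e4)
  l <- synthetic_ld_profile(20000, seed = 31)
  cfg <- simulation_config(ts, list(co), m_snps = 20000, seed = 31,
                           mode = "sumstat_direct", ld = l)
  sim <- simulate_sumstats_direct(cfg, pheno_corr = matrix(c(1, 1, 1, 1), 2))
  ld <- ld_scores(sim$tables$c1$A$SNP, l)
  g <- fit_gencov(sim$tables$c1$A, sim$tables$c1$B, ld)
  expect_lt(abs(g$intercept - 1), 3 * g$se_intercept)
  expect_lt(abs(g$gencov), 3 * g$se_gencov)
  # and with zero overlap the cross products are centred on zero
  sim0 <- simulate_sumstats_direct(cfg, overlap = function(a, b) 0)
  expect_lt(abs(mean(sim0$z[, 1] * sim0$z[, 2])),
            3 / sqrt(nrow(sim0$z)))
})

test_that("build_S_V recovers structure, keeps diag equal to h2, is permutable", {
  st <- direct_study(seed = 41, k = 3, m = 8000, n = 3e4)
  scv <- build_S_V(st$tabs, st$ld, n_blocks = 100)
  truthS <- true_gencov(st$truth)
  expect_equal(dim(scv$S), c(3, 3))
  expect_lt(max(abs(scv$S - truthS)), 0.05)
  # diagonal equals the univariate estimates exactly
  expect_equal(unname(diag(scv$S)), scv$h2_table$h2_obs, tolerance = 1e-12)
  # V symmetric PSD
  expect_equal(scv$V, t(scv$V), tolerance = 1e-12)
  expect_gte(min(eigen(scv$V, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # permuting traits permutes S and V consistently
  perm <- c(3, 1, 2)
  scv_p <- reorder_scv(scv, perm)
  expect_equal(scv_p$S, scv$S[perm, perm])
  direct <- build_S_V(st$tabs[perm], st$ld, n_blocks = 100)
  expect_equal(scv_p$S, direct$S, tolerance = 1e-12)
  expect_equal(scv_p$V, direct$V, tolerance = 1e-12)
})

test_that("liability conversion scales covariances by geometric means", {
  st <- direct_study(seed = 51, k = 2, m = 5000, n = 2e4)
  prev <- data.frame(label = names(st$tabs), P = c(0.5, 0.5),
                     K = c(0.1, 0.2))
  raw <- build_S_V(st$tabs, st$ld, n_blocks = 50)
  conv <- build_S_V(st$tabs, st$ld, prevalences = prev, n_blocks = 50)
  m1 <- liability_factor(0.5, 0.1); m2 <- liability_factor(0.5, 0.2)
  expect_equal(conv$S[1, 1], raw$S[1, 1] * m1, tolerance = 1e-10)
  expect_equal(conv$S[1, 2], raw$S[1, 2] * sqrt(m1 * m2), tolerance = 1e-10)
  expect_equal(conv$h2_table$h2_liab,
               conv$h2_table$h2_obs * c(m1, m2), tolerance = 1e-10)
  expect_identical(conv$scale, "liability")
})

test_that("S-hat approaches the oracle as sample size grows", {
  err <- vapply(c(1e4, 5e4, 2e5), function(n) {
    e <- 0
    for (s in 1:3) {
      st <- direct_study(seed = 60 + s, k = 3, m = 5000, n = n)
      scv <- build_S_V(st$tabs, st$ld, n_blocks = 50, weights = "ols")
      e <- e + norm(scv$S - true_gencov(st$truth), "F")
    }
    e / 3
  }, numeric(1))
  expect_true(err[3] < err[1])
})
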