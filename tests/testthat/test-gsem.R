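test_that("a saturated model fits perfectly with zero df", {
  S <- one_factor_S(c(0.8, 0.6))
  scv <- toy_scv(S)
  # 2 indicators, 1 factor: 2 loadings + 2 residuals = 4 > u = 3 is not
  # identified; fix one residual to reach saturation (df = 0)
  spec <- model_spec(matrix(NA_real_, 2, 1, dimnames = list(rownames(S), "F")),
                     resid_var = c(NA_real_, 0.64))
  fit <- fit_model(spec, scv)
  expect_equal(fit$df, 0)
  expect_equal(fit$chisq, 0, tolerance = 1e-8)
  expect_equal(fit$srmr, 0, tolerance = 1e-6)
  # over-parameterized specs are rejected before fitting
  spec_bad <- model_spec(matrix(NA_real_, 2, 1,
                                dimnames = list(rownames(S), "F")))
  expect_error(fit_model(spec_bad, scv), "not identified")
})

test_that("exact one-factor structures are recovered to high precision", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  scv <- toy_scv(one_factor_S(lam))
  spec <- build_factor_spec(list(F1 = scv$labels), scv$labels)
  fit <- fit_model(spec, scv)
  expect_equal(fit$df, 2)
  expect_lt(max(abs(abs(fit$loadings[, 1]) - lam)), 1e-4)
  expect_lt(fit$chisq, 1e-4)
  expect_lt(fit$srmr, 1e-6)
  expect_equal(fit$cfi, 1, tolerance = 1e-6)
  expect_equal(fit$aic, fit$chisq + 2 * 8)
  # residual variances recovered as 1 - lambda^2
  expect_lt(max(abs(diag(fit$resid) - (1 - lam^2))), 1e-4)
})

test_that("SRMR matches its hand-computed definition", {
  # observed correlation 0.5, implied 0.4, unit diagonals:
  # sqrt(0.01 / 3) ~ 0.0577
  S <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  scv <- toy_scv(S)
  lam <- sqrt(0.4)
  spec <- model_spec(matrix(c(lam, lam), 2, 1,
                            dimnames = list(c("a", "b"), "F")),
                     resid_var = c(0.6, 0.6))
  fit <- fit_model(spec, scv)
  expect_equal(fit$implied[1, 2], 0.4, tolerance = 1e-12)
  expect_equal(fit$srmr, sqrt(0.01 / 3), tolerance = 1e-10)
})

test_that("fit is invariant to indicator ordering", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  S <- one_factor_S(lam)
  S[1, 2] <- S[2, 1] <- 0.7  # inject misfit so chisq > 0
  set.seed(6)
  u <- 10
  V <- diag(stats::runif(u, 5e-5, 2e-4))
  scv <- toy_scv(S, V)
  fit1 <- fit_model(build_factor_spec(list(F1 = scv$labels), scv$labels), scv)
  perm <- c(3, 1, 4, 2)
  scv2 <- reorder_scv(scv, perm)
  fit2 <- fit_model(build_factor_spec(list(F1 = scv2$labels), scv2$labels),
                    scv2)
  expect_gt(fit1$chisq, 1)
  expect_equal(fit2$chisq, fit1$chisq, tolerance = 1e-6)
  expect_equal(fit2$aic, fit1$aic, tolerance = 1e-6)
  expect_equal(fit2$srmr, fit1$srmr, tolerance = 1e-6)
  expect_equal(abs(fit2$loadings[scv$labels, 1]),
               abs(fit1$loadings[scv$labels, 1]), tolerance = 1e-5)
})

test_that("freeing a parameter of a nested model never increases chi-square", {
  # two-factor truth fitted by its own model vs the more constrained
  # one-factor model
  labs <- paste0("y", 1:6)
  L <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.7, 0.6, 0.5))
  Psi <- matrix(c(1, 0.4, 0.4, 1), 2)
  S <- L %*% Psi %*% t(L)
  diag(S) <- 1
  dimnames(S) <- list(labs, labs)
  set.seed(8)
  scv <- toy_scv(S, diag(stats::runif(21, 5e-5, 2e-4)))
  one <- fit_model(build_factor_spec(list(G = labs), labs), scv)
  two_spec <- build_factor_spec(list(F1 = labs[1:3], F2 = labs[4:6]), labs)
  # warm start from the nested solution: same loadings, free correlation
  two <- fit_model(two_spec, scv,
                   start = c(one$theta[1:6], 0.5, one$theta[7:12]))
  expect_lt(two$chisq, one$chisq + 1e-6)
  expect_lt(two$chisq, 1e-3)  # true model fits
  expect_equal(two$factor_corr[1, 2], 0.4, tolerance = 1e-3)
})

test_that("sandwich standard errors cover the truth in repeated sampling", {
  lam <- 0.7
  hits <- 0; total <- 0
  for (s in 1:12) {
    st <- direct_study(seed = 400 + s, k = 4, m = 4000, n = 1e5)
    scv <- build_S_V(st$tabs, st$ld, n_blocks = 100)
    spec <- build_factor_spec(list(F1 = scv$labels), scv$labels)
    fit <- fit_model(spec, scv, seed = s)
    truth_load <- sqrt(0.2) * 0.7  # covariance-scale loading
    est <- fit$estimates[grepl("=~", fit$estimates$parameter)]
    hits <- hits + sum(abs(abs(est$estimate) - truth_load) <= 2 * est$se)
    total <- total + nrow(est)
  }
  expect_gte(hits / total, 0.8)
})

test_that("Heywood cases are flagged rather than clipped", {
  S <- one_factor_S(c(0.9, 0.8, 0.7))
  S[1, 2] <- S[2, 1] <- 0.99  # forces residual of an indicator negative
  scv <- toy_scv(S, diag(1e-5, 6))
  fit <- fit_model(build_factor_spec(list(F = rownames(S)), rownames(S)), scv)
  expect_true(any(grepl("Heywood", fit$warnings)) || all(diag(fit$resid) >= 0))
})

test_that("Benjamini-Yekutieli adjustment matches the worked example", {
  q <- fdr_by(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(q, rep(0.01 * 4 * (1 + 1/2 + 1/3 + 1/4), 4),
               tolerance = 1e-10)
  expect_true(all(fdr_by(c(0.5, 0.9)) <= 1))
})

test_that("genetic regression isolates factor-specific covariance", {
  # trait covaries with factor 1 only; multiple regression beta on factor 2
  # must vanish on the exactly implied covariance matrix
  labs <- c(paste0("y", 1:4), "trait")
  L <- rbind(c(0.8, 0), c(0.7, 0), c(0, 0.6), c(0, 0.5))
  Psi <- matrix(c(1, 0.3, 0.3, 1), 2)
  gamma <- c(0.4, 0)
  S <- matrix(0, 5, 5, dimnames = list(labs, labs))
  S[1:4, 1:4] <- L %*% Psi %*% t(L)
  diag(S)[1:4] <- 1
  S[5, 1:4] <- S[1:4, 5] <- as.numeric(L %*% Psi %*% gamma)
  S[5, 5] <- 1
  scv <- toy_scv(S)
  meas <- build_factor_spec(list(F1 = labs[1:2], F2 = labs[3:4]), labs[1:4])
  multi <- genetic_regression(scv, meas, trait = "trait", mode = "multiple")
  expect_lt(abs(multi$beta[multi$factor == "F2"]), 1e-5)
  expect_equal(multi$beta[multi$factor == "F1"], 0.4, tolerance = 1e-3)
  single <- genetic_regression(scv, meas, trait = "trait", mode = "single")
  # the true pathway fits exactly in single mode
  expect_equal(single$beta[single$factor == "F1"], 0.4, tolerance = 1e-3)
  # marginal F2 effect is positive (shared via the factor correlation) and
  # vanishes only after adjustment - the single-vs-multiple contrast
  expect_gt(single$beta[single$factor == "F2"], 0.05)
  expect_lt(abs(multi$beta[multi$factor == "F2"]),
            single$beta[single$factor == "F2"])
  expect_true(all(c("q_by") %in% names(single)))
})

test_that("a genetically uncorrelated trait regresses to zero on all factors", {
  st <- direct_study(seed = 71, k = 4, m = 4000, n = 5e4)
  # append an independent null trait
  set.seed(72)
  null_tab <- symfactor:::new_sumstat(data.table::data.table(
    SNP = st$tabs[[1]]$SNP, A1 = "A", A2 = "G",
    Z = stats::rnorm(nrow(st$tabs[[1]])), N = 5e4))
  tabs <- c(st$tabs, list(trait = null_tab))
  scv <- build_S_V(tabs, st$ld, n_blocks = 100)
  meas <- build_factor_spec(list(F1 = names(st$tabs)), names(st$tabs))
  res <- genetic_regression(scv, meas, trait = "trait", mode = "single")
  expect_true(all(abs(res$beta) <= 2.5 * res$se))
})
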