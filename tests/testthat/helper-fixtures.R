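# Shared fixtures: small covariance structures and simulated studies built
# in code at test time.

# Wrap a covariance matrix (and optional V) as a gencov_structure so the
# SEM layer can be unit-tested on exactly constructed inputs.
toy_scv <- function(S, V = NULL, N = 1e5, labels = rownames(S),
                    I_mat = NULL) {
  k <- nrow(S)
  u <- k * (k + 1) / 2
  if (is.null(labels)) labels <- paste0("t", seq_len(k))
  dimnames(S) <- list(labels, labels)
  if (is.null(V)) V <- diag(1e-6, u)
  h2t <- data.table::data.table(
    label = labels, h2_obs = diag(S), se_h2_obs = 0.01,
    intercept = 1, se_intercept = 0.01, mean_chi2 = 1.5,
    n_eff = rep(N, k))
  structure(list(labels = labels, S = S, V = V,
                 I_mat = I_mat %||% diag(k), h2_table = h2t,
                 N = rep(N, k), n_blocks = 200L, M = 1000L,
                 scale = "observed", smoothing_log = character()),
            class = "gencov_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-factor implied covariance with unit diagonal.
one_factor_S <- function(lambda) {
  S <- tcrossprod(lambda)
  diag(S) <- 1
  dimnames(S) <- list(paste0("y", seq_along(lambda)),
                      paste0("y", seq_along(lambda)))
  S
}

# Small direct-mode study: one cohort, k symptoms on a single factor.
direct_study <- function(seed, k = 3, m = 2000, n = 2e4, h2 = 0.2,
                         loading = 0.7, overlap_zero = TRUE) {
  labs <- paste0("S", seq_len(k))
  ts <- true_structure(labs, matrix(loading, k, 1), h2_liab = rep(h2, k),
                       prevalence_pop = rep(0.3, k))
  co <- cohort_design("c1", "community", n)
  l <- synthetic_ld_profile(m, seed = seed)
  cfg <- simulation_config(ts, list(co), m_snps = m, seed = seed,
                           mode = "sumstat_direct", ld = l)
  sim <- simulate_sumstats_direct(
    cfg, overlap = if (overlap_zero) function(a, b) 0 else NULL)
  tabs <- sim$tables$c1
  names(tabs) <- paste0("c1_", names(tabs))
  list(sim = sim, tabs = tabs, ld = ld_scores(tabs[[1]]$SNP, l), cfg = cfg,
       truth = ts)
}
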