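# Per-SNP genomic factor meta-analysis: common-pathway SNP effects on a
# symptom factor, independent-pathway comparison, and the Q_SNP
# heterogeneity statistic.

#' Well-powered symptom filter
#'
#' Returns the trait labels whose univariate LDSC results pass the power
#' thresholds used before the factor meta-analysis: positive SNP
#' heritability and mean chi-square above 1.02. The genetic-covariance
#' intercept criterion is directionally ambiguous as usually quoted, so it
#' is configurable and disabled by default: `intercept_rule = "above"`
#' requires intercept > threshold (intercept as a power proxy), `"below"`
#' requires intercept < threshold (absence of confounding).
#'
#' @param scv `gencov_structure` (uses its `h2_table`).
#' @param min_h2 minimum observed-scale h2 (default 0, exclusive).
#' @param min_mean_chi2 minimum mean chi-square (default 1.02).
#' @param min_n_eff minimum effective sample size (default 5000).
#' @param intercept_rule "none", "above" or "below".
#' @param intercept_threshold threshold for the intercept rule (default 1).
#' @return list: `included` labels, `table` (per-label pass/fail with
#'   reasons).
#' @export
well_powered_filter <- function(scv, min_h2 = 0, min_mean_chi2 = 1.02,
                                min_n_eff = 5000,
                                intercept_rule = c("none", "above", "below"),
                                intercept_threshold = 1) {
  intercept_rule <- match.arg(intercept_rule)
  ht <- scv$h2_table
  pass_h2 <- ht$h2_obs > min_h2
  pass_chi2 <- ht$mean_chi2 > min_mean_chi2
  pass_n <- ht$n_eff > min_n_eff
  pass_int <- switch(intercept_rule,
                     none = rep(TRUE, nrow(ht)),
                     above = ht$intercept > intercept_threshold,
                     below = ht$intercept < intercept_threshold)
  reason <- apply(cbind(!pass_h2, !pass_chi2, !pass_n, !pass_int), 1,
                  function(r) paste(c("h2", "mean_chi2", "n_eff",
                                      "intercept")[r], collapse = "+"))
  tab <- data.table::data.table(
    label = ht$label, h2_obs = ht$h2_obs, mean_chi2 = ht$mean_chi2,
    n_eff = ht$n_eff, intercept = ht$intercept,
    included = pass_h2 & pass_chi2 & pass_n & pass_int,
    excluded_by = ifelse(reason == "", NA_character_, reason))
  included <- tab$label[tab$included]
  if (!length(included)) warning("no trait passes the well-powered filter")
  list(included = included, table = tab,
       thresholds = list(min_h2 = min_h2, min_mean_chi2 = min_mean_chi2,
                         min_n_eff = min_n_eff,
                         intercept_rule = intercept_rule,
                         intercept_threshold = intercept_threshold))
}

#' Q_SNP heterogeneity test for one variant
#'
#' Compares a common-pathway model (the SNP affects every symptom through a
#' single path to the factor) against the independent-pathway model (one
#' free path per symptom, which fits the k SNP moments exactly). With b the
#' per-symptom SNP effects, their sampling covariance V_b built from the
#' LDSC intercept matrix (V_b[i,j] = intercept_ij se_i se_j), and delta the
#' covariance-scale factor loadings, the common-model effect is the GLS
#' combination a = (delta' W delta)^-1 delta' W b, W = V_b^-1, and
#' Q_SNP = (b - delta a)' W (b - delta a), asymptotically chi-square with
#' k - 1 degrees of freedom under the common pathway.
#'
#' @param z per-symptom z-scores of the SNP (named, order matching
#'   `loadings`).
#' @param n per-symptom sample sizes.
#' @param freq effect-allele frequency (SNP variance 2 f (1-f)); required.
#' @param I_mat LDSC intercept matrix (diagonal: univariate intercepts;
#'   off-diagonal: cross-trait sample-overlap intercepts).
#' @param loadings covariance-scale loadings of the symptoms on the common
#'   factor (from the fitted common-factor model).
#' @return `snp_association` list: beta_f, se, z, p (common pathway),
#'   q_snp, df, p_q, per-symptom independent effects.
#' @export
qsnp <- function(z, n, freq, I_mat, loadings) {
  k <- length(z)
  if (k < 2L) stop("Q_SNP undefined for fewer than 2 symptoms")
  stopifnot(length(n) == k, length(loadings) == k)
  if (is.na(freq) || freq <= 0 || freq >= 1)
    stop("valid allele frequency required for the SNP-variance expansion")
  v <- 2 * freq * (1 - freq)
  se_b <- 1 / sqrt(n * v)
  b <- z * se_b
  Vb <- I_mat * outer(se_b, se_b)
  W <- tryCatch(solve(Vb), error = function(e) pseudo_inverse(Vb))
  dWd <- drop(crossprod(loadings, W %*% loadings))
  a <- drop(crossprod(loadings, W %*% b)) / dWd
  r <- b - loadings * a
  q <- max(0, drop(t(r) %*% W %*% r))
  se_a <- sqrt(1 / dWd)
  structure(list(beta_f = a, se = se_a, z = a / se_a,
                 p = 2 * stats::pnorm(-abs(a / se_a)),
                 q_snp = q, df = k - 1L,
                 p_q = stats::pchisq(q, k - 1L, lower.tail = FALSE),
                 independent_beta = b, independent_se = se_b),
            class = "snp_association")
}

#' Genomic factor meta-analysis scan
#'
#' Fits the common-factor measurement model to the covariance structure
#' once, then applies [qsnp()] to every variant shared by all symptom
#' tables. Variants without a valid allele frequency, or failing the
#' per-variant computation, are logged and skipped. Output is sorted by the
#' common-pathway p-value and annotated with the significance tier
#' ("study_wide" below 5e-8 divided by the number of meta-analyses).
#'
#' @param tables named list of `sumstat` tables, one per included symptom
#'   (names matching `scv$labels`), harmonized to a common variant set.
#' @param scv `gencov_structure` over the same traits (observed scale:
#'   the z-scores and the structure must be on the same scale).
#' @param spec optional [model_spec()]; default one common factor.
#' @param n_meta number of meta-analyses for the study-wide tier (default 22).
#' @param ... passed to [fit_model()].
#' @return data.table: SNP, beta_f, se, z, p, q_snp, df, p_q, tier; the
#'   fitted measurement model and skip log as attributes.
#' @export
factor_meta_scan <- function(tables, scv, spec = NULL, n_meta = 22L, ...) {
  labels <- names(tables)
  stopifnot(!is.null(labels), all(labels %in% scv$labels))
  if (length(labels) < 2L) stop("need at least 2 symptoms for a factor scan")
  if (is.null(spec))
    spec <- build_factor_spec(list(F1 = labels), labels)
  fit <- fit_model(spec, scv, ...)
  delta <- fit$loadings[, 1]
  snps <- Reduce(intersect, lapply(tables, function(t) t$SNP))
  Zm <- vapply(tables, function(t) t$Z[match(snps, t$SNP)],
               numeric(length(snps)))
  Nm <- vapply(tables, function(t) {
    nn <- if ("N_EFF" %in% names(t) && !all(is.na(t$N_EFF))) t$N_EFF else t$N
    nn[match(snps, t$SNP)]
  }, numeric(length(snps)))
  fq <- if ("FREQ" %in% names(tables[[1L]]))
    tables[[1L]]$FREQ[match(snps, tables[[1L]]$SNP)] else
      rep(NA_real_, length(snps))
  Im <- scv$I_mat[labels, labels]
  skipped <- character()
  rows <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    res <- tryCatch(
      qsnp(Zm[i, ], Nm[i, ], fq[i], Im, delta),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- c(skipped, paste0(snps[i], ": ", res))
      next
    }
    rows[[i]] <- data.table::data.table(
      SNP = snps[i], beta_f = res$beta_f, se = res$se, z = res$z, p = res$p,
      q_snp = res$q_snp, df = res$df, p_q = res$p_q)
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out)) {
    out[, "tier" := significance_tier(out$p, n_meta)]
    data.table::setorderv(out, "p")
  }
  data.table::setattr(out, "measurement_fit", fit)
  data.table::setattr(out, "skipped", skipped)
  out[]
}
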