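# LD-score regression: SNP heritability, genetic covariance, the joint
# (S, V) genetic covariance structure via a shared block jackknife, and
# liability-scale conversion under clinical/community ascertainment.

#' LD score table
#'
#' @param snp variant ids.
#' @param l2 per-variant LD scores (>= 0).
#' @param M total number of SNPs the scores were computed over (defaults to
#'   the number of rows; for unlinked simulated SNPs l2 = 1 and M = rows).
#' @return `ld_scores` data.table with attribute `M`.
#' @export
ld_scores <- function(snp, l2, M = length(snp)) {
  stopifnot(length(snp) == length(l2), all(l2 >= 0), M >= length(snp))
  dt <- data.table::data.table(SNP = snp, L2 = as.numeric(l2))
  data.table::setattr(dt, "M", M)
  data.table::setattr(dt, "class", c("ld_scores", class(dt)))
  dt
}

#' Unit LD scores for unlinked variants
#'
#' @param snp variant ids.
#' @return [ld_scores()] with L2 = 1 for every variant.
#' @export
ld_scores_unit <- function(snp) ld_scores(snp, rep(1, length(snp)))

#' Read an LDSC-dialect .l2.ldscore file
#'
#' Tab-delimited with at least SNP and L2 columns; `M` is read from a
#' sidecar file (path plus ".M" suffix, single number) when present.
#'
#' @param path ldscore file.
#' @param m_path optional sidecar with the total SNP count.
#' @return [ld_scores()].
#' @export
read_ld_scores <- function(path, m_path = paste0(path, ".M")) {
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("SNP", "L2") %in% names(dt)))
    stop("LD score file must have SNP and L2 columns")
  M <- if (file.exists(m_path)) as.numeric(readLines(m_path)[1L]) else nrow(dt)
  ld_scores(dt$SNP, dt$L2, M)
}

# Assign n variants (in file order) to n_blocks contiguous jackknife blocks.
jackknife_blocks <- function(n, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, floor(n / 2)))
  list(id = ceiling(seq_len(n) * n_blocks / n), n_blocks = n_blocks)
}

# Weighted two-parameter regression y ~ 1 + x with a delete-a-block
# jackknife. Returns full-sample intercept/slope, leave-one-block-out
# estimates, and pseudovalue-based standard errors. With `int_fixed` the
# intercept is held at a known value (needed when x is constant, e.g. unit
# LD scores) and only the slope is estimated.
ldsc_regress <- function(y, x, w, block_id, n_blocks, int_fixed = NULL) {
  if (!is.null(int_fixed)) {
    yc <- y - int_fixed
    swx2 <- rowsum(w * x * x, block_id)
    swxy <- rowsum(w * x * yc, block_id)
    t2 <- sum(swx2); txy <- sum(swxy)
    full <- cbind(int = int_fixed, slope = txy / t2)
    loo <- cbind(int = rep(int_fixed, n_blocks),
                 slope = (txy - swxy) / (t2 - swx2))
    pseudo <- matrix(rep(n_blocks * full, each = n_blocks), ncol = 2) -
      (n_blocks - 1) * loo
    pseudo[, 1] <- int_fixed
    se <- c(0, sqrt(stats::var(pseudo[, 2]) / n_blocks))
  } else {
    sw <- rowsum(w, block_id); swx <- rowsum(w * x, block_id)
    swx2 <- rowsum(w * x * x, block_id); swy <- rowsum(w * y, block_id)
    swxy <- rowsum(w * x * y, block_id)
    tot <- c(sum(sw), sum(swx), sum(swx2), sum(swy), sum(swxy))
    solve2 <- function(a11, a12, a22, b1, b2) {
      det <- a11 * a22 - a12^2
      cbind(int = (a22 * b1 - a12 * b2) / det,
            slope = (a11 * b2 - a12 * b1) / det)
    }
    full <- solve2(tot[1], tot[2], tot[3], tot[4], tot[5])
    loo <- solve2(tot[1] - sw, tot[2] - swx, tot[3] - swx2,
                  tot[4] - swy, tot[5] - swxy)
    pseudo <- matrix(rep(n_blocks * full, each = n_blocks), ncol = 2) -
      (n_blocks - 1) * loo
    se <- sqrt(apply(pseudo, 2, stats::var) / n_blocks)
  }
  list(intercept = full[1], slope = full[2],
       se_intercept = se[1], se_slope = se[2],
       loo = loo, pseudo = pseudo)
}

# Fixed-intercept fallback value when LD scores are constant: 1 for a
# chi-square regression, 0 for a cross-trait product regression.
constant_ld_intercept <- function(l, cross = FALSE) {
  if (stats::var(l) > 1e-12) return(NULL)
  message("constant LD scores: intercept fixed at ", if (cross) 0 else 1)
  if (cross) 0 else 1
}

# Two-step LDSC heteroskedasticity weights for chi^2 (a == b) or z_a z_b
# regression; first pass unweighted to get a provisional slope.
ldsc_weights <- function(x, M, Na, Nb, slope_a, slope_b, slope_ab,
                         int_ab = 0) {
  la <- pmax(x, 1e-8)
  # heteroskedasticity: var(z_a z_b) ~ (1+Na h2a l/M)(1+Nb h2b l/M) + (cross)^2
  a_term <- pmax(1 + slope_a * x, 0.05)
  b_term <- pmax(1 + slope_b * x, 0.05)
  cross <- slope_ab * x + int_ab
  1 / (la * (a_term * b_term + cross^2))
}

#' SNP heritability by LD-score regression
#'
#' Regresses per-variant chi-square statistics on LD scores with a free
#' intercept: E[chi2_j] = a + (N h2 / M) l_j. The slope is rescaled by M/N to
#' the observed-scale heritability; standard errors come from a
#' delete-a-block jackknife over contiguous blocks. With `weights = "twostep"`
#' (default) a first unweighted pass supplies LDSC-style heteroskedasticity
#' weights 1/(l_j (1 + N h2 l_j / M)^2); `weights = "ols"` is exact on toy
#' collinear inputs. Supplying sample prevalence `P` and population
#' prevalence `K` adds the liability-scale conversion.
#'
#' @param dt `sumstat` table with Z and N (N_EFF used if present).
#' @param ld [ld_scores()].
#' @param n_blocks jackknife blocks (default 200; floored at 2, capped at
#'   half the variant count).
#' @param weights "twostep" or "ols".
#' @param chisq_cap optional cap on chi-square outliers (LDSC uses
#'   max(80, 0.001 N) on real data; disabled by default for synthetic data).
#' @param P,K sample and population prevalence for liability conversion.
#' @return `h2_result` list: h2_obs, intercept, ses, mean_chi2, n_blocks,
#'   n_snps, h2_liab (if P, K given), and jackknife internals.
#' @export
fit_h2 <- function(dt, ld, n_blocks = 200L, weights = c("twostep", "ols"),
                   chisq_cap = NULL, P = NULL, K = NULL) {
  weights <- match.arg(weights)
  x <- data.table::as.data.table(dt)
  m <- merge(x, ld, by = "SNP", sort = FALSE)
  if (nrow(m) < 3L) stop("too few variants joined to LD scores")
  if (nrow(m) < 200L && nrow(m) < nrow(ld))
    warning("fewer than 200 variants joined to LD scores; estimates unstable")
  N <- if ("N_EFF" %in% names(m) && !all(is.na(m$N_EFF))) m$N_EFF else m$N
  if (is.null(N) || all(is.na(N))) stop("N (or N_EFF) required for LDSC")
  Nbar <- mean(N)
  M <- attr(ld, "M") %||% nrow(ld)
  chi2 <- m$Z^2
  if (!is.null(chisq_cap)) chi2 <- pmin(chi2, chisq_cap)
  l <- m$L2
  bl <- jackknife_blocks(length(chi2), n_blocks)
  w0 <- rep(1, length(chi2))
  int_fix <- constant_ld_intercept(l)
  fit <- ldsc_regress(chi2, l, w0, bl$id, bl$n_blocks, int_fix)
  if (weights == "twostep") {
    w <- ldsc_weights(l, M, Nbar, Nbar, fit$slope, fit$slope, fit$slope)
    fit <- ldsc_regress(chi2, l, w, bl$id, bl$n_blocks, int_fix)
  }
  scale <- M / Nbar
  out <- list(h2_obs = fit$slope * scale, intercept = fit$intercept,
              se_h2 = fit$se_slope * scale, se_intercept = fit$se_intercept,
              mean_chi2 = mean(chi2), n_blocks = bl$n_blocks,
              n_snps = length(chi2), N = Nbar, M = M,
              loo_h2 = fit$loo[, 2] * scale, loo_intercept = fit$loo[, 1],
              weights = weights)
  if (out$h2_obs < 0) out$flag <- "negative_h2"
  if (!is.null(P) && !is.null(K)) {
    mult <- liability_factor(P, K)
    out$h2_liab <- out$h2_obs * mult
    out$se_h2_liab <- out$se_h2 * mult
    out$P <- P; out$K <- K
  }
  class(out) <- "h2_result"
  out
}

#' @export
print.h2_result <- function(x, ...) {
  cat(sprintf("h2_obs = %.4f (%.4f)  intercept = %.4f (%.4f)  mean chi2 = %.3f\n",
              x$h2_obs, x$se_h2, x$intercept, x$se_intercept, x$mean_chi2))
  if (!is.null(x$h2_liab))
    cat(sprintf("h2_liab = %.4f (%.4f)  [P = %.3g, K = %.3g]\n",
                x$h2_liab, x$se_h2_liab, x$P, x$K))
  invisible(x)
}

#' Cross-trait LD-score regression (genetic covariance)
#'
#' Regresses z_a z_b on LD scores; the slope times M / sqrt(N_a N_b) is the
#' genetic covariance and the free intercept absorbs sample overlap
#' (rho N_s / sqrt(N_a N_b)). The genetic correlation is
#' cov / sqrt(h2_a h2_b).
#'
#' @param a,b `sumstat` tables, harmonized to common alleles.
#' @param ld [ld_scores()].
#' @inheritParams fit_h2
#' @return `gencov_result` list: gencov, intercept, ses, rg, n_snps,
#'   jackknife internals.
#' @export
fit_gencov <- function(a, b, ld, n_blocks = 200L,
                       weights = c("twostep", "ols")) {
  weights <- match.arg(weights)
  pick_n <- function(t) {
    nn <- if ("N_EFF" %in% names(t) && !all(is.na(t$N_EFF))) t$N_EFF else t$N
    if (is.null(nn)) stop("N (or N_EFF) required for cross-trait LDSC")
    mean(nn)
  }
  Na <- pick_n(a); Nb <- pick_n(b)
  da <- data.table::as.data.table(a); db <- data.table::as.data.table(b)
  m <- merge(da[, c("SNP", "Z")], db[, c("SNP", "Z")],
             by = "SNP", suffixes = c("_a", "_b"), sort = FALSE)
  if (nrow(m) < 3L) stop("no (or too few) overlapping variants")
  m <- merge(m, ld, by = "SNP", sort = FALSE)
  M <- attr(ld, "M") %||% nrow(ld)
  y <- m$Z_a * m$Z_b
  l <- m$L2
  bl <- jackknife_blocks(length(y), n_blocks)
  int_x <- constant_ld_intercept(l, cross = TRUE)
  int_u <- constant_ld_intercept(l)
  ones <- rep(1, length(y))
  fit <- ldsc_regress(y, l, ones, bl$id, bl$n_blocks, int_x)
  ha <- ldsc_regress(m$Z_a^2, l, ones, bl$id, bl$n_blocks, int_u)
  hb <- ldsc_regress(m$Z_b^2, l, ones, bl$id, bl$n_blocks, int_u)
  if (weights == "twostep") {
    w <- ldsc_weights(l, M, Na, Nb, ha$slope, hb$slope, fit$slope,
                      fit$intercept)
    fit <- ldsc_regress(y, l, w, bl$id, bl$n_blocks, int_x)
  }
  scale <- M / sqrt(Na * Nb)
  h2a <- ha$slope * M / Na; h2b <- hb$slope * M / Nb
  rg <- if (h2a > 0 && h2b > 0) fit$slope * scale / sqrt(h2a * h2b) else NA_real_
  structure(list(gencov = fit$slope * scale, intercept = fit$intercept,
                 se_gencov = fit$se_slope * scale,
                 se_intercept = fit$se_intercept, rg = rg,
                 n_snps = length(y), n_blocks = bl$n_blocks,
                 loo_gencov = fit$loo[, 2] * scale),
            class = "gencov_result")
}

#' Observed-to-liability scale conversion factor
#'
#' For a binary trait analysed with sample prevalence P and population
#' prevalence K, heritability on the liability scale is the observed-scale
#' estimate times K^2 (1-K)^2 / (P (1-P) phi(z)^2), z = Phi^-1(1-K). At
#' P = K = 0.5 the multiplier is exactly pi/2. Genetic covariance elements
#' are scaled by the geometric mean of the two traits' multipliers.
#'
#' @param P sample prevalence in (0,1).
#' @param K population prevalence in (0,1).
#' @return the multiplier.
#' @export
liability_factor <- function(P, K) {
  if (any(P <= 0 | P >= 1)) stop("P must be in (0,1)")
  if (any(K <= 0 | K >= 1)) stop("K must be in (0,1)")
  z <- stats::qnorm(1 - K)
  K^2 * (1 - K)^2 / (P * (1 - P) * stats::dnorm(z)^2)
}

#' Multivariable genetic covariance structure (S, V)
#'
#' Assembles the genetic covariance matrix S among k traits from univariate
#' and bivariate LD-score regressions on a common variant set, and its
#' sampling covariance V from a joint delete-a-block jackknife: all
#' u = k(k+1)/2 unique elements are re-estimated leaving out each block, and
#' V is the covariance of the pseudovalues divided by the number of blocks.
#' Half-vectorization follows [vech()] (column-major lower triangle,
#' diagonal included). Supplying prevalences applies the liability
#' conversion elementwise by the geometric mean of the univariate
#' multipliers; the diagonal of S then equals the univariate liability
#' heritabilities exactly. Non-PSD S or V are eigenvalue-clipped with a log
#' entry.
#'
#' @param tables named list of `sumstat` tables (one per trait), harmonized
#'   to the same variant set and order.
#' @param ld [ld_scores()].
#' @param prevalences optional data.frame with columns label, P, K.
#' @param n_blocks jackknife blocks.
#' @param weights "twostep" or "ols".
#' @return `gencov_structure`: labels, S, V, I_mat (LDSC intercepts:
#'   univariate on the diagonal, cross-trait off it), h2_table, N, smoothing
#'   log, scale ("liability" or "observed").
#' @export
build_S_V <- function(tables, ld, prevalences = NULL, n_blocks = 200L,
                      weights = c("twostep", "ols")) {
  weights <- match.arg(weights)
  k <- length(tables)
  labels <- names(tables)
  if (is.null(labels) || anyDuplicated(labels))
    stop("tables must be uniquely named by trait label")
  snps <- tables[[1L]]$SNP
  for (t in tables)
    if (!identical(t$SNP, snps))
      stop("all tables must share an identical variant set and order")
  m0 <- merge(data.table::data.table(SNP = snps, ord = seq_along(snps)),
              ld, by = "SNP", sort = FALSE)
  data.table::setorderv(m0, "ord")
  l <- m0$L2
  keep <- match(m0$SNP, snps)
  M <- attr(ld, "M") %||% nrow(ld)
  Z <- vapply(tables, function(t) t$Z[keep], numeric(length(keep)))
  N <- vapply(tables, function(t) {
    nn <- if ("N_EFF" %in% names(t) && !all(is.na(t$N_EFF))) t$N_EFF else t$N
    mean(nn[keep])
  }, numeric(1))
  bl <- jackknife_blocks(length(l), n_blocks)
  u <- k * (k + 1) / 2
  S <- matrix(0, k, k, dimnames = list(labels, labels))
  I_mat <- matrix(0, k, k, dimnames = list(labels, labels))
  pseudo <- matrix(0, bl$n_blocks, u)
  h2_rows <- vector("list", k)
  ones <- rep(1, length(l))
  int_u <- constant_ld_intercept(l)
  int_x <- constant_ld_intercept(l, cross = TRUE)
  # univariate first (their slopes feed the cross-trait weights)
  uni <- vector("list", k)
  for (i in seq_len(k)) {
    y <- Z[, i]^2
    f0 <- ldsc_regress(y, l, ones, bl$id, bl$n_blocks, int_u)
    f <- if (weights == "twostep") {
      w <- ldsc_weights(l, M, N[i], N[i], f0$slope, f0$slope, f0$slope)
      ldsc_regress(y, l, w, bl$id, bl$n_blocks, int_u)
    } else f0
    uni[[i]] <- f
    h2_rows[[i]] <- data.table::data.table(
      label = labels[i], h2_obs = f$slope * M / N[i],
      se_h2_obs = f$se_slope * M / N[i], intercept = f$intercept,
      se_intercept = f$se_intercept, mean_chi2 = mean(y), n_eff = N[i])
  }
  col <- 0L
  for (j in seq_len(k)) for (i in j:k) {
    col <- col + 1L
    if (i == j) {
      f <- uni[[i]]
      scale <- M / N[i]
      S[i, i] <- f$slope * scale
      I_mat[i, i] <- f$intercept
      pseudo[, col] <- f$pseudo[, 2] * scale
    } else {
      y <- Z[, i] * Z[, j]
      f0 <- ldsc_regress(y, l, ones, bl$id, bl$n_blocks, int_x)
      f <- if (weights == "twostep") {
        w <- ldsc_weights(l, M, N[i], N[j], uni[[i]]$slope, uni[[j]]$slope,
                          f0$slope, f0$intercept)
        ldsc_regress(y, l, w, bl$id, bl$n_blocks, int_x)
      } else f0
      scale <- M / sqrt(N[i] * N[j])
      S[i, j] <- S[j, i] <- f$slope * scale
      I_mat[i, j] <- I_mat[j, i] <- f$intercept
      pseudo[, col] <- f$pseudo[, 2] * scale
    }
  }
  h2_table <- data.table::rbindlist(h2_rows)
  scale_used <- "observed"
  if (!is.null(prevalences)) {
    pv <- data.table::as.data.table(prevalences)
    if (!all(labels %in% pv$label))
      stop("prevalences must cover every trait label; missing: ",
           paste(setdiff(labels, pv$label), collapse = ", "))
    mult <- vapply(labels, function(lb) {
      r <- pv[pv$label == lb][1L]
      liability_factor(r$P, r$K)
    }, numeric(1))
    gm <- sqrt(outer(mult, mult))
    S <- S * gm
    pseudo <- pseudo * rep(vech(gm), each = bl$n_blocks)
    h2_table[, "h2_liab" := h2_table$h2_obs * mult]
    h2_table[, "se_h2_liab" := h2_table$se_h2_obs * mult]
    scale_used <- "liability"
  }
  V <- stats::cov(pseudo) / bl$n_blocks
  log_lines <- character()
  Ssm <- smooth_psd(S)
  if (attr(Ssm, "smoothed")) log_lines <- c(log_lines, sprintf(
    "S eigenvalue-clipped; perturbation spectral norm %.3g",
    attr(Ssm, "smoothing_norm")))
  Vsm <- smooth_psd(V)
  if (attr(Vsm, "smoothed")) log_lines <- c(log_lines, sprintf(
    "V eigenvalue-clipped; perturbation spectral norm %.3g",
    attr(Vsm, "smoothing_norm")))
  vl <- vech_labels(labels)
  dimnames(Vsm) <- list(vl, vl)
  attr(Ssm, "smoothed") <- attr(Ssm, "smoothing_norm") <- NULL
  attr(Vsm, "smoothed") <- attr(Vsm, "smoothing_norm") <- NULL
  structure(list(labels = labels, S = Ssm, V = Vsm, I_mat = I_mat,
                 h2_table = h2_table, N = N, n_blocks = bl$n_blocks,
                 M = M, scale = scale_used, smoothing_log = log_lines),
            class = "gencov_structure")
}

#' @export
print.gencov_structure <- function(x, ...) {
  cat(sprintf("<gencov_structure> %d traits (%s scale), %d jackknife blocks\n",
              length(x$labels), x$scale, x$n_blocks))
  print(round(x$S, 4))
  invisible(x)
}

#' Reorder the traits of a genetic covariance structure
#'
#' Permutes S rows/columns, the intercept matrix, and V consistently.
#'
#' @param scv `gencov_structure`.
#' @param new_order permutation of the labels (character or integer).
#' @return permuted `gencov_structure`.
#' @export
reorder_scv <- function(scv, new_order) {
  idx <- if (is.character(new_order)) match(new_order, scv$labels) else new_order
  stopifnot(!anyNA(idx), length(idx) == length(scv$labels))
  k <- length(idx)
  old_pos <- outer(seq_len(k), seq_len(k), function(i, j)
    vech_pos(pmax(idx[i], idx[j]), pmin(idx[i], idx[j]), k))
  sel <- vech(old_pos)
  out <- scv
  out$labels <- scv$labels[idx]
  out$S <- scv$S[idx, idx]
  out$I_mat <- scv$I_mat[idx, idx]
  out$V <- scv$V[sel, sel]
  out$N <- scv$N[idx]
  out$h2_table <- scv$h2_table[match(out$labels, scv$h2_table$label)]
  vl <- vech_labels(out$labels)
  dimnames(out$V) <- list(vl, vl)
  out
}

#' Append an external trait to a genetic covariance structure
#'
#' Builds the (k+1)-trait structure needed for genetic regression by
#' re-running the joint jackknife over all traits.
#'
#' @param tables named trait tables including the external trait (last).
#' @inheritParams build_S_V
#' @return `gencov_structure` over k+1 traits.
#' @export
augment_scv <- function(tables, ld, prevalences = NULL, n_blocks = 200L,
                        weights = c("twostep", "ols")) {
  build_S_V(tables, ld, prevalences, n_blocks, match.arg(weights))
}
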