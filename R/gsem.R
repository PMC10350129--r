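# Confirmatory genetic factor models on (S, V) by diagonally weighted least
# squares, with sandwich standard errors, a residual-based model chi-square,
# AIC / CFI / SRMR fit indices, and genetic regression of external traits on
# symptom factors.
#
# Identification convention: factor variances fixed to 1 (all loadings
# free), matching the reporting of standardized loadings. The DWLS weight
# matrix is diag(V)^-1; the full sampling covariance V enters only the
# sandwich covariance and the test statistic.

#' Specify a genetic factor model
#'
#' @param loadings indicator x factor matrix: `NA` = free loading, a number
#'   = fixed value (0 = no loading). Row names are indicator labels, column
#'   names factor names.
#' @param factor_corr factor x factor pattern: `NA` = free correlation,
#'   number = fixed (0 = orthogonal). Diagonal must be fixed at 1 (unit
#'   factor variance identification). Default: all correlations free.
#' @param resid_var length-k pattern for residual variances (`NA` free,
#'   default all free).
#' @param resid_cov list of label pairs with free residual covariances.
#' @return `model_spec` object.
#' @export
model_spec <- function(loadings, factor_corr = NULL, resid_var = NULL,
                       resid_cov = NULL) {
  loadings <- as.matrix(loadings)
  k <- nrow(loadings); f <- ncol(loadings)
  if (is.null(rownames(loadings))) stop("loadings need indicator row names")
  if (is.null(colnames(loadings)))
    colnames(loadings) <- paste0("F", seq_len(f))
  if (is.null(factor_corr)) {
    factor_corr <- matrix(NA_real_, f, f)
    diag(factor_corr) <- 1
  }
  factor_corr <- as.matrix(factor_corr)
  dimnames(factor_corr) <- list(colnames(loadings), colnames(loadings))
  if (any(is.na(diag(factor_corr))) || any(diag(factor_corr) != 1))
    stop("factor variances must be fixed to 1 (unit-variance identification)")
  if (is.null(resid_var)) resid_var <- rep(NA_real_, k)
  loads <- is.na(loadings) | loadings != 0
  if (any(rowSums(loads) == 0))
    stop("indicator(s) load on no factor: ",
         paste(rownames(loadings)[rowSums(loads) == 0], collapse = ", "))
  for (pr in resid_cov)
    if (!all(pr %in% rownames(loadings)))
      stop("residual covariance names unknown: ", paste(pr, collapse = ", "))
  structure(list(loadings = loadings, factor_corr = factor_corr,
                 resid_var = resid_var, resid_cov = resid_cov %||% list(),
                 labels = rownames(loadings),
                 factors = colnames(loadings)),
            class = "model_spec")
}

#' Number of free parameters in a model specification
#' @param spec `model_spec`.
#' @return integer count.
#' @export
n_free_params <- function(spec) {
  sum(is.na(spec$loadings)) +
    sum(is.na(spec$factor_corr[lower.tri(spec$factor_corr)])) +
    sum(is.na(spec$resid_var)) + length(spec$resid_cov)
}

# Subset a gencov_structure to a label subset (in the given order).
subset_scv <- function(scv, labels) {
  stopifnot(all(labels %in% scv$labels))
  reorder_scv(scv, c(labels, setdiff(scv$labels, labels))) |>
    (function(x) {
      k <- length(labels)
      keep <- seq_len(k)
      sel <- vech(outer(seq_len(k), seq_len(k), function(i, j)
        vech_pos(pmax(i, j), pmin(i, j), length(x$labels))))
      out <- x
      out$labels <- x$labels[keep]
      out$S <- x$S[keep, keep, drop = FALSE]
      out$I_mat <- x$I_mat[keep, keep, drop = FALSE]
      out$V <- x$V[sel, sel, drop = FALSE]
      out$N <- x$N[keep]
      out$h2_table <- x$h2_table[match(out$labels, x$h2_table$label)]
      out
    })()
}

# Map a parameter vector into (Lambda, Psi, Theta) given the spec.
spec_skeleton <- function(spec) {
  L <- spec$loadings; P <- spec$factor_corr
  k <- nrow(L); f <- ncol(L)
  iL <- which(is.na(L))
  iP <- which(is.na(P) & lower.tri(P))
  iTh <- which(is.na(spec$resid_var))
  rc <- t(vapply(spec$resid_cov, function(pr)
    match(pr, spec$labels), integer(2)))
  list(L0 = ifelse(is.na(L), 0, L), P0 = ifelse(is.na(P), 0, P),
       Th0 = ifelse(is.na(spec$resid_var), 0, spec$resid_var),
       iL = iL, iP = iP, iTh = iTh, rc = rc, k = k, f = f,
       n_par = length(iL) + length(iP) + length(iTh) + nrow(rc))
}

spec_implied <- function(theta, sk) {
  L <- sk$L0; P <- sk$P0; th <- sk$Th0
  nL <- length(sk$iL); nP <- length(sk$iP); nT <- length(sk$iTh)
  if (nL) L[sk$iL] <- theta[seq_len(nL)]
  if (nP) {
    P[sk$iP] <- theta[nL + seq_len(nP)]
    P[upper.tri(P)] <- t(P)[upper.tri(P)]
  }
  Theta <- diag(th, sk$k)
  if (nT) diag(Theta)[sk$iTh] <- theta[nL + nP + seq_len(nT)]
  if (nrow(sk$rc)) for (r in seq_len(nrow(sk$rc))) {
    i <- sk$rc[r, 1]; j <- sk$rc[r, 2]
    Theta[i, j] <- Theta[j, i] <- theta[nL + nP + nT + r]
  }
  Sigma <- L %*% P %*% t(L) + Theta
  list(Sigma = Sigma, L = L, P = P, Theta = Theta)
}

# Numeric Jacobian of vech(Sigma(theta)).
implied_jacobian <- function(theta, sk) {
  u <- sk$k * (sk$k + 1) / 2
  J <- matrix(0, u, length(theta))
  for (p in seq_along(theta)) {
    h <- 1e-6 * (abs(theta[p]) + 1e-3)
    tp <- theta; tp[p] <- tp[p] + h
    tm <- theta; tm[p] <- tm[p] - h
    J[, p] <- (vech(spec_implied(tp, sk)$Sigma) -
                 vech(spec_implied(tm, sk)$Sigma)) / (2 * h)
  }
  J
}

start_values <- function(spec, sk, S, jitter = 0) {
  d <- sqrt(pmax(diag(S), 1e-4))
  st <- numeric(sk$n_par)
  nL <- length(sk$iL); nP <- length(sk$iP); nT <- length(sk$iTh)
  if (nL) {
    rows <- ((sk$iL - 1) %% sk$k) + 1
    st[seq_len(nL)] <- 0.6 * d[rows]
  }
  if (nP) st[nL + seq_len(nP)] <- 0.3
  if (nT) st[nL + nP + seq_len(nT)] <- 0.5 * pmax(diag(S), 1e-4)[sk$iTh]
  if (jitter > 0) st <- st * (1 + jitter * stats::rnorm(length(st)))
  st
}

#' Fit a genetic factor model by diagonally weighted least squares
#'
#' Minimizes (s - sigma(theta))' D^-1 (s - sigma(theta)) with s = vech(S)
#' and D = diag(V), using a quasi-Newton optimizer with several seeded
#' restarts. Standard errors are sandwich estimates using the full V. The
#' model chi-square is the residual-based quadratic form
#' e' (V+ - V+ J (J'V+J)^-1 J'V+) e with J the Jacobian of the implied
#' moments, which is 0 at saturation and asymptotically chi-square on
#' u - n_free degrees of freedom. AIC = chi2 + 2 n_free; CFI compares to the
#' diagonal (independence) model; SRMR is the root mean square residual of
#' the observed-diagonal-standardized matrices over unique elements
#' including the diagonal.
#'
#' @param spec [model_spec()]; its labels must be a subset of the structure's.
#' @param scv `gencov_structure` from [build_S_V()] (traits with h2 <= 0
#'   should be excluded beforehand; see [well_powered_filter()]).
#' @param restarts optimizer restarts with jittered starts (default 5).
#' @param seed seed for the jitter (deterministic fits).
#' @param tol relative convergence tolerance (default 1e-10).
#' @param start optional user start vector (e.g. a nested model's solution
#'   padded with zeros, which guarantees the nesting inequality); used for
#'   the first restart.
#' @return `fit_result`: estimates table (with sandwich SEs), chisq, df, p,
#'   AIC, CFI, SRMR, residuals, convergence, warnings (Heywood cases),
#'   implied matrices.
#' @export
fit_model <- function(spec, scv, restarts = 5L, seed = 1L, tol = 1e-10,
                      start = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(scv, "gencov_structure"))
  if (!all(spec$labels %in% scv$labels))
    stop("spec labels absent from structure: ",
         paste(setdiff(spec$labels, scv$labels), collapse = ", "))
  if (!identical(spec$labels, scv$labels)) scv <- subset_scv(scv, spec$labels)
  S <- scv$S; V <- scv$V
  k <- nrow(S); u <- k * (k + 1) / 2
  sk <- spec_skeleton(spec)
  q <- sk$n_par
  df <- u - q
  if (df < 0) stop("model not identified: ", q, " free parameters > ", u,
                   " unique moments")
  s <- vech(S)
  d <- pmax(diag(V), max(diag(V), 1e-12) * 1e-8)
  obj <- function(theta) {
    r <- s - vech(spec_implied(theta, sk)$Sigma)
    sum(r * r / d)
  }
  best <- NULL
  if (!is.null(start) && length(start) != q)
    stop("start vector must have length ", q)
  if (q == 0L) {
    best <- list(par = numeric(0), objective = obj(numeric(0)),
                 convergence = 0L)
  } else {
    for (r in seq_len(restarts)) {
      set.seed(seed + r - 1L)
      st <- if (r == 1L && !is.null(start)) start else
        start_values(spec, sk, S, jitter = if (r == 1L) 0 else 0.25)
      ft <- tryCatch(
        stats::nlminb(st, obj, control = list(rel.tol = tol, x.tol = 1e-12,
                                              iter.max = 2000, eval.max = 8000)),
        error = function(e) NULL)
      if (!is.null(ft) && (is.null(best) || ft$objective < best$objective))
        best <- ft
    }
    if (is.null(best)) stop("optimizer failed in all restarts")
  }
  converged <- best$convergence == 0 || best$objective < 1e-12
  theta <- best$par
  imp <- spec_implied(theta, sk)
  e <- s - vech(imp$Sigma)
  J <- implied_jacobian(theta, sk)
  W <- 1 / d
  # sandwich covariance of theta-hat
  if (q > 0L) {
    B <- crossprod(J, J * W)
    Binv <- tryCatch(solve(B), error = function(e) pseudo_inverse(B))
    meat <- crossprod(J * W, V %*% (J * W))
    acov <- Binv %*% meat %*% Binv
    se <- sqrt(pmax(diag(acov), 0))
  } else {
    acov <- matrix(0, 0, 0)
    se <- numeric(0)
  }
  # residual-based test statistic
  Vp <- pseudo_inverse(V)
  chisq <- if (df == 0) 0 else if (q == 0L) {
    max(0, drop(t(e) %*% Vp %*% e))
  } else {
    VJ <- Vp %*% J
    Pm <- Vp - VJ %*% pseudo_inverse(crossprod(J, VJ)) %*% t(VJ)
    max(0, drop(t(e) %*% Pm %*% e))
  }
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  # independence (diagonal) model for CFI: fits the diagonal exactly
  diag_pos <- vech_pos(seq_len(k), seq_len(k), k)
  Ji <- matrix(0, u, k); Ji[cbind(diag_pos, seq_len(k))] <- 1
  ei <- s; ei[diag_pos] <- 0
  VJi <- Vp %*% Ji
  Pmi <- Vp - VJi %*% pseudo_inverse(crossprod(Ji, VJi)) %*% t(VJi)
  chisq_ind <- max(0, drop(t(ei) %*% Pmi %*% ei))
  df_ind <- u - k
  denom <- chisq_ind - df_ind
  cfi <- if (denom <= 0) NA_real_ else
    min(1, max(0, (denom - (chisq - df)) / denom))
  # SRMR on the observed-diagonal-standardized metric, diagonal included
  ds <- sqrt(pmax(diag(S), 1e-12))
  Rres <- (S - imp$Sigma) / outer(ds, ds)
  srmr <- sqrt(mean(vech(Rres)^2))
  aic <- chisq + 2 * q
  # parameter table
  par_names <- c(
    if (length(sk$iL)) sprintf("%s =~ %s",
      colnames(spec$loadings)[((sk$iL - 1) %/% k) + 1],
      spec$labels[((sk$iL - 1) %% k) + 1]),
    if (length(sk$iP)) sprintf("%s ~~ %s",
      spec$factors[((sk$iP - 1) %/% sk$f) + 1],
      spec$factors[((sk$iP - 1) %% sk$f) + 1]),
    if (length(sk$iTh)) sprintf("resid %s", spec$labels[sk$iTh]),
    if (nrow(sk$rc)) sprintf("resid %s ~~ %s", spec$labels[sk$rc[, 1]],
                             spec$labels[sk$rc[, 2]]))
  est <- if (q == 0L)
    data.table::data.table(parameter = character(), estimate = numeric(),
                           se = numeric(), z = numeric(), p = numeric())
  else
    data.table::data.table(parameter = par_names, estimate = theta,
                           se = se, z = theta / se,
                           p = 2 * stats::pnorm(-abs(theta / se)))
  warns <- character()
  heywood <- which(diag(imp$Theta) < 0)
  if (length(heywood))
    warns <- c(warns, paste0("Heywood case (negative residual variance): ",
                             paste(spec$labels[heywood], collapse = ", ")))
  std_load <- imp$L / sqrt(pmax(diag(imp$Sigma), 1e-12))
  if (any(abs(std_load) > 1 + 1e-8 & rep(diag(imp$Theta) >= 0, sk$f)))
    warns <- c(warns, "standardized loading outside [-1, 1]")
  structure(list(estimates = est, theta = theta, acov = acov,
                 chisq = chisq, df = df, p = p, aic = aic, cfi = cfi,
                 srmr = srmr, n_free = q, u = u,
                 chisq_independence = chisq_ind, df_independence = df_ind,
                 residuals = Rres, implied = imp$Sigma,
                 loadings = imp$L, factor_corr = imp$P, resid = imp$Theta,
                 std_loadings = std_load,
                 converged = converged, objective = best$objective,
                 warnings = warns, spec = spec, labels = spec$labels),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("chi2(%d) = %.3f  p = %.3g  AIC = %.1f  CFI = %.3f  SRMR = %.4f\n",
              x$df, x$chisq, x$p, x$aic, x$cfi, x$srmr))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Fit indices of a fitted model
#'
#' @param fit a `fit_result`.
#' @return named list: AIC, CFI, SRMR, chisq, df, p.
#' @export
fit_indices <- function(fit) {
  list(AIC = fit$aic, CFI = fit$cfi, SRMR = fit$srmr,
       chisq = fit$chisq, df = fit$df, p = fit$p)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' q_i = min over j >= i of m c(m) p_(j) / j with c(m) the harmonic number,
#' capped at 1; valid under arbitrary dependence. Thin wrapper around
#' [stats::p.adjust()] with `method = "BY"`.
#'
#' @param p p-values.
#' @return adjusted q-values.
#' @export
fdr_by <- function(p) stats::p.adjust(p, method = "BY")

#' Genetic regression of an external trait on symptom factors
#'
#' The trait (already a row/column of the structure) is regressed on the
#' factors of a measurement model: the implied covariance treats the trait
#' as an extra variable with free paths from the regression factors, so
#' coefficients are partial (multiple mode) or marginal (single mode)
#' standardized effects on unit-variance factors.
#'
#' @param scv `gencov_structure` containing the symptom indicators and the
#'   trait.
#' @param factors [model_spec()] for the symptom measurement model (factors
#'   only over symptom indicators).
#' @param trait label of the external trait inside `scv`.
#' @param mode "single" (one factor per fit) or "multiple" (all factors
#'   jointly).
#' @param on restrict regression to these factors (default: all
#'   non-orthogonal-measurement factors).
#' @param ... passed to [fit_model()].
#' @return data.table: factor, mode, beta (standardized), se, z, p, q_by.
#' @export
genetic_regression <- function(scv, factors, trait,
                               mode = c("single", "multiple"),
                               on = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(trait %in% scv$labels)
  on <- on %||% factors$factors
  rows <- list()
  make_aug <- function(which_factors) {
    L <- rbind(factors$loadings,
               matrix(0, 1, length(factors$factors),
                      dimnames = list(trait, factors$factors)))
    L[trait, which_factors] <- NA_real_
    model_spec(L, factor_corr = factors$factor_corr,
               resid_var = c(factors$resid_var, NA_real_),
               resid_cov = factors$resid_cov)
  }
  sub <- subset_scv(scv, c(factors$labels, trait))
  fit_one <- function(which_factors, mode_label) {
    aug <- make_aug(which_factors)
    fit <- fit_model(aug, sub, ...)
    gamma <- fit$loadings[trait, which_factors]
    sd_t <- sqrt(max(fit$implied[trait, trait], 1e-12))
    idx <- match(sprintf("%s =~ %s", which_factors, trait),
                 fit$estimates$parameter)
    se <- fit$estimates$se[idx]
    unstable <- any(diag(fit$factor_corr) <= 0)
    data.table::data.table(
      trait = trait, factor = which_factors, mode = mode_label,
      beta = as.numeric(gamma) / sd_t, se = se / sd_t,
      z = as.numeric(gamma) / se,
      p = 2 * stats::pnorm(-abs(as.numeric(gamma) / se)),
      flag = if (unstable) "unstable_factor_variance" else NA_character_)
  }
  if (mode == "single") {
    for (fc in on) rows[[fc]] <- fit_one(fc, "single")
  } else {
    rows[["multiple"]] <- fit_one(on, "multiple")
  }
  out <- data.table::rbindlist(rows)
  out[, "q_by" := fdr_by(out$p)]
  out[]
}
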