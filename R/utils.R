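# Small numeric helpers shared across modules.

#' Half-vectorize a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) in column-major order:
#' for column j, rows j..k. This is the fixed ordering used for the sampling
#' covariance `V` of a genetic covariance matrix throughout the package.
#'
#' @param M symmetric numeric matrix.
#' @return numeric vector of length k(k+1)/2.
#' @export
vech <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  M[lower.tri(M, diag = TRUE)]
}

#' Invert [vech()]: rebuild the symmetric matrix
#'
#' @param v vector of length k(k+1)/2.
#' @param k matrix dimension.
#' @return k x k symmetric matrix.
#' @export
unvech <- function(v, k) {
  stopifnot(length(v) == k * (k + 1) / 2)
  M <- matrix(0, k, k)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

# Names for vech elements, "a~a", "b~a", ... in vech order.
vech_labels <- function(labels) {
  k <- length(labels)
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  paste(labels[idx[, "row"]], labels[idx[, "col"]], sep = "~")
}

# Position of element (i, j), i >= j, in the vech vector.
vech_pos <- function(i, j, k) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1L) * k - (lo - 1L) * lo / 2 + hi
}

#' Clip a symmetric matrix to positive semi-definiteness
#'
#' Eigenvalues below `eps` times the mean diagonal magnitude are raised to
#' that floor. Used to smooth genetic covariance matrices (and their sampling
#' covariances) whose elementwise estimates need not be jointly PSD.
#'
#' @param M symmetric matrix.
#' @param eps relative eigenvalue floor (default 1e-6).
#' @return matrix with attribute `"smoothed"` (logical) and
#'   `"smoothing_norm"` (spectral norm of the perturbation).
#' @export
smooth_psd <- function(M, eps = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  floorv <- eps * mean(abs(diag(M)))
  if (all(e$values >= floorv)) {
    attr(M, "smoothed") <- FALSE
    attr(M, "smoothing_norm") <- 0
    return(M)
  }
  vals <- pmax(e$values, floorv)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(M)
  attr(out, "smoothed") <- TRUE
  attr(out, "smoothing_norm") <- max(abs(vals - e$values))
  out
}

# Moore-Penrose pseudo-inverse via symmetric eigendecomposition.
pseudo_inverse <- function(M, tol = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) stop("matrix numerically zero; cannot invert")
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# round() uses banker's rounding; printed prevalence tables round half up.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
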