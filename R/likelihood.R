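#' Row-scaled likelihood matrix
#'
#' Builds the n x m matrix of component likelihoods that defines the finite
#' NPMLE problem.  For a location grid the entry is the Gaussian density
#' `phi_{Sigma_i}(Y_i - mu_j)`; for a scale grid (d = 1) it is the density of
#' `N(0, sigma_j^2)` at `Y_i`.  All work is done in the log domain and each
#' row is scaled by its maximum: the stored matrix satisfies
#' `max_j L[i, j] = 1` and the raw likelihood is
#' `exp(row_log_scale[i]) * L[i, j]`.  Row scaling leaves the maximizing
#' weights unchanged (the log of a row sum shifts by a constant) and makes
#' far-away grid points underflow to 0 harmlessly instead of producing
#' non-finite values.
#'
#' @param data a [mixture_data].
#' @param support a [support_set]; `"scale"` kind requires d = 1.
#' @return an object of class `likelihood_matrix` with fields `L` (n x m,
#'   rows scaled to max 1), `row_log_scale` (length n), `n`, `m`, and
#'   `lowrank` (`NULL` until [lowrank_factorize()] is applied).
#' @export
likelihood_matrix <- function(data, support) {
  stopifnot(inherits(data, "mixture_data"), inherits(support, "support_set"))
  logL <- if (support$kind == "scale") {
    if (data$d != 1L) stop("scale mixtures require d = 1")
    log_lik_scale(data$Y[, 1L], support$points[, 1L])
  } else {
    if (support$d != data$d)
      stop(sprintf("grid dimension %d does not match data dimension %d",
                   support$d, data$d))
    switch(data$cov_mode,
           shared = log_lik_shared(data$Y, support$points, data$covs),
           diag   = log_lik_diag(data$Y, support$points, data$covs),
           full   = log_lik_full(data$Y, support$points, data$covs))
  }
  rls <- logL[cbind(seq_len(nrow(logL)),
                    max.col(logL, ties.method = "first"))]
  L <- exp(logL - rls)
  new_likelihood_matrix(L, rls)
}

new_likelihood_matrix <- function(L, row_log_scale, lowrank = NULL) {
  structure(list(L = L, row_log_scale = as.numeric(row_log_scale),
                 n = nrow(L), m = ncol(L), lowrank = lowrank),
            class = "likelihood_matrix")
}

#' @export
print.likelihood_matrix <- function(x, ...) {
  cat(sprintf("likelihood_matrix: %d x %d (row-scaled)%s\n", x$n, x$m,
              if (!is.null(x$lowrank))
                sprintf(", low-rank factors k = %d", x$lowrank$k) else ""))
  invisible(x)
}

# log N(Y_i; mu_j, Sigma) for one shared SPD Sigma, via one Cholesky factor
log_lik_shared <- function(Y, M, Sigma) {
  d <- ncol(Y)
  R <- chol(Sigma)                      # Sigma = R'R, R upper triangular
  Yw <- t(backsolve(R, t(Y), transpose = TRUE))
  Mw <- t(backsolve(R, t(M), transpose = TRUE))
  d2 <- outer(rowSums(Yw^2), rowSums(Mw^2), "+") - 2 * tcrossprod(Yw, Mw)
  d2[d2 < 0] <- 0                       # clip roundoff
  -0.5 * d2 - 0.5 * d * log(2 * pi) - sum(log(diag(R)))
}

# per-observation diagonal covariances: accumulate coordinate-wise quadratics
log_lik_diag <- function(Y, M, V) {
  n <- nrow(Y); m <- nrow(M); d <- ncol(Y)
  q <- matrix(0, n, m)
  for (cc in seq_len(d)) {
    w <- 1 / V[, cc]
    q <- q + outer(Y[, cc]^2 * w, rep(1, m)) -
      2 * tcrossprod(Y[, cc] * w, M[, cc]) +
      tcrossprod(w, M[, cc]^2)
  }
  -0.5 * q - 0.5 * d * log(2 * pi) - 0.5 * rowSums(log(V))
}

# per-observation full covariances: loop over observations, caching the
# Cholesky factor across identical consecutive matrices
log_lik_full <- function(Y, M, covs) {
  n <- nrow(Y); m <- nrow(M); d <- ncol(Y)
  out <- matrix(0, n, m)
  R <- NULL; prev <- NULL
  for (i in seq_len(n)) {
    Si <- covs[[i]]
    if (is.null(prev) || !identical(Si, prev)) {
      R <- chol(Si)
      prev <- Si
    }
    diff <- t(M) - Y[i, ]               # d x m
    W <- backsolve(R, diff, transpose = TRUE)
    out[i, ] <- -0.5 * colSums(W^2) - 0.5 * d * log(2 * pi) -
      sum(log(diag(R)))
  }
  out
}

# centered Gaussian scale mixture: L_ij = N(Y_i; 0, var_j)
log_lik_scale <- function(y, vars) {
  -0.5 * outer(y^2, 1 / vars) - rep(0.5 * log(2 * pi * vars),
                                    each = length(y))
}

#' Attach a truncated column-pivoted QR factorization of L
#'
#' Computes `L ~ Q R P'` (column-pivoted QR truncated at rank k) with the
#' smallest k such that the Frobenius norm of the discarded trailing block
#' of R is at most `rank_tol * ||L||_F`.  The factors are used to accelerate
#' the matrix-vector products of gradient evaluations when L is numerically
#' low rank (typical for d = 1); they are deliberately never used in Hessian
#' assembly, where the active-column submatrix is already small.
#'
#' @param Lmat a [likelihood_matrix].
#' @param rank_tol relative Frobenius tolerance (default `1e-8`).
#' @param max_rank cap on k; if the tolerance would need a larger rank the
#'   factorization is skipped and `Lmat` is returned unchanged.
#' @return `Lmat` with the `lowrank` field set (or unchanged on fallback).
#' @export
lowrank_factorize <- function(Lmat, rank_tol = 1e-8,
                              max_rank = min(Lmat$n, Lmat$m)) {
  stopifnot(inherits(Lmat, "likelihood_matrix"))
  qrf <- qr(Lmat$L, LAPACK = TRUE)
  Rfull <- qr.R(qrf)
  r <- min(Lmat$n, Lmat$m)
  # trailing residual: ||L - Q_k R_k P'||_F^2 = sum of squares of rows > k of R
  row_sq <- rowSums(Rfull^2)[seq_len(r)]
  tail_sq <- rev(cumsum(rev(row_sq)))   # tail_sq[k+1] = residual^2 after rank k
  fro2 <- sum(row_sq)
  thresh <- (rank_tol^2) * fro2
  k <- which(c(tail_sq[-1L], 0) <= thresh)[1L]
  if (is.na(k) || k > max_rank) return(Lmat)
  Q <- qr.Q(qrf)[, seq_len(k), drop = FALSE]
  R <- Rfull[seq_len(k), , drop = FALSE]
  perm <- qrf$pivot                      # L[, perm] ~ Q R
  Lmat$lowrank <- list(Q = Q, R = R, perm = perm, k = k, rank_tol = rank_tol)
  Lmat
}

# L %*% w and t(L) %*% v, routed through the low-rank factors when attached.
# Used on the gradient path only.
lik_mv <- function(Lmat, w) {
  lr <- Lmat$lowrank
  if (is.null(lr)) return(drop(Lmat$L %*% w))
  drop(lr$Q %*% (lr$R %*% w[lr$perm]))
}

lik_tmv <- function(Lmat, v) {
  lr <- Lmat$lowrank
  if (is.null(lr)) return(drop(crossprod(Lmat$L, v)))
  out <- numeric(Lmat$m)
  out[lr$perm] <- drop(crossprod(lr$R, crossprod(lr$Q, v)))
  out
}
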