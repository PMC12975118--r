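#' @name ssn
#' @title Semismooth Newton solver for the augmented Lagrangian subproblem
#'
#' @description
#' Each outer iteration of the augmented Lagrangian method (ALM) minimizes,
#' over the dual variable `v`, the continuously differentiable reduction
#'
#' \deqn{\phi(v) = (\sigma/2) || max((1/n) L'v - 1_m + x/\sigma, 0) ||^2
#'                + M_h^\sigma(v - y/\sigma),}
#'
#' where `h(u) = -(1/n) sum log u_i` and `M_h^sigma` is its Moreau envelope.
#' The proximal map of `h` has the closed form
#' `p_i = (w_i + sqrt(w_i^2 + 4/(sigma n)))/2`, so phi, its gradient, and a
#' generalized Hessian are all available explicitly.  The gradient is
#' piecewise smooth (semismooth), and the Clarke generalized Hessian
#' `sigma [ (1/n^2) L_J L_J' + D ]` involves only the columns J of L where
#' the max is active — the second-order sparsity that makes a Newton step
#' cheap via the Sherman-Morrison-Woodbury identity.
#'
#' All functions below use the convention that the full sigma factor is
#' folded into both the gradient and the Hessian.
NULL

#' Fixed data of one ALM subproblem
#'
#' Bundles the likelihood matrix with the current multipliers `x`, `y` and
#' penalty `sigma` that define the subproblem objective phi.
#'
#' @param Lmat a [likelihood_matrix].
#' @param x,y current multiplier estimates.
#' @param sigma positive penalty parameter.
#' @return an object of class `subproblem_context`.
#' @export
subproblem_context <- function(Lmat, x, y, sigma) {
  stopifnot(inherits(Lmat, "likelihood_matrix"), sigma > 0, all(x >= 0))
  structure(list(Lmat = Lmat, x = x, y = y, sigma = sigma,
                 n = Lmat$n, m = Lmat$m),
            class = "subproblem_context")
}

#' Proximal map of the negative mean-log barrier
#'
#' Closed-form minimizer of `-(1/n) sum log p_i + (sigma/2) ||p - w||^2`:
#' `p_i = (w_i + sqrt(w_i^2 + 4/(sigma n)))/2 > 0`.  Evaluated in a
#' cancellation-free form for large negative `w_i`.
#'
#' @param w numeric vector.
#' @param sigma positive penalty parameter.
#' @param n number of observations (the barrier is scaled by 1/n).
#' @return positive vector of the same length as `w`.
#' @export
prox_h <- function(w, sigma, n) {
  a <- 4 / (sigma * n)
  s <- sqrt(w^2 + a)
  ifelse(w > 0, (w + s) / 2, a / (2 * (s - w)))
}

#' Diagonal of the Jacobian of [prox_h]
#'
#' Entries `(1 + w_i / sqrt(w_i^2 + 4/(sigma n)))/2`, strictly in (0, 1);
#' computed as `p_i / s_i` which is stable for both signs of `w_i`.
#'
#' @inheritParams prox_h
#' @return vector with entries in (0, 1).
#' @export
prox_h_jacobian_diag <- function(w, sigma, n) {
  a <- 4 / (sigma * n)
  s <- sqrt(w^2 + a)
  prox_h(w, sigma, n) / s
}

# 1 - jacobian = a / (4 p s), strictly positive; avoids the catastrophic
# cancellation of 1 - w/s for large positive w
prox_h_complement_diag <- function(w, sigma, n) {
  a <- 4 / (sigma * n)
  s <- sqrt(w^2 + a)
  p <- ifelse(w > 0, (w + s) / 2, a / (2 * (s - w)))
  a / (4 * p * s)
}

#' Moreau envelope of the negative mean-log barrier
#'
#' `M_h^sigma(w) = h(p) + (sigma/2) ||p - w||^2` at `p = prox_h(w)`, with
#' `h(p) = -(1/n) sum log p_i`.  The residual `p - w` is computed as
#' `1/(sigma n p)` (exact algebraic identity), which is stable for large
#' `|w|`.
#'
#' @inheritParams prox_h
#' @return scalar envelope value.
#' @export
moreau_envelope_h <- function(w, sigma, n) {
  p <- prox_h(w, sigma, n)
  r <- 1 / (sigma * n * p)             # p - w, via sigma (p - w) = 1/(n p)
  -sum(log(p)) / n + 0.5 * sigma * sum(r^2)
}

#' Subproblem objective phi
#'
#' @param v dual iterate (length n).
#' @param ctx subproblem context from the ALM (fixed `x`, `y`, `sigma`).
#' @param ztilde optional precomputed `(1/n) L'v` to skip the matrix-vector
#'   product (used by the line search).
#' @return scalar value of phi (the constant `-(||x||^2 + ||y||^2)/(2 sigma)`
#'   is excluded).
#' @export
phi_obj <- function(v, ctx, ztilde = NULL) {
  if (is.null(ztilde)) ztilde <- lik_tmv(ctx$Lmat, v) / ctx$n
  zp <- pmax(ztilde - 1 + ctx$x / ctx$sigma, 0)
  0.5 * ctx$sigma * sum(zp^2) +
    moreau_envelope_h(v - ctx$y / ctx$sigma, ctx$sigma, ctx$n)
}

#' Gradient of phi
#'
#' `(sigma/n) L max((1/n) L'v - 1 + x/sigma, 0) + sigma (w - prox_h(w))`
#' with `w = v - y/sigma`; the envelope part uses the identity
#' `sigma (w - p) = -1/(n p)`.
#'
#' @inheritParams phi_obj
#' @return length-n gradient vector.
#' @export
grad_phi <- function(v, ctx, ztilde = NULL) {
  if (is.null(ztilde)) ztilde <- lik_tmv(ctx$Lmat, v) / ctx$n
  zp <- pmax(ztilde - 1 + ctx$x / ctx$sigma, 0)
  w <- v - ctx$y / ctx$sigma
  p <- prox_h(w, ctx$sigma, ctx$n)
  (ctx$sigma / ctx$n) * lik_mv(ctx$Lmat, zp) - 1 / (ctx$n * p)
}

#' Active set and diagonal of the generalized Hessian
#'
#' The Clarke generalized Jacobian of `max(., 0)` at 0 is the interval
#' [0, 1]; following the sparsest-element rule, entries with `z_j = 0` are
#' treated as inactive.  Returns the index set `J = {j : z_j > 0}`, its size
#' `s`, the sigma-scaled positive diagonal
#' `D_full = sigma (I - Jac prox_h)` evaluated at `v - y/sigma`, and the
#' linear-system mode (`"smw"` when `s < n`, else dense).
#'
#' @inheritParams phi_obj
#' @return a list with fields `J`, `s`, `D_full`, `solve_mode`.
#' @export
active_set <- function(v, ctx, ztilde = NULL) {
  if (is.null(ztilde)) ztilde <- lik_tmv(ctx$Lmat, v) / ctx$n
  z <- ztilde - 1 + ctx$x / ctx$sigma
  J <- which(z > 0)
  D_full <- ctx$sigma *
    prox_h_complement_diag(v - ctx$y / ctx$sigma, ctx$sigma, ctx$n)
  s <- length(J)
  structure(list(J = J, s = s, D_full = D_full,
                 solve_mode = if (s < ctx$n) "smw" else "dense_n"),
            class = "newton_system")
}

#' Inexact semismooth Newton direction
#'
#' Solves `[sigma (1/n^2) L_J L_J' + D_full] d = rhs`.  In `"smw"` mode the
#' Sherman-Morrison-Woodbury identity reduces this to one s x s symmetric
#' positive definite solve with `Ltil = (sqrt(sigma)/n) L_J`; in `"dense_n"`
#' mode the n x n matrix is factored directly.  A numerically singular
#' factorization is retried once with a `1e-12 * trace/n` jitter.
#'
#' @param sys output of [active_set()].
#' @param ctx subproblem context.
#' @param rhs right-hand side (usually `-grad_phi(v, ctx)`).
#' @return list with `d` (the direction) and `residual`
#'   (`||H d - rhs||_2`, machine-level for the direct solves).
#' @export
newton_direction <- function(sys, ctx, rhs) {
  Dinv_rhs <- rhs / sys$D_full
  if (sys$s == 0L) {
    return(list(d = Dinv_rhs, residual = 0))
  }
  Ltil <- (sqrt(ctx$sigma) / ctx$n) * ctx$Lmat$L[, sys$J, drop = FALSE]
  if (sys$solve_mode == "smw") {
    M <- crossprod(Ltil, Ltil / sys$D_full)
    diag(M) <- diag(M) + 1
    cf <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cf)) {
      diag(M) <- diag(M) + 1e-12 * sum(diag(M)) / nrow(M)
      cf <- chol(M)                     # second failure propagates
    }
    t1 <- crossprod(Ltil, Dinv_rhs)
    d <- Dinv_rhs - (Ltil %*% backsolve(cf, backsolve(cf, t1, transpose = TRUE))) / sys$D_full
    d <- drop(d)
  } else {
    H <- tcrossprod(Ltil)
    diag(H) <- diag(H) + sys$D_full
    cf <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(cf)) {
      diag(H) <- diag(H) + 1e-12 * sum(diag(H)) / nrow(H)
      cf <- chol(H)
    }
    d <- drop(backsolve(cf, backsolve(cf, rhs, transpose = TRUE)))
  }
  Hd <- sys$D_full * d + Ltil %*% crossprod(Ltil, d)
  list(d = d, residual = sqrt(sum((Hd - rhs)^2)))
}

#' Armijo backtracking line search on phi
#'
#' Largest step in `{1, beta, beta^2, ...}` satisfying
#' `phi(v + a d) <= phi(v) + mu a <grad, d>`, capped at 50 backtracks.
#' The trial objective reuses `L'd` so each trial costs O(n + m), not
#' O(n m).
#'
#' @param v current iterate; `d` search direction (descent).
#' @param d search direction.
#' @param ctx subproblem context.
#' @param mu Armijo slope parameter in (0, 1/2).
#' @param beta backtracking factor in (0, 1).
#' @param g gradient at `v` (recomputed if missing).
#' @param ztilde,ztilde_d optional cached `(1/n) L'v` and `(1/n) L'd`.
#' @return list with `alpha`, the accepted `phi` value, the trial count,
#'   and the updated `ztilde` at the accepted point.
#' @export
line_search <- function(v, d, ctx, mu = 1e-4, beta = 0.5, g = NULL,
                        ztilde = NULL, ztilde_d = NULL) {
  if (is.null(ztilde)) ztilde <- lik_tmv(ctx$Lmat, v) / ctx$n
  if (is.null(ztilde_d)) ztilde_d <- lik_tmv(ctx$Lmat, d) / ctx$n
  if (is.null(g)) g <- grad_phi(v, ctx, ztilde = ztilde)
  slope <- sum(g * d)
  if (slope >= 0) {                     # engineering guard; H > 0 in theory
    warning("non-descent Newton direction; falling back to steepest descent")
    d <- -g
    ztilde_d <- lik_tmv(ctx$Lmat, d) / ctx$n
    slope <- -sum(g^2)
  }
  f0 <- phi_obj(v, ctx, ztilde = ztilde)
  alpha <- 1
  for (trial in 0:50) {
    zt <- ztilde + alpha * ztilde_d
    f <- phi_obj(v + alpha * d, ctx, ztilde = zt)
    if (f <= f0 + mu * alpha * slope) {
      return(list(alpha = alpha, phi = f, trials = trial, ztilde = zt,
                  d = d, converged = TRUE))
    }
    alpha <- alpha * beta
  }
  warning("line search exhausted 50 backtracks; returning last step")
  list(alpha = alpha, phi = f, trials = 51L, ztilde = zt, d = d,
       converged = FALSE)
}

#' Solve one ALM subproblem by semismooth Newton iteration
#'
#' Iterates `v <- v + alpha d` with inexact generalized-Newton directions
#' (accepted when `||H d + grad||| <= min(eta_bar, ||grad||^{1+tau})`) and
#' Armijo line search, until `||grad phi(v)|| <= eps` or `max_inner` steps.
#' Returns `u = prox_h(v - y/sigma)` alongside `v`.
#'
#' @param ctx subproblem context built from the current ALM state.
#' @param eps gradient-norm stopping tolerance.
#' @param config a [solver_config].
#' @param v0 starting point (warm-started by the ALM).
#' @return list with `u`, `v`, `iterations`, `converged`, `ztilde`
#'   (`(1/n) L'v` at the solution, reused by the multiplier update), and a
#'   per-iteration `diagnostics` data frame (gradient norm, active-set size,
#'   step size, backtracks).
#' @export
ssn_solve <- function(ctx, eps, config = solver_config(), v0 = NULL) {
  stopifnot(eps > 0)
  v <- if (is.null(v0)) numeric(ctx$n) else v0
  ztilde <- lik_tmv(ctx$Lmat, v) / ctx$n
  diag_rows <- vector("list", config$max_inner)
  t <- 0L
  repeat {
    g <- grad_phi(v, ctx, ztilde = ztilde)
    gnorm <- sqrt(sum(g^2))
    if (gnorm <= eps || t >= config$max_inner) break
    sys <- active_set(v, ctx, ztilde = ztilde)
    nd <- newton_direction(sys, ctx, -g)
    if (nd$residual > min(config$eta_bar, gnorm^(1 + config$tau))) {
      # direct factorizations should satisfy the test; refuse silently bad
      # directions and take a gradient step instead
      nd$d <- -g
    }
    ls <- line_search(v, nd$d, ctx, mu = config$mu, beta = config$beta,
                      g = g, ztilde = ztilde)
    v <- v + ls$alpha * ls$d
    ztilde <- ls$ztilde
    t <- t + 1L
    diag_rows[[t]] <- c(gnorm = gnorm, s = sys$s, alpha = ls$alpha,
                        backtracks = ls$trials)
  }
  u <- prox_h(v - ctx$y / ctx$sigma, ctx$sigma, ctx$n)
  diagnostics <- if (t > 0L) {
    as.data.frame(do.call(rbind, diag_rows[seq_len(t)]))
  } else {
    data.frame(gnorm = numeric(), s = numeric(), alpha = numeric(),
               backtracks = numeric())
  }
  list(u = u, v = v, iterations = t, converged = gnorm <= eps,
       gnorm = gnorm, ztilde = ztilde, diagnostics = diagnostics)
}
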