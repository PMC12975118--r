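#' @name baseline-oracles
#' @title Independent baseline solvers for the mixture-weight problem
#'
#' @description
#' Three deliberately simple solvers for the same finite NPMLE problem used
#' to certify the augmented Lagrangian solver: the classical EM fixed point,
#' projected gradient with exact simplex projection, and exhaustive simplex
#' search for m <= 3.  They share no code with the ALM path.
NULL

#' @rdname baseline-oracles
#' @param Lmat a [likelihood_matrix].
#' @param max_iter iteration cap.
#' @param tol max-abs change stopping tolerance on the weights.
#' @return list with `weights` (simplex vector), `objective` (negative mean
#'   log-likelihood via [negative_loglik]), `iterations`.
#' @export
em_solve <- function(Lmat, max_iter = 10000L, tol = 1e-10) {
  stopifnot(inherits(Lmat, "likelihood_matrix"))
  n <- Lmat$n; m <- Lmat$m
  x <- rep(1 / m, m)
  it <- 0L
  for (it in seq_len(max_iter)) {
    r <- 1 / drop(Lmat$L %*% x)
    x_new <- x * drop(crossprod(Lmat$L, r)) / n
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta <= tol) break
  }
  list(weights = x / sum(x), objective = negative_loglik(Lmat, x),
       iterations = it)
}

#' Euclidean projection onto the probability simplex
#'
#' Standard sorting-based algorithm (O(m log m)).
#'
#' @param z numeric vector.
#' @return the closest point on the simplex to `z`.
#' @export
simplex_project <- function(z) {
  m <- length(z)
  s <- sort(z, decreasing = TRUE)
  css <- cumsum(s)
  rho <- max(which(s - (css - 1) / seq_len(m) > 0))
  lambda <- (css[rho] - 1) / rho
  pmax(z - lambda, 0)
}

#' @rdname baseline-oracles
#' @export
projected_gradient_solve <- function(Lmat, max_iter = 5000L, tol = 1e-10) {
  stopifnot(inherits(Lmat, "likelihood_matrix"))
  n <- Lmat$n; m <- Lmat$m
  x <- rep(1 / m, m)
  f <- negative_loglik(Lmat, x)
  step <- 1
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- -drop(crossprod(Lmat$L, 1 / drop(Lmat$L %*% x))) / n
    # backtracking on the projected step
    accepted <- FALSE
    for (bt in 1:60) {
      x_new <- simplex_project(x - step * g)
      lx <- drop(Lmat$L %*% x_new)
      if (all(lx > 0)) {
        f_new <- -(sum(log(lx)) + sum(Lmat$row_log_scale)) / n
        if (f_new <= f - 1e-4 * sum(g * (x - x_new)) + 1e-15) {
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) break
    delta <- max(abs(x_new - x))
    x <- x_new; f <- f_new
    step <- min(step * 2, 1e6)
    if (delta <= tol) break
  }
  list(weights = x, objective = negative_loglik(Lmat, x), iterations = it)
}

#' @rdname baseline-oracles
#' @param step lattice spacing of the exhaustive search (refined once at
#'   `step/100` around the best lattice point).
#' @export
brute_force_simplex <- function(Lmat, step = 1e-3) {
  stopifnot(inherits(Lmat, "likelihood_matrix"))
  m <- Lmat$m
  if (m > 3L) stop("brute force search supports m <= 3 only")
  # boundary lattice points can make some mixture density zero; +Inf is a
  # legitimate value during exhaustive search, so the warning is silenced
  obj <- function(x) suppressWarnings(negative_loglik(Lmat, x))
  if (m == 1L)
    return(list(weights = 1, objective = obj(1), iterations = 1L))
  eval_lattice <- function(center, h, half_width) {
    lo <- pmax(center - half_width, 0)
    hi <- pmin(center + half_width, 1)
    g1 <- seq(lo[1], hi[1], by = h)
    best <- NULL; best_f <- Inf
    if (m == 2L) {
      for (x1 in g1) {
        f <- obj(c(x1, 1 - x1))
        if (f < best_f) { best_f <- f; best <- c(x1, 1 - x1) }
      }
    } else {
      g2 <- seq(lo[2], hi[2], by = h)
      for (x1 in g1) for (x2 in g2) {
        x3 <- 1 - x1 - x2
        if (x3 < -1e-12) next
        f <- obj(c(x1, x2, max(x3, 0)))
        if (f < best_f) { best_f <- f; best <- c(x1, x2, max(x3, 0)) }
      }
    }
    list(x = best, f = best_f)
  }
  coarse <- eval_lattice(rep(0.5, m), step, rep(0.5, m))
  fine <- eval_lattice(coarse$x, step / 100, rep(step, m))
  x <- fine$x / sum(fine$x)
  list(weights = x, objective = obj(x),
       iterations = NA_integer_)
}
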