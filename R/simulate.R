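#' @name simulate-scenarios
#' @title Seeded synthetic-data generators
#'
#' @description
#' Pure functions of their parameters and a seed, reproducing the standard
#' simulation designs for Gaussian mixture deconvolution:
#'
#' * `gen_example1`: sparse-normal-means — exactly `tau` of the `n` latent
#'   means equal `nu`, the rest are 0, unit noise.  Signals are assigned by
#'   exact count (sampled without replacement), not Bernoulli draws, so a
#'   replication always carries the stated number of signals.
#' * `gen_example2`: 50% / 20% / 30% of the observations drawn from
#'   N(0,1), Student t4, and t6 — a Gaussian scale mixture target.  Counts
#'   are the rounded proportions with any remainder going to the first
#'   component.
#' * `gen_circles`: latent means uniform on two concentric circles
#'   (radii 2 and 6 by default, half the sample each), unit bivariate noise.
#' * `gen_generic`: latent means i.i.d. from an arbitrary discrete mixing
#'   distribution, Gaussian noise under any covariance specification.
#'
#' All generators record the true covariances in the returned
#' [mixture_data] and also return the latent means for evaluation.
NULL

#' @rdname simulate-scenarios
#' @param n sample size.
#' @param nu signal value.
#' @param tau number of signal coordinates, `0 <= tau <= n`.
#' @param seed integer seed.
#' @return `gen_example1`: list with `data` ([mixture_data], shared unit
#'   covariance) and `theta` (latent means).
#' @export
gen_example1 <- function(n, nu = 3, tau, seed = 1L) {
  stopifnot(n >= 1, tau >= 0, tau <= n)
  set.seed(seed)
  theta <- numeric(n)
  if (tau > 0) theta[sample.int(n, tau)] <- nu
  Y <- theta + rnorm(n)
  list(data = mixture_data(matrix(Y, ncol = 1L)), theta = theta)
}

#' @rdname simulate-scenarios
#' @return `gen_example2`: a [mixture_data] (d = 1) with a `component`
#'   attribute giving each draw's source (1 = normal, 2 = t4, 3 = t6).
#' @export
gen_example2 <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  n2 <- floor(0.2 * n); n3 <- floor(0.3 * n)
  n1 <- n - n2 - n3                      # remainder to the normal block
  y <- c(rnorm(n1), rt(n2, df = 4), rt(n3, df = 6))
  dat <- mixture_data(matrix(y, ncol = 1L))
  attr(dat, "component") <- rep(1:3, times = c(n1, n2, n3))
  dat
}

#' @rdname simulate-scenarios
#' @param radii two positive circle radii.
#' @return `gen_circles`: list with `data` ([mixture_data], d = 2, shared
#'   identity covariance) and `theta` (n x 2 latent means on the circles).
#' @export
gen_circles <- function(n, radii = c(2, 6), seed = 1L) {
  stopifnot(length(radii) == 2, all(radii > 0))
  if (n %% 2L != 0L) stop("n must be even (half the sample per circle)")
  set.seed(seed)
  half <- n %/% 2L
  ang <- runif(n, 0, 2 * pi)
  r <- rep(radii, each = half)
  theta <- cbind(r * cos(ang), r * sin(ang))
  Y <- theta + matrix(rnorm(2L * n), n, 2L)
  list(data = mixture_data(Y), theta = theta)
}

#' @rdname simulate-scenarios
#' @param G_star a [mixing_distribution]: the true prior.
#' @param covs,cov_mode covariance specification as in [mixture_data]
#'   (default shared identity).
#' @return `gen_generic`: list with `data` and `theta`.
#' @export
gen_generic <- function(n, G_star, covs = NULL,
                        cov_mode = c("shared", "diag", "full"), seed = 1L) {
  stopifnot(inherits(G_star, "mixing_distribution"), n >= 1)
  cov_mode <- match.arg(cov_mode)
  set.seed(seed)
  idx <- sample.int(G_star$m, n, replace = TRUE, prob = G_star$weights)
  theta <- G_star$support[idx, , drop = FALSE]
  d <- G_star$d
  dat0 <- mixture_data(matrix(0, n, d), covs, cov_mode)  # validates covs
  Z <- switch(dat0$cov_mode,
    shared = matrix(rnorm(n * d), n, d) %*% chol(dat0$covs),
    diag = matrix(rnorm(n * d), n, d) * sqrt(dat0$covs),
    full = t(vapply(seq_len(n), function(i) {
      drop(crossprod(chol(dat0$covs[[i]]), rnorm(d)))
    }, numeric(d))))
  if (d == 1L && !is.matrix(Z)) Z <- matrix(Z, ncol = 1L)
  list(data = mixture_data(theta + Z, dat0$covs, dat0$cov_mode),
       theta = theta)
}
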