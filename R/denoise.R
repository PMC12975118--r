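#' Empirical-Bayes posterior means under the fitted prior
#'
#' `theta_hat_i = sum_j w_ij mu_j` with posterior weights
#' `w_ij = L_ij x_j / sum_j' L_ij' x_j'`; the row scaling of L cancels in the
#' ratio.  Each estimate is a convex combination of the grid atoms.
#'
#' @param data a [mixture_data] (used only for dimension checks).
#' @param Lmat the [likelihood_matrix] built on the same grid as `G`.
#' @param G a [mixing_distribution] whose support is (a subset of) the grid
#'   that generated `Lmat`; weights off `G$support` are taken as zero.
#' @param support the full [support_set] matching the columns of `Lmat`.
#' @return n x d matrix of posterior means.
#' @export
posterior_mean <- function(data, Lmat, G, support) {
  stopifnot(inherits(Lmat, "likelihood_matrix"),
            inherits(G, "mixing_distribution"),
            inherits(support, "support_set"), support$m == Lmat$m)
  if (support$kind != "location")
    stop("posterior means are defined for location mixtures")
  x <- match_weights(G, support)
  num <- Lmat$L %*% (support$points * x)     # n x d
  den <- drop(Lmat$L %*% x)
  if (any(den <= 0))
    stop(sprintf("grid does not cover observation %d (zero posterior mass)",
                 which(den <= 0)[1L]))
  sweep(num, 1L, den, "/")
}

# place G's weights onto the full grid (rows of G$support must be grid rows)
match_weights <- function(G, support) {
  key_g <- apply(G$support, 1L, paste, collapse = "\r")
  key_s <- apply(support$points, 1L, paste, collapse = "\r")
  idx <- match(key_g, key_s)
  if (anyNA(idx))
    stop("mixing distribution atoms are not a subset of the support grid")
  x <- numeric(support$m)
  x[idx] <- G$weights
  x
}

#' Drop negligible atoms and renormalize
#'
#' @param G a [mixing_distribution].
#' @param threshold keep atoms with weight strictly greater than this
#'   (in [0, 1)).
#' @return pruned, renormalized [mixing_distribution].
#' @export
prune_support <- function(G, threshold = 1e-6) {
  stopifnot(inherits(G, "mixing_distribution"),
            threshold >= 0, threshold < 1)
  keep <- G$weights > threshold
  if (!any(keep))
    stop("pruning removed every atom; use a smaller threshold")
  w <- G$weights[keep]
  mixing_distribution(G$support[keep, , drop = FALSE], w / sum(w))
}

#' Exact optimal-transport plan between the data and the fitted prior
#'
#' Solves the discrete Kantorovich problem
#' `min sum_ij pi_ij ||Y_i - a_j||^2` subject to `pi 1 = 1_n/n`,
#' `pi' 1 = alpha`, `pi >= 0` — a transportation linear program — exactly,
#' by the network (transportation) simplex.  The optimal cost is the
#' squared 2-Wasserstein distance between the empirical law of the data and
#' the fitted mixing distribution.
#'
#' The barycentric-projection denoiser is defined through the exact plan;
#' no entropic smoothing is used.
#'
#' @param data a [mixture_data].
#' @param G a pruned [mixing_distribution] with at most `max_atoms` atoms.
#' @param max_atoms guard against accidentally passing an unpruned fit.
#' @return an object of class `transport_plan`: `pi` (n x k, dense), `atoms`
#'   (k x d), `atom_weights`, `cost`, and the LP dual potentials
#'   `potential_row`, `potential_col` certifying optimality.
#' @export
ot_plan <- function(data, G, max_atoms = 5000L) {
  stopifnot(inherits(data, "mixture_data"),
            inherits(G, "mixing_distribution"))
  if (data$d != G$d) stop("data and atoms differ in dimension")
  if (G$m > max_atoms)
    stop(sprintf("%d atoms exceed max_atoms = %d; prune the fit first",
                 G$m, max_atoms))
  if (abs(sum(G$weights) - 1) > 1e-8)
    stop("atom weights do not sum to 1; not a probability measure")
  if (data$cov_mode != "shared")
    message(paste("note: the optimal-transport denoising guarantee assumes",
                  "a shared noise covariance; proceeding anyway"))
  n <- data$n
  # presort observations and atoms along the dominant direction of the atom
  # cloud: the solver's north-west starting basis then nearly matches the
  # monotone coupling, which is exactly optimal in one dimension and a good
  # warm start otherwise
  A <- G$support
  w <- if (G$d == 1L) {
    1
  } else {
    Ac <- sweep(A, 2L, colMeans(A))
    eigen(crossprod(Ac), symmetric = TRUE)$vectors[, 1L]
  }
  ord_r <- order(drop(data$Y %*% w))
  ord_c <- order(drop(A %*% w))
  cost <- sq_dist(data$Y, A)
  res <- transport_simplex_cpp(cost[ord_r, ord_c, drop = FALSE],
                               rep(1 / n, n), G$weights[ord_c])
  if (res$status != 0L)
    stop("transportation simplex failed to reach an optimal basis")
  pi_mat <- matrix(0, n, G$m)
  pi_mat[ord_r, ord_c] <- res$plan
  u <- numeric(n); u[ord_r] <- res$u
  vv <- numeric(G$m); vv[ord_c] <- res$v
  structure(list(pi = pi_mat, atoms = G$support, atom_weights = G$weights,
                 cost = sum(pi_mat * cost),
                 potential_row = u, potential_col = vv,
                 n = n, k = G$m),
            class = "transport_plan")
}

sq_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf(paste0("transport_plan: %d observations -> %d atoms, ",
                     "W2^2 cost %.6f, %d nonzeros\n"),
              x$n, x$k, x$cost, sum(x$pi > 0)))
  invisible(x)
}

#' Barycentric projection of a transport plan
#'
#' `T(Y_i) = n sum_j pi_ij a_j`: since each plan row carries mass `1/n`,
#' this is the conditional mean of the atom given `Y_i`.  When a row has a
#' single nonzero entry (most rows, as the plan is a tree solution) the
#' output is exactly an atom.
#'
#' @param plan a [transport_plan].
#' @return n x d matrix of denoised estimates.
#' @export
barycentric_projection <- function(plan) {
  stopifnot(inherits(plan, "transport_plan"))
  plan$n * (plan$pi %*% plan$atoms)
}

#' Denoise observations under a fitted mixing distribution
#'
#' Dispatches to the empirical-Bayes posterior mean and/or the
#' optimal-transport barycentric projection.
#'
#' @param data a [mixture_data].
#' @param Lmat the [likelihood_matrix] of the fit (needed for `"eb"`).
#' @param G the fitted, pruned [mixing_distribution].
#' @param support the [support_set] matching `Lmat` (needed for `"eb"`).
#' @param method `"eb"`, `"ot"`, or `"both"`.
#' @return list with elements `eb` and/or `ot` (n x d matrices), plus
#'   `ot_cost` and `plan` when transport was run.
#' @export
denoise <- function(data, Lmat = NULL, G, support = NULL,
                    method = c("both", "eb", "ot")) {
  method <- match.arg(method)
  out <- list()
  if (method %in% c("eb", "both")) {
    if (is.null(Lmat) || is.null(support))
      stop("empirical-Bayes denoising needs the likelihood matrix and grid")
    out$eb <- posterior_mean(data, Lmat, G, support)
  }
  if (method %in% c("ot", "both")) {
    plan <- ot_plan(data, G)
    out$ot <- barycentric_projection(plan)
    out$ot_cost <- plan$cost
    out$plan <- plan
  }
  out
}
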