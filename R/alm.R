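#' Solver configuration for the augmented Lagrangian method
#'
#' @param sigma0 initial penalty parameter (> 0).
#' @param sigma_growth multiplicative penalty growth factor (>= 1), applied
#'   when the KKT residual fails to halve between outer iterations.
#' @param sigma_max penalty cap.
#' @param tol outer KKT-residual tolerance.
#' @param max_outer maximum outer (multiplier) iterations.
#' @param inner_tol0 first inner gradient-norm tolerance; iteration k uses
#'   `max(inner_tol0 * inner_decay^k, 0.1 * tol)`, a summable schedule.
#' @param inner_decay geometric decay of the inner tolerance, in (0, 1).
#' @param eta_bar,tau inexactness parameters of the Newton direction test
#'   `||H d + g|| <= min(eta_bar, ||g||^{1+tau})`; `eta_bar` in (0,1),
#'   `tau` in (0,1].
#' @param mu Armijo slope parameter, in (0, 1/2).
#' @param beta backtracking factor, in (0, 1).
#' @param max_inner maximum semismooth Newton iterations per subproblem.
#' @param prune_tol reporting threshold: atoms with final weight below this
#'   are dropped from the returned mixing distribution.
#' @param seed optional integer seed recorded with the fit.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(sigma0 = 1, sigma_growth = 3, sigma_max = 1e8,
                          tol = 1e-6, max_outer = 100L,
                          inner_tol0 = 1e-3, inner_decay = 0.5,
                          eta_bar = 0.1, tau = 0.5, mu = 1e-4, beta = 0.5,
                          max_inner = 50L, prune_tol = 1e-6, seed = NULL) {
  stopifnot(sigma0 > 0, sigma_growth >= 1, sigma_max > 0, tol > 0,
            max_outer >= 1, inner_tol0 > 0,
            inner_decay > 0, inner_decay < 1,
            eta_bar > 0, eta_bar < 1, tau > 0, tau <= 1,
            mu > 0, mu < 0.5, beta > 0, beta < 1, max_inner >= 1,
            prune_tol >= 0, prune_tol < 1)
  structure(list(sigma0 = sigma0, sigma_growth = sigma_growth,
                 sigma_max = sigma_max, tol = tol,
                 max_outer = as.integer(max_outer),
                 inner_tol0 = inner_tol0, inner_decay = inner_decay,
                 eta_bar = eta_bar, tau = tau, mu = mu, beta = beta,
                 max_inner = as.integer(max_inner), prune_tol = prune_tol,
                 seed = seed),
            class = "solver_config")
}

#' Negative mean log-likelihood of mixing weights
#'
#' `l(x) = -(1/n) sum_i [ log((L x)_i) + row_log_scale_i ]`, i.e. the
#' objective of the finite NPMLE problem evaluated in the row-scaled
#' convention with the scaling constants added back.
#'
#' @param Lmat a [likelihood_matrix].
#' @param x nonnegative weight vector of length m.
#' @return scalar; `+Inf` with a warning if some `(L x)_i = 0` (the weights
#'   put no mass near observation i).
#' @export
negative_loglik <- function(Lmat, x) {
  stopifnot(inherits(Lmat, "likelihood_matrix"), length(x) == Lmat$m,
            all(x >= 0))
  lx <- drop(Lmat$L %*% x)
  if (any(lx <= 0)) {
    warning(sprintf("zero mixture density at observation %d; returning +Inf",
                    which(lx <= 0)[1L]))
    return(Inf)
  }
  -(sum(log(lx)) + sum(Lmat$row_log_scale)) / Lmat$n
}

#' Initial ALM state
#'
#' Uniform weights `x0 = 1/m`, `y0 = L x0`, and `u0 = v0 = 1/y0` so that the
#' complementarity relation `u o y = 1` holds exactly at the start.
#'
#' The stored `y` is kept on the primal scale (`y = L x` at optimality, so
#' `u o y = 1` as in the KKT system).  The multiplier associated with the
#' 1/n-scaled equality constraint of the primal reformulation — the quantity
#' the augmented Lagrangian recursion actually updates — is `y / n`; the
#' conversion happens inside [alm_fit()] and [update_multipliers()].
#'
#' @param Lmat a [likelihood_matrix].
#' @param config a [solver_config].
#' @return an object of class `alm_state`.
#' @export
initialize_state <- function(Lmat, config = solver_config()) {
  x <- rep(1 / Lmat$m, Lmat$m)
  y <- drop(Lmat$L %*% x)
  u <- 1 / y
  structure(list(x = x, y = y, u = u, v = u, sigma = config$sigma0,
                 outer_iter = 0L),
            class = "alm_state")
}

#' Multiplier update of the augmented Lagrangian method
#'
#' After an inner solve at penalty `sigma` returning `(u_new, v_new)`:
#' `x <- max((sigma/n) L'v_new - sigma 1_m + x, 0)` and
#' `y <- y + n sigma (u_new - v_new)`; the dual pair is stored as-is.
#' (The factor n reflects that the stored `y` is n times the multiplier of
#' the 1/n-scaled equality constraint; see [initialize_state()].)
#'
#' Because `u_new` is the proximal point of `v_new - y/(n sigma)`, its
#' stationarity identity `sigma (u - w) = 1/(n u)` makes the y-update
#' algebraically identical to `y <- 1/u_new`, which is how it is computed:
#' the difference form multiplies an O(1/sigma) difference by sigma and is
#' destroyed by roundoff once sigma is large.
#'
#' @param state current `alm_state`.
#' @param Lmat a [likelihood_matrix].
#' @param u_new,v_new inner-solve output.
#' @param ztilde optional precomputed `(1/n) L'v_new`.
#' @return updated `alm_state`.
#' @export
update_multipliers <- function(state, Lmat, u_new, v_new, ztilde = NULL) {
  if (is.null(ztilde)) ztilde <- drop(crossprod(Lmat$L, v_new)) / Lmat$n
  state$x <- pmax(state$sigma * ztilde - state$sigma + state$x, 0)
  state$y <- 1 / u_new          # = y + n sigma (u_new - v_new), exactly
  state$u <- u_new
  state$v <- v_new
  state$outer_iter <- state$outer_iter + 1L
  state
}

#' Normalized KKT residual report
#'
#' Five scale-insensitive components, each zero exactly at a KKT point of
#' the primal-dual pair in the row-scaled likelihood convention:
#' primal feasibility `||Lx - y|| / (1 + ||y||)`; dual feasibility
#' `||max((1/n) L'v - 1, 0)|| / (1 + sqrt(m))`; complementarity
#' `|x'(1 - (1/n) L'v)| / (1 + ||x||_1)`; the barrier relation
#' `||u o y - 1|| / (1 + sqrt(n))`; and dual consistency
#' `||u - v|| / (1 + ||u||)`.  `eta_max` is their maximum.
#'
#' @param state an `alm_state` (requires `u > 0`).
#' @param Lmat a [likelihood_matrix].
#' @param ztilde optional precomputed `(1/n) L'v`.
#' @param lx optional precomputed `L x`.
#' @return an object of class `kkt_report` (the five components, `eta_max`,
#'   and the primal objective [negative_loglik]).
#' @export
kkt_residual <- function(state, Lmat, ztilde = NULL, lx = NULL) {
  n <- Lmat$n; m <- Lmat$m
  if (is.null(ztilde)) ztilde <- drop(crossprod(Lmat$L, state$v)) / n
  if (is.null(lx)) lx <- drop(Lmat$L %*% state$x)
  eta_primal <- sqrt(sum((lx - state$y)^2)) / (1 + sqrt(sum(state$y^2)))
  viol <- pmax(ztilde - 1, 0)
  eta_dual <- sqrt(sum(viol^2)) / (1 + sqrt(m))
  eta_comp <- abs(sum(state$x * (1 - ztilde))) / (1 + sum(abs(state$x)))
  eta_uy <- sqrt(sum((state$u * state$y - 1)^2)) / (1 + sqrt(n))
  eta_uv <- sqrt(sum((state$u - state$v)^2)) / (1 + sqrt(sum(state$u^2)))
  obj <- if (all(lx > 0)) {
    -(sum(log(lx)) + sum(Lmat$row_log_scale)) / n
  } else {
    Inf
  }
  comps <- c(eta_primal = eta_primal, eta_dual = eta_dual,
             eta_comp = eta_comp, eta_uy = eta_uy, eta_uv = eta_uv)
  structure(list(eta_primal = eta_primal, eta_dual = eta_dual,
                 eta_comp = eta_comp, eta_uy = eta_uy, eta_uv = eta_uv,
                 eta_max = max(comps), objective = obj),
            class = "kkt_report")
}

#' @export
print.kkt_report <- function(x, ...) {
  cat(sprintf(paste0("kkt_report: eta_max %.3e (primal %.2e, dual %.2e, ",
                     "comp %.2e, uy %.2e, uv %.2e), objective %.8f\n"),
              x$eta_max, x$eta_primal, x$eta_dual, x$eta_comp, x$eta_uy,
              x$eta_uv, x$objective))
  invisible(x)
}

#' Penalty schedule
#'
#' Keeps `sigma` when the aggregate KKT residual at least halved since the
#' previous outer iteration, otherwise grows it by `sigma_growth`, capped at
#' `sigma_max`.  Never decreases.
#'
#' @param state current `alm_state`.
#' @param report,prev_report current and previous [kkt_residual] reports
#'   (`prev_report` may be `NULL` on the first iteration).
#' @param config a [solver_config].
#' @return the next penalty value.
#' @export
sigma_schedule <- function(state, report, prev_report, config) {
  fast <- !is.null(prev_report) && report$eta_max <= 0.5 * prev_report$eta_max
  if (fast) state$sigma
  else min(config$sigma_growth * state$sigma, config$sigma_max)
}

#' Fit the discretized NPMLE by the dual augmented Lagrangian method
#'
#' Outer loop: warm-started semismooth Newton solve of the subproblem at a
#' geometrically tightening gradient tolerance, multiplier update, KKT
#' residual check, penalty schedule.  Terminates when `eta_max <= tol` or at
#' `max_outer` (then returns the final iterate with `converged = FALSE` and
#' a warning, never an error).  On exit the weights are renormalized onto
#' the simplex — at an optimum they already sum to one, a property the
#' report records — and thresholded into a [mixing_distribution].
#'
#' @param Lmat a [likelihood_matrix].
#' @param support the [support_set] the columns of `Lmat` correspond to.
#' @param config a [solver_config].
#' @param verbose print one line per outer iteration.
#' @return an object of class `npmle_fit`: fields `G` (pruned
#'   [mixing_distribution]), `weights_raw` (all m weights before pruning,
#'   renormalized), `sum_x_final` (`1'x` before renormalization), `state`,
#'   `kkt` ([kkt_residual] report), `objective`, `converged`, and `log`
#'   (per-outer-iteration data frame).
#' @export
alm_fit <- function(Lmat, support, config = solver_config(),
                    verbose = FALSE) {
  stopifnot(inherits(Lmat, "likelihood_matrix"),
            inherits(support, "support_set"), support$m == Lmat$m)
  if (Lmat$m == 1L) stop("m = 1 is degenerate: the solution is x = 1")
  state <- initialize_state(Lmat, config)
  report <- NULL
  log_rows <- vector("list", config$max_outer)
  for (k in seq_len(config$max_outer)) {
    eps_k <- max(config$inner_tol0 * config$inner_decay^(k - 1L),
                 0.1 * config$tol)
    ctx <- subproblem_context(Lmat, state$x, state$y / Lmat$n, state$sigma)
    inner <- ssn_solve(ctx, eps_k, config,
                       v0 = if (k == 1L) NULL else state$v)
    prev_report <- report
    sigma_k <- state$sigma
    state <- update_multipliers(state, Lmat, inner$u, inner$v,
                                ztilde = inner$ztilde)
    report <- kkt_residual(state, Lmat, ztilde = inner$ztilde)
    log_rows[[k]] <- data.frame(
      k = k, sigma = sigma_k, inner_iterations = inner$iterations,
      line_search_steps = sum(inner$diagnostics$backtracks),
      inner_gnorm = inner$gnorm, eta_max = report$eta_max,
      objective = report$objective)
    if (verbose)
      message(sprintf(
        "outer %3d  sigma %9.3e  inner %3d  obj %.8f  kkt %.3e",
        k, sigma_k, inner$iterations, report$objective, report$eta_max))
    if (report$eta_max <= config$tol) break
    state$sigma <- sigma_schedule(state, report, prev_report, config)
  }
  converged <- report$eta_max <= config$tol
  if (!converged)
    warning(sprintf("ALM stopped at max_outer = %d with KKT residual %.3e",
                    config$max_outer, report$eta_max))
  sum_x <- sum(state$x)
  weights <- state$x / sum_x
  G <- prune_support(
    mixing_distribution(support$points, weights, normalized = FALSE),
    threshold = config$prune_tol)
  structure(list(G = G, weights_raw = weights, sum_x_final = sum_x,
                 support = support, state = state, kkt = report,
                 objective = report$objective, converged = converged,
                 config = config,
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                       TRUE)])),
            class = "npmle_fit")
}

#' @export
print.npmle_fit <- function(x, ...) {
  cat(sprintf(paste0("npmle_fit: %d support atoms above %.0e (of %d grid ",
                     "points)\n  negative log-likelihood %.8f, KKT residual ",
                     "%.3e, %s after %d outer iterations\n"),
              x$G$m, x$config$prune_tol, length(x$weights_raw),
              x$objective, x$kkt$eta_max,
              if (x$converged) "converged" else "NOT converged",
              nrow(x$log)))
  invisible(x)
}

#' One-call NPMLE fit from data
#'
#' Convenience wrapper: builds the grid (equally spaced for d = 1, box grid
#' for d >= 2, geometric variance grid for scale mixtures), the row-scaled
#' likelihood matrix, and runs [alm_fit()].
#'
#' @param data a [mixture_data].
#' @param m grid size for d = 1 (location or scale kind).
#' @param per_dim per-coordinate grid size for d >= 2.
#' @param mixture `"location"` or `"scale"`.
#' @param grid optional explicit [support_set] overriding the constructions.
#' @param config a [solver_config].
#' @param lowrank if `TRUE`, attach a truncated QR factorization of L
#'   (d = 1 only) to accelerate gradient products.
#' @param verbose print outer-iteration progress.
#' @return an `npmle_fit` (with the likelihood matrix in `$Lmat`).
#' @export
npmle <- function(data, m = 300L, per_dim = 40L,
                  mixture = c("location", "scale"), grid = NULL,
                  config = solver_config(), lowrank = FALSE,
                  verbose = FALSE) {
  mixture <- match.arg(mixture)
  if (is.null(grid)) {
    grid <- if (mixture == "scale") build_scale_grid(data, m)
    else if (data$d == 1L) build_grid_1d(data, m)
    else build_grid_box(data, per_dim)
  }
  Lmat <- likelihood_matrix(data, grid)
  if (lowrank && data$d == 1L) Lmat <- lowrank_factorize(Lmat)
  fit <- alm_fit(Lmat, grid, config, verbose = verbose)
  fit$Lmat <- Lmat
  fit$data <- data
  fit
}
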