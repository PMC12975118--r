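test_that("prox_h closed form satisfies its stationarity identity", {
  expect_equal(prox_h(0, 1, 1), 1)            # solves -1/p + p = 0
  expect_equal(prox_h(0, 1, 4), 0.5)
  expect_equal(prox_h(10, 1, 1), (10 + sqrt(104)) / 2)
  # scalar-minimization oracle
  for (w in c(-3, 0.2, 10)) {
    p_opt <- optimize(function(p) -log(p) + 0.5 * (p - w)^2,
                      c(1e-8, 50), tol = 1e-12)$minimum
    expect_equal(prox_h(w, 1, 1), p_opt, tolerance = 1e-6)
  }
  set.seed(1)
  # moderate regime: the residual p - w is large enough that forming it by
  # subtraction is meaningful at 1e-10 relative (at extreme sigma*n the
  # subtraction itself, not the prox, loses digits)
  for (rep in 1:20) {
    n <- sample(1:50, 1)
    sigma <- 10^runif(1, -2, 1)
    w <- rnorm(n, sd = 3)
    p <- prox_h(w, sigma, n)
    expect_true(all(p > 0))
    # sigma (p - w) = 1/(n p), relative to the larger side
    lhs <- sigma * (p - w); rhs <- 1 / (n * p)
    expect_lt(max(abs(lhs - rhs) / pmax(abs(rhs), 1e-300)), 1e-10)
  }
  # extreme regime: positivity and finiteness never break down
  for (rep in 1:10) {
    n <- sample(1:1000, 1)
    sigma <- 10^runif(1, -4, 10)
    w <- rnorm(n, sd = 10^runif(1, -2, 6))
    p <- prox_h(w, sigma, n)
    expect_true(all(is.finite(p) & p > 0))
  }
})

test_that("prox jacobian diagonal: closed form, limits, finite differences", {
  expect_equal(prox_h_jacobian_diag(0, 3, 7), 0.5)   # symmetry at 0
  expect_gt(prox_h_jacobian_diag(1e8, 1, 1), 1 - 1e-10)
  expect_lt(prox_h_jacobian_diag(-1e8, 1, 1), 1e-10)
  set.seed(2)
  w <- rnorm(30, sd = 3); sigma <- 0.7; n <- 30
  jd <- prox_h_jacobian_diag(w, sigma, n)
  expect_true(all(jd > 0 & jd < 1))
  h <- 1e-6
  fd <- (prox_h(w + h, sigma, n) - prox_h(w - h, sigma, n)) / (2 * h)
  expect_equal(jd, fd, tolerance = 1e-6)
  # complement is computed without cancellation and matches 1 - jacobian
  expect_equal(almix:::prox_h_complement_diag(w, sigma, n), 1 - jd,
               tolerance = 1e-12)
})

test_that("Moreau envelope: value, minimality, gradient identity", {
  expect_equal(moreau_envelope_h(0, 1, 1), 0.5)   # p = 1, h = 0, 0.5*1
  set.seed(3)
  n <- 12; sigma <- 2.5
  w <- rnorm(n)
  env <- moreau_envelope_h(w, sigma, n)
  for (rep in 1:10) {
    z <- exp(rnorm(n))
    expect_lte(env, -sum(log(z)) / n + sigma / 2 * sum((z - w)^2) + 1e-12)
  }
  # smoothness: finite-difference gradient equals sigma (w - prox(w))
  g_exact <- sigma * (w - prox_h(w, sigma, n))
  h <- 1e-6
  g_fd <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- h
    (moreau_envelope_h(w + e, sigma, n) -
       moreau_envelope_h(w - e, sigma, n)) / (2 * h)
  }, 0)
  expect_equal(g_exact, g_fd, tolerance = 1e-6)
})

test_that("phi: value composition, convexity, descent direction", {
  set.seed(4)
  Lm <- random_lik(6, 4)
  # x = 0, y = 0, v = 0: the max term vanishes, only the envelope remains
  ctx0 <- subproblem_context(Lm, numeric(4), numeric(6), 1.3)
  expect_equal(phi_obj(numeric(6), ctx0),
               moreau_envelope_h(numeric(6), 1.3, 6))
  ctx <- subproblem_context(Lm, rexp(4), rnorm(6), 2)
  for (rep in 1:10) {
    v1 <- rnorm(6); v2 <- rnorm(6)
    mid <- phi_obj((v1 + v2) / 2, ctx)
    expect_lte(mid, (phi_obj(v1, ctx) + phi_obj(v2, ctx)) / 2 + 1e-12)
  }
  v <- rnorm(6)
  g <- grad_phi(v, ctx)
  expect_lt(phi_obj(v - 1e-4 * g, ctx), phi_obj(v, ctx))
})

test_that("grad_phi matches hand arithmetic and finite differences", {
  # m = n = 1, L = 1, x = 0, y = 0, sigma = 1: gradient at 0 is -1
  Lm1 <- raw_lik(matrix(1, 1, 1))
  ctx1 <- subproblem_context(Lm1, 0, 0, 1)
  expect_equal(grad_phi(0, ctx1), -1)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:10, 1); m <- sample(2:10, 1)
    Lm <- random_lik(n, m)
    ctx <- subproblem_context(Lm, rexp(m), rnorm(n), 10^runif(1, -1, 2))
    v <- rnorm(n)
    g <- grad_phi(v, ctx)
    h <- 1e-6
    fd <- vapply(seq_len(n), function(i) {
      e <- numeric(n); e[i] <- h
      (phi_obj(v + e, ctx) - phi_obj(v - e, ctx)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - fd)) / max(1, max(abs(g))), 1e-5)
  }
})

test_that("active_set uses the sparsest Clarke element and positive diagonal", {
  # craft z = (0.2, 0, -0.1): the tied coordinate is excluded from J
  L <- rbind(c(1.2, 1, 0.9), c(1.2, 1, 0.9))
  ctx <- subproblem_context(raw_lik(L), numeric(3), numeric(2), 1)
  sys <- active_set(c(1, 1), ctx)
  expect_equal(sys$J, 1L)
  expect_equal(sys$s, 1L)
  expect_true(all(sys$D_full > 0))
  expect_equal(sys$solve_mode, "smw")
  # all-negative z: empty active set, diagonal Newton system
  sys0 <- active_set(c(-1, -1), ctx)
  expect_equal(sys0$s, 0L)
  d <- newton_direction(sys0, ctx, c(2, 3))
  expect_equal(d$d, c(2, 3) / sys0$D_full)
  expect_equal(d$residual, 0)
})

test_that("newton_direction solves the SMW system exactly", {
  # hand-checkable 2x2: D = I, Ltil = (1,1)', rhs = (1,1) => d = (1/3, 1/3)
  # with sigma = 1, n = 2: Ltil = (sqrt(1)/2) L_J, so L_J = (2,2)'
  Lm <- raw_lik(matrix(c(2, 2), 2, 1))
  ctx <- subproblem_context(Lm, 0, numeric(2), 1)
  sys <- structure(list(J = 1L, s = 1L, D_full = c(1, 1),
                        solve_mode = "smw"), class = "newton_system")
  nd <- newton_direction(sys, ctx, c(1, 1))
  expect_equal(nd$d, c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_lt(nd$residual, 1e-12)
  # smw vs dense oracle on random instances
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(5:50, 1); m <- sample(5:30, 1)
    Lm <- random_lik(n, m)
    sigma <- 10^runif(1, -1, 3)
    ctx <- subproblem_context(Lm, rexp(m), rnorm(n), sigma)
    v <- rnorm(n)
    sys <- active_set(v, ctx)
    rhs <- -grad_phi(v, ctx)
    nd <- newton_direction(sys, ctx, rhs)
    H <- sigma * (tcrossprod(Lm$L[, sys$J, drop = FALSE]) / n^2) +
      diag(sys$D_full, n)
    d_dense <- solve(H, rhs)
    expect_lt(max(abs(nd$d - d_dense)) / max(1, max(abs(d_dense))), 1e-8)
  }
})

test_that("generalized Hessian matches directional gradient differences", {
  set.seed(7)
  ok <- 0
  for (rep in 1:20) {
    n <- sample(4:12, 1); m <- sample(3:10, 1)
    Lm <- random_lik(n, m)
    ctx <- subproblem_context(Lm, rexp(m), rnorm(n), 2)
    v <- rnorm(n)
    z <- drop(crossprod(Lm$L, v)) / n - 1 + ctx$x / ctx$sigma
    if (min(abs(z)) < 1e-3) next       # stay away from kinks
    sys <- active_set(v, ctx)
    dirn <- rnorm(n); dirn <- dirn / sqrt(sum(dirn^2))
    t <- 1e-6
    Hd_fd <- (grad_phi(v + t * dirn, ctx) - grad_phi(v, ctx)) / t
    Hd <- ctx$sigma * drop(Lm$L[, sys$J, drop = FALSE] %*%
      crossprod(Lm$L[, sys$J, drop = FALSE], dirn)) / n^2 +
      sys$D_full * dirn
    expect_lt(max(abs(Hd - Hd_fd)) / max(1, max(abs(Hd))), 1e-4)
    ok <- ok + 1
  }
  expect_gte(ok, 10)
})

test_that("line search: unit steps near optimum, Armijo vs exhaustive scan", {
  set.seed(8)
  Lm <- random_lik(8, 5)
  ctx <- subproblem_context(Lm, rexp(5), rnorm(8), 3)
  # steepest descent with a tiny gradient is accepted at alpha = 1
  sol <- ssn_solve(ctx, 1e-9, solver_config())
  g <- grad_phi(sol$v, ctx)
  ls <- line_search(sol$v, -g, ctx)
  expect_equal(ls$alpha, 1)
  # at a random point, the accepted alpha is the first beta^j passing Armijo
  v <- rnorm(8)
  g <- grad_phi(v, ctx)
  d <- -5 * g                          # aggressive scaling forces backtracks
  ls <- line_search(v, d, ctx, mu = 0.4, beta = 0.5)
  f0 <- phi_obj(v, ctx)
  armijo <- vapply(0:50, function(j) {
    a <- 0.5^j
    phi_obj(v + a * d, ctx) <= f0 + 0.4 * a * sum(g * d)
  }, TRUE)
  expect_equal(ls$alpha, 0.5^(which(armijo)[1] - 1))
  # monotone descent at every accepted step of an inner solve
  ctx2 <- subproblem_context(Lm, rexp(5), rnorm(8), 1)
  v <- rnorm(8)
  f_prev <- phi_obj(v, ctx2)
  for (t in 1:5) {
    g <- grad_phi(v, ctx2)
    if (sqrt(sum(g^2)) < 1e-12) break
    sys <- active_set(v, ctx2)
    nd <- newton_direction(sys, ctx2, -g)
    ls <- line_search(v, nd$d, ctx2, g = g)
    v <- v + ls$alpha * ls$d
    f <- phi_obj(v, ctx2)
    expect_lt(f, f_prev)
    f_prev <- f
  }
})

test_that("ssn_solve reaches the subproblem optimum and returns valid u", {
  set.seed(9)
  # toy identity subproblem from the first outer iteration
  Lm <- raw_lik(diag(2))
  st <- initialize_state(Lm)
  ctx <- subproblem_context(Lm, st$x, st$y / 2, 1)
  sol <- ssn_solve(ctx, 1e-10, solver_config())
  expect_true(sol$converged)
  expect_lte(sol$iterations, 10)
  # generic smooth-convex minimizer oracle on phi
  opt <- optim(c(0, 0), function(v) phi_obj(v, ctx),
               function(v) grad_phi(v, ctx), method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(phi_obj(sol$v, ctx), opt$value, tolerance = 1e-8)
  # u is the prox at the solution: positive, stationarity identity holds
  expect_true(all(sol$u > 0))
  w <- sol$v - ctx$y / ctx$sigma
  expect_equal(ctx$sigma * (sol$u - w), 1 / (2 * sol$u), tolerance = 1e-10)
  # starting at the optimum returns immediately
  sol2 <- ssn_solve(ctx, 1e-8, solver_config(), v0 = sol$v)
  expect_equal(sol2$iterations, 0L)
  # qualitative superlinear tail: last gradient norm halves the previous
  Lm2 <- random_lik(10, 6)
  ctx2 <- subproblem_context(Lm2, rexp(6), rnorm(10), 5)
  sol3 <- ssn_solve(ctx2, 1e-11, solver_config())
  gn <- c(sol3$diagnostics$gnorm, sol3$gnorm)
  ng <- length(gn)
  expect_lte(gn[ng], 0.5 * gn[ng - 1])
})

test_that("second-order sparsity is bounded by the positive weights at dual-feasible points", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:40, 1); m <- sample(5:20, 1)
    Lm <- random_lik(n, m)
    fit <- alm_fit(Lm, support_set(matrix(seq_len(m), m, 1)),
                   solver_config(tol = 1e-8))
    st <- fit$state
    # scale the converged v inward so the dual constraint holds exactly
    # (at tolerance-level convergence the constraint is active to ~1e-8,
    # which can sit a hair on the infeasible side)
    ztilde <- drop(crossprod(Lm$L, st$v)) / n
    v_feas <- st$v / max(1, max(ztilde))
    ctx <- subproblem_context(Lm, st$x, st$y / n, st$sigma)
    sys <- active_set(v_feas, ctx)
    expect_lte(sys$s, sum(st$x > 0))
  }
})
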