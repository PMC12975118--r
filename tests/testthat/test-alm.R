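test_that("negative_loglik: identity example, zero rows, summation oracle", {
  Lm <- raw_lik(diag(2))
  expect_equal(negative_loglik(Lm, c(0.5, 0.5)), log(2))
  expect_warning(v <- negative_loglik(Lm, c(1, 0)), "observation 2")
  expect_equal(v, Inf)
  set.seed(11)
  L4 <- matrix(rexp(12), 4, 3)
  Lm4 <- raw_lik(L4)
  x <- rexp(3)
  expect_equal(negative_loglik(Lm4, x), -mean(log(L4 %*% x)),
               tolerance = 1e-12)
  # row_log_scale constants are added back
  Ls <- almix:::new_likelihood_matrix(L4, c(1, 2, 3, 4))
  expect_equal(negative_loglik(Ls, x),
               -mean(log(L4 %*% x) + 1:4), tolerance = 1e-12)
})

test_that("initialize_state: uniform weights, exact complementarity", {
  Lm <- raw_lik(diag(2))
  st <- initialize_state(Lm)
  expect_equal(st$x, c(0.5, 0.5))
  expect_equal(st$y, c(0.5, 0.5))
  expect_equal(st$u, c(2, 2))
  expect_equal(st$v, c(2, 2))
  set.seed(12)
  Lr <- random_lik(7, 4)
  str <- initialize_state(Lr)
  expect_equal(str$x, rep(0.25, 4))
  expect_equal(str$u * str$y, rep(1, 7))  # eta_uy = 0 by construction
  expect_equal(kkt_residual(str, Lr)$eta_uy, 0)
})

test_that("update_multipliers follows the max-based rule", {
  Lm <- raw_lik(diag(2))
  st <- initialize_state(Lm)
  st$x <- c(0.3, 0.7)
  # sigma = 1, v_new = (2,2): (sigma/n) L'v - sigma + x = x
  st2 <- update_multipliers(st, Lm, u_new = c(2, 2), v_new = c(2, 2))
  expect_equal(st2$x, c(0.3, 0.7))
  # strongly negative argument clips to zero
  st3 <- initialize_state(Lm)
  st3$x <- c(0.3, 0.7)
  st3 <- update_multipliers(st3, Lm, u_new = c(2, 2), v_new = c(-2, -2))
  expect_equal(st3$x, c(0, 0))
  # u_new = v_new is a fixed point of the y-update (y <- 1/u = y unchanged
  # only when u o y = 1 already holds, as at the toy optimum)
  st4 <- initialize_state(Lm)
  y_before <- st4$y
  st4 <- update_multipliers(st4, Lm, u_new = c(2, 2), v_new = c(2, 2))
  expect_equal(st4$y, y_before)
})

test_that("kkt_residual vanishes exactly at the toy optimum", {
  Lm <- raw_lik(diag(2))
  st <- initialize_state(Lm)   # this IS the optimum for L = I2
  rep0 <- kkt_residual(st, Lm)
  expect_equal(rep0$eta_max, 0)
  expect_equal(rep0$objective, log(2))
  # perturbing y moves exactly eta_primal and eta_uy by the stated amounts
  st2 <- st
  delta <- c(1e-3, -2e-3)
  st2$y <- st2$y + delta
  r2 <- kkt_residual(st2, Lm)
  expect_equal(r2$eta_primal,
               sqrt(sum(delta^2)) / (1 + sqrt(sum(st2$y^2))))
  expect_equal(r2$eta_dual, 0)
  # zero weights give zero complementarity regardless of v
  st3 <- st
  st3$x <- c(0, 0)
  expect_equal(kkt_residual(st3, Lm)$eta_comp, 0)
})

test_that("sigma_schedule grows on stalls, holds on fast progress, caps", {
  cfg <- solver_config(sigma_growth = 3, sigma_max = 10)
  st <- list(sigma = 1)
  slow <- structure(list(eta_max = 0.9), class = "kkt_report")
  prev <- structure(list(eta_max = 1.0), class = "kkt_report")
  fast <- structure(list(eta_max = 0.4), class = "kkt_report")
  expect_equal(sigma_schedule(st, slow, prev, cfg), 3)
  expect_equal(sigma_schedule(st, fast, prev, cfg), 1)
  st$sigma <- 10
  expect_equal(sigma_schedule(st, slow, prev, cfg), 10)
  # first iteration (no previous report) grows
  expect_equal(sigma_schedule(list(sigma = 1), slow, NULL, cfg), 3)
})

test_that("alm_fit solves the identity toy problem to high accuracy", {
  Lm <- raw_lik(diag(2))
  g <- support_set(c(0, 1))
  fit <- alm_fit(Lm, g, solver_config(tol = 1e-8))
  expect_true(fit$converged)
  expect_equal(fit$weights_raw, c(0.5, 0.5), tolerance = 1e-6)
  expect_lte(fit$kkt$eta_max, 1e-8)
  # brute-force simplex oracle agrees
  bf <- brute_force_simplex(Lm, step = 1e-3)
  expect_equal(fit$objective, bf$objective, tolerance = 1e-5)
})

test_that("duplicated columns share the weight of the merged solution", {
  set.seed(13)
  L <- matrix(rexp(40) + 0.1, 10, 4)
  L <- L / apply(L, 1, max)
  Ldup <- cbind(L, L[, 2])
  f1 <- alm_fit(raw_lik(L), support_set(matrix(1:4, 4, 1)),
                solver_config(tol = 1e-9))
  f2 <- alm_fit(raw_lik(Ldup), support_set(matrix(1:5, 5, 1)),
                solver_config(tol = 1e-9))
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
  expect_equal(f2$weights_raw[2] + f2$weights_raw[5], f1$weights_raw[2],
               tolerance = 1e-5)
})

test_that("simplex consistency and duality gap hold at convergence", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(20:60, 1); m <- sample(5:25, 1)
    Lm <- random_lik(n, m)
    tol <- 1e-8
    fit <- alm_fit(Lm, support_set(matrix(seq_len(m), m, 1)),
                   solver_config(tol = tol))
    expect_true(fit$converged)
    expect_lt(abs(fit$sum_x_final - 1), 1e-6)
    st <- fit$state
    primal <- mean(log(st$y)) - sum(st$x) + 1
    dual <- -mean(log(st$u))
    expect_lte(abs(primal - dual), 10 * tol)
    # monotone penalty and nonnegative weights along the path
    expect_true(all(diff(fit$log$sigma) >= 0))
    expect_true(all(st$x >= 0))
  }
})

test_that("alm_fit matches EM and brute force on random instances", {
  set.seed(15)
  # oracle agreement, m <= 3: exhaustive lattice search
  for (rep in 1:6) {
    n <- sample(5:30, 1); m <- sample(2:3, 1)
    Lm <- random_lik(n, m)
    fit <- alm_fit(Lm, support_set(matrix(seq_len(m), m, 1)),
                   solver_config(tol = 1e-9))
    bf <- brute_force_simplex(Lm, step = 1e-3)
    expect_equal(fit$objective, bf$objective, tolerance = 1e-5)
    expect_lte(fit$objective, bf$objective + 1e-6)
  }
  # EM parity on larger instances
  for (rep in 1:4) {
    n <- sample(50:200, 1); m <- sample(10:50, 1)
    Lm <- random_lik(n, m)
    fit <- alm_fit(Lm, support_set(matrix(seq_len(m), m, 1)),
                   solver_config(tol = 1e-9))
    em <- em_solve(Lm, max_iter = 5000, tol = 0)
    expect_lte(fit$objective, em$objective + 1e-8)
  }
})

test_that("non-convergence returns the best iterate with a warning, never errors", {
  set.seed(16)
  Lm <- random_lik(30, 10)
  expect_warning(
    fit <- alm_fit(Lm, support_set(matrix(1:10, 10, 1)),
                   solver_config(tol = 1e-12, max_outer = 2)),
    "max_outer")
  expect_false(fit$converged)
  expect_s3_class(fit$G, "mixing_distribution")
})

test_that("m = 1 grids are rejected as degenerate", {
  Lm <- raw_lik(matrix(c(1, 1), 2, 1))
  g <- structure(list(points = matrix(0), kind = "location", m = 1L, d = 1L),
                 class = "support_set")
  expect_error(alm_fit(Lm, g), "degenerate")
})

test_that("iteration log records the outer trajectory", {
  set.seed(17)
  Lm <- random_lik(25, 8)
  fit <- alm_fit(Lm, support_set(matrix(1:8, 8, 1)),
                 solver_config(tol = 1e-8))
  expect_true(all(c("k", "sigma", "inner_iterations", "eta_max",
                    "objective") %in% names(fit$log)))
  expect_equal(fit$log$k, seq_len(nrow(fit$log)))
  expect_lte(fit$log$eta_max[nrow(fit$log)], 1e-8)
})

test_that("npmle wrapper builds grid and likelihood automatically", {
  ex <- gen_example1(150, nu = 4, tau = 30, seed = 19)
  fit <- npmle(ex$data, m = 60, config = solver_config(tol = 1e-7))
  expect_true(fit$converged)
  expect_s3_class(fit$Lmat, "likelihood_matrix")
  expect_equal(fit$Lmat$m, 60L)
  # scale-mixture route
  d2 <- gen_example2(300, seed = 20)
  fs <- npmle(d2, m = 40, mixture = "scale",
              config = solver_config(tol = 1e-7))
  expect_true(fs$converged)
  expect_equal(fs$support$kind, "scale")
})
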