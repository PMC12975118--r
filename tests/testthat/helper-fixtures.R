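# shared fixtures: tiny likelihood matrices and oracles used across files

# wrap a raw nonnegative matrix as a row-scaled likelihood matrix with unit
# scaling constants (tests that exercise solver algebra, not densities)
raw_lik <- function(L) {
  almix:::new_likelihood_matrix(as.matrix(L), rep(0, nrow(L)))
}

# random likelihood-like matrix with positive entries and row max 1
random_lik <- function(n, m) {
  L <- matrix(stats::rexp(n * m) + 0.05, n, m)
  L <- L / apply(L, 1, max)
  raw_lik(L)
}

# direct log-sum-exp evaluation of the negative mean log-likelihood from
# raw log densities (independent of the row-scaling bookkeeping)
nll_logsumexp <- function(logdens, x) {
  lw <- log(x)
  val <- apply(logdens, 1, function(r) {
    t <- r + lw
    M <- max(t)
    M + log(sum(exp(t - M)))
  })
  -mean(val)
}

# random symmetric matrix with one negative eigenvalue (never SPD)
random_non_spd <- function(d) {
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  ev <- sort(stats::rexp(d) + 0.1, decreasing = TRUE)
  ev[d] <- -abs(ev[d])
  Q %*% diag(ev, d) %*% t(Q)
}

# random SPD matrix
random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d, d)
  crossprod(A) + diag(d) * 0.1
}

# optimal cost of the 1-d squared-distance transportation problem by the
# monotone (quantile) coupling: sort both sides and couple mass greedily.
# For convex costs in one dimension this north-west style coupling on sorted
# supports is the exact optimum (independent closed-form oracle).
monotone_coupling_cost <- function(y, a, atoms, b) {
  oy <- order(y); oa <- order(atoms)
  y <- y[oy]; a <- a[oy]; atoms <- atoms[oa]; b <- b[oa]
  i <- 1L; j <- 1L
  ra <- a[1L]; rb <- b[1L]
  cost <- 0
  repeat {
    f <- min(ra, rb)
    cost <- cost + f * (y[i] - atoms[j])^2
    ra <- ra - f; rb <- rb - f
    if (i == length(y) && j == length(atoms)) break
    if (ra <= rb && i < length(y)) {
      i <- i + 1L; ra <- a[i]
    } else {
      j <- j + 1L; rb <- b[j]
    }
  }
  cost
}

# brute-force optimal assignment cost over all permutations (n <= 7)
assignment_cost_bruteforce <- function(Y, A) {
  n <- nrow(Y)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, sum(rowSums((Y - A[p, , drop = FALSE])^2)))
  best / n
}
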