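# almix — scalable NPMLE for Gaussian mixture deconvolution

`almix` computes the **nonparametric maximum likelihood estimator (NPMLE)**
of a mixing distribution — the Kiefer–Wolfowitz estimator — in the
(multivariate, possibly heteroscedastic) Gaussian location mixture model

    Y_i = theta_i + Z_i,   theta_i ~ G* i.i.d.,   Z_i ~ N(0, Sigma_i),

with known noise covariances `Sigma_i`. It is written for statisticians and
applied scientists who observe noisy measurements of latent quantities
(astronomical photometry, effect sizes, abundances, …) and want to estimate
the latent distribution `G*` and denoise the individual observations by
empirical Bayes.

After discretizing `G` on a fixed grid of atoms `mu_1, ..., mu_m`, the NPMLE
solves the convex program

    max_x  (1/n) sum_i log( sum_j L_ij x_j )   s.t.  1'x = 1,  x >= 0,
    L_ij = phi_{Sigma_i}(Y_i - mu_j),

which `almix` attacks through an **augmented Lagrangian method on the dual**,
with each subproblem minimized by a **semismooth Newton** iteration. The
generalized Hessian is `sigma [ (1/n^2) L_J L_J' + D ]` where `J` is the
small active column set — the *second-order sparsity* that lets the solver
handle `n ~ 10^4–10^6` and `m ~ 10^3–10^4` in seconds on one core, far past
where EM or off-the-shelf interior-point methods give up.

Two denoisers operate on the fitted prior `G_hat`:

* **empirical Bayes posterior means** `E[theta_i | Y_i]` under `G_hat`
  (optimal for squared error, but possibly far from the support of `G*`), and
* an **optimal-transport barycentric projection**: the exact Kantorovich
  plan between the empirical law of the data and `G_hat` is solved by a
  built-in transportation simplex (Rcpp), and each `Y_i` is mapped to its
  conditional mean atom — estimates that inherit the support structure of
  the prior.

Seeded generators reproduce the standard simulation designs (sparse normal
means; a normal/t4/t6 scale-mixture; latent means on concentric circles),
and independent baseline solvers (EM, projected gradient, exhaustive simplex
search) certify the main solver in the test suite.

## Worked example

```r
library(almix)

# sparse normal means: 200 of n = 2,000 latent means equal 3, unit noise
ex   <- gen_example1(n = 2000, nu = 3, tau = 200, seed = 1)
grid <- build_grid_1d(ex$data, m = 300)
Lmat <- likelihood_matrix(ex$data, grid)
fit  <- alm_fit(Lmat, grid, solver_config(tol = 1e-7))
print(fit)
#> npmle_fit: 6 support atoms above 1e-06 (of 300 grid points)
#>   negative log-likelihood 1.65703964, KKT residual 2.139e-08, converged
#>   after 18 outer iterations
```

The fitted prior puts mass 0.83 at the null atom and spreads the remaining
signal mass between the null and the planted atom at 3 — the familiar
NPMLE behavior at this moderate signal strength (6 atoms survive the 1e-6
pruning threshold out of 300 grid points):

```r
cbind(atom = round(fit$G$support[, 1], 4), weight = round(fit$G$weights, 4))
#>         atom weight
#> [1,] -0.0867 0.5431
#> [2,] -0.0572 0.2912
#> [3,]  1.3851 0.0419
#> [4,]  1.4146 0.0656
#> [5,]  3.3280 0.0174
#> [6,]  3.3574 0.0409

dn <- denoise(ex$data, Lmat, fit$G, grid, method = "both")
mean((dn$eb - ex$theta)^2)   #> 0.2961   (empirical Bayes)
mean((dn$ot - ex$theta)^2)   #> 0.3810   (transport projection)
mean((ex$data$Y - ex$theta)^2) #> 1.0506 (no denoising)
dn$ot_cost                   #> 0.7099   W2^2(empirical law, fitted prior)
```

Both denoisers cut the squared error of the raw data by two thirds; the
transport estimates additionally sit exactly on the fitted atoms, which is
what you want when `G*` is structured (clusters, manifolds — see the
concentric-circles test, where OT beats EB in distance-to-support).

A command-line front end covers the same pipeline:

```sh
Rscript inst/cli/almix.R simulate example1 --n 2000 --nu 3 --tau 200 \
        --seed 1 --out obs.csv
Rscript inst/cli/almix.R fit --input obs.csv --grid-size 300 --tol 1e-7 \
        --out fit.json
Rscript inst/cli/almix.R denoise --input obs.csv --mixing fit.json \
        --method both --out denoised.csv
```

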