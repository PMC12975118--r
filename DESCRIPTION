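Package: almix
Title: Scalable Nonparametric Maximum Likelihood for Gaussian Mixture
    Deconvolution via a Dual Augmented Lagrangian Method
Version: 0.1.0
Authors@R:
    person("almix", "developers", email = "almix@example.org", role = c("aut", "cre"))
Description: Computes the discretized nonparametric maximum likelihood
    estimator (NPMLE, the Kiefer-Wolfowitz estimator) of a mixing
    distribution in multivariate, possibly heteroscedastic Gaussian
    mixture models.  The mixing weights are obtained by an augmented
    Lagrangian method applied to the dual of the simplex-constrained
    likelihood problem, with each subproblem solved by a semismooth
    Newton method that exploits second-order sparsity.  The fitted prior
    supports empirical-Bayes posterior-mean denoising and an optimal
    transport barycentric-projection denoiser backed by an exact
    transportation-simplex solver.  Includes seeded synthetic-data
    generators and independent baseline solvers (EM, projected gradient,
    brute-force simplex search) for verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
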