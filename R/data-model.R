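#' Mixture observation data with known noise covariances
#'
#' Container for the Gaussian deconvolution model `Y_i = theta_i + Z_i`,
#' `theta_i ~ G*` i.i.d., `Z_i ~ N(0, Sigma_i)` independent, where the noise
#' covariances `Sigma_i` are known.  Three covariance specifications are
#' supported:
#'
#' * `"shared"`: one d x d symmetric positive definite (SPD) matrix used for
#'   every observation;
#' * `"diag"`: an n x d matrix of positive per-observation variances
#'   (diagonal covariances);
#' * `"full"`: a list of n SPD d x d matrices.
#'
#' @param Y numeric matrix (n x d) or vector (treated as n x 1) of
#'   observations.  Must be finite.
#' @param covs covariance specification matching `cov_mode`; `NULL` means the
#'   shared identity.
#' @param cov_mode one of `"shared"`, `"diag"`, `"full"`.
#' @return an object of class `mixture_data` with fields `Y`, `covs`,
#'   `cov_mode`, `n`, `d`.
#' @export
mixture_data <- function(Y, covs = NULL, cov_mode = c("shared", "diag", "full")) {
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  if (!is.matrix(Y)) Y <- matrix(as.numeric(Y), ncol = 1L)
  storage.mode(Y) <- "double"
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    stop("observations must form a non-empty n x d matrix")
  if (!all(is.finite(Y)))
    stop("non-finite entries in the observation matrix")
  n <- nrow(Y); d <- ncol(Y)
  cov_mode <- match.arg(cov_mode)
  if (is.null(covs)) {
    cov_mode <- "shared"
    covs <- diag(d)
  }
  covs <- switch(cov_mode,
    shared = {
      covs <- as.matrix(covs)
      if (!identical(dim(covs), c(d, d)))
        stop(sprintf("shared covariance must be %d x %d, got %d x %d",
                     d, d, nrow(covs), ncol(covs)))
      check_spd(covs, what = "shared covariance")
      covs
    },
    diag = {
      covs <- as.matrix(covs)
      if (nrow(covs) != n || ncol(covs) != d)
        stop(sprintf("diagonal variances must be %d x %d, got %d x %d",
                     n, d, nrow(covs), ncol(covs)))
      bad <- which(!(covs > 0) | !is.finite(covs), arr.ind = TRUE)
      if (nrow(bad) > 0L)
        stop(sprintf("non-positive variance for observation %d (coordinate %d)",
                     bad[1L, 1L], bad[1L, 2L]))
      covs
    },
    full = {
      if (!is.list(covs) || length(covs) != n)
        stop(sprintf("full covariance mode needs a list of %d matrices", n))
      for (i in seq_len(n)) {
        Si <- as.matrix(covs[[i]])
        if (!identical(dim(Si), c(d, d)))
          stop(sprintf("covariance block %d is not %d x %d", i, d, d))
        check_spd(Si, what = sprintf("covariance of observation %d", i))
        covs[[i]] <- Si
      }
      covs
    })
  structure(list(Y = Y, covs = covs, cov_mode = cov_mode, n = n, d = d),
            class = "mixture_data")
}

# SPD test: symmetric to roundoff and smallest eigenvalue > tol
check_spd <- function(S, tol = 1e-12, what = "covariance") {
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop(sprintf("%s is not symmetric", what))
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol)
    stop(sprintf("%s is not positive definite (min eigenvalue %.3e)",
                 what, min(ev)))
  invisible(TRUE)
}

#' @export
print.mixture_data <- function(x, ...) {
  cat(sprintf("mixture_data: n = %d observations in d = %d (%s covariances)\n",
              x$n, x$d, x$cov_mode))
  invisible(x)
}

#' Discrete mixing distribution (atoms and simplex weights)
#'
#' The discretized prior `G = sum_j x_j delta_{mu_j}`.  Duplicate atom rows
#' are merged by summing their weights (the likelihood only depends on the
#' total weight on each distinct atom).  Weights must be nonnegative; they
#' are checked, not rescaled, so a finalized estimate must sum to one within
#' `1e-8`.
#'
#' @param support numeric m x d matrix of atoms (a vector is taken as m x 1).
#' @param weights nonnegative length-m vector.
#' @param normalized if `TRUE` (default) require `|sum(weights) - 1| <= 1e-8`.
#' @return an object of class `mixing_distribution` with fields `support`,
#'   `weights`, `m`, `d`.
#' @export
mixing_distribution <- function(support, weights, normalized = TRUE) {
  if (!is.matrix(support)) support <- matrix(as.numeric(support), ncol = 1L)
  storage.mode(support) <- "double"
  weights <- as.numeric(weights)
  if (length(weights) == 0L) stop("empty weight vector")
  if (nrow(support) != length(weights))
    stop("support rows and weights differ in length")
  if (any(!is.finite(support)) || any(!is.finite(weights)))
    stop("non-finite support point or weight")
  if (any(weights < 0)) stop("negative mixing weight")
  key <- apply(support, 1L, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    grp <- match(key, key)
    keep <- sort(unique(grp))
    weights <- vapply(keep, function(g) sum(weights[grp == g]), 0)
    support <- support[keep, , drop = FALSE]
  }
  if (normalized && abs(sum(weights) - 1) > 1e-8)
    stop(sprintf("weights sum to %.10f, not 1", sum(weights)))
  structure(list(support = support, weights = weights,
                 m = nrow(support), d = ncol(support)),
            class = "mixing_distribution")
}

#' @export
print.mixing_distribution <- function(x, ...) {
  cat(sprintf("mixing_distribution: %d atoms in d = %d, total mass %.6f\n",
              x$m, x$d, sum(x$weights)))
  invisible(x)
}

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_numeric_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, sep = delim_for(path, delim),
                           header = FALSE, colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  M <- suppressWarnings(matrix(as.numeric(as.matrix(tab)),
                               nrow = nrow(tab), ncol = ncol(tab)))
  bad <- which(is.na(M), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1L, 1L], bad[1L, 2L], path))
  M
}

#' Read observations (and optional covariances) from delimited text
#'
#' The delimiter is autodetected from the extension (`.csv` is comma,
#' anything else tab) unless `delim` is given.  The covariance file layout
#' depends on `cov_mode`: shared, d rows x d columns; diag, n rows x d
#' columns of variances; full, n*d rows x d columns of stacked blocks.
#'
#' @param path observation file, n rows x d numeric columns.
#' @param cov_path optional covariance file; absent means shared identity.
#' @param cov_mode `"shared"`, `"diag"` or `"full"`.
#' @param delim optional delimiter override.
#' @return a [mixture_data] object.
#' @export
read_observations <- function(path, cov_path = NULL,
                              cov_mode = c("shared", "diag", "full"),
                              delim = NULL) {
  cov_mode <- match.arg(cov_mode)
  Y <- read_numeric_table(path, delim)
  n <- nrow(Y); d <- ncol(Y)
  if (is.null(cov_path)) return(mixture_data(Y))
  Cv <- read_numeric_table(cov_path, delim)
  covs <- switch(cov_mode,
    shared = {
      if (nrow(Cv) != d)
        stop(sprintf("shared covariance file has %d rows, expected %d",
                     nrow(Cv), d))
      Cv
    },
    diag = {
      if (nrow(Cv) != n)
        stop(sprintf("diagonal variance file has %d rows, expected %d",
                     nrow(Cv), n))
      Cv
    },
    full = {
      if (nrow(Cv) != n * d)
        stop(sprintf("full covariance file has %d rows, expected %d",
                     nrow(Cv), n * d))
      lapply(seq_len(n), function(i) Cv[((i - 1L) * d + 1L):(i * d), , drop = FALSE])
    })
  mixture_data(Y, covs, cov_mode)
}

#' Serialize a mixing distribution to JSON (full double precision)
#'
#' Round-trips bit-exactly through [read_mixing_distribution()].
#'
#' @param G a [mixing_distribution].
#' @param path output file.
#' @export
write_mixing_distribution <- function(G, path) {
  stopifnot(inherits(G, "mixing_distribution"))
  # re-validate (constructor merges duplicates, so duplicates here mean
  # the object was tampered with)
  key <- apply(G$support, 1L, paste, collapse = "\r")
  if (anyDuplicated(key)) stop("duplicate support atoms; rebuild the object")
  if (length(G$weights) == 0L) stop("empty mixing distribution")
  doc <- list(support = unname(G$support), weights = G$weights,
              m = G$m, d = G$d)
  # I(17) = 17 significant digits, enough to round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a mixing distribution written by [write_mixing_distribution()]
#' @param path JSON file.
#' @return a [mixing_distribution].
#' @export
read_mixing_distribution <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  # accept both a bare document and a solver result wrapping one
  if (!is.null(doc$mixing_distribution)) doc <- doc$mixing_distribution
  support <- matrix(as.numeric(doc$support), nrow = doc$m, ncol = doc$d)
  mixing_distribution(support, as.numeric(doc$weights), normalized = FALSE)
}

#' Write denoised estimates as delimited text
#'
#' @param estimates finite n x d numeric matrix.
#' @param method_tag `"eb"` (posterior mean) or `"ot"` (barycentric
#'   projection); written as the header line.
#' @param path output file; extension selects the delimiter.
#' @export
write_denoised <- function(estimates, method_tag = c("eb", "ot"), path) {
  method_tag <- match.arg(method_tag)
  if (!is.matrix(estimates)) estimates <- matrix(as.numeric(estimates), ncol = 1L)
  if (nrow(estimates) == 0L) stop("no estimates to write")
  if (any(!is.finite(estimates))) stop("non-finite denoised estimate")
  sep <- delim_for(path)
  header <- paste(rep(method_tag, ncol(estimates)), seq_len(ncol(estimates)),
                  sep = "_")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  utils::write.table(format(estimates, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
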