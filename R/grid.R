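#' Support grids for the discretized NPMLE
#'
#' A `support_set` holds the fixed candidate atoms `mu_j` of the discretized
#' mixing distribution.  Two kinds are supported: `"location"` grids of mean
#' vectors (m x d) and `"scale"` grids of variances (m x 1, for centered
#' Gaussian scale mixtures in d = 1).  Points are stored sorted
#' (lexicographically by coordinate) and duplicates are removed.
#'
#' @param points m x d matrix (location) or m x 1 matrix / vector of
#'   variances (scale).
#' @param kind `"location"` or `"scale"`.
#' @return an object of class `support_set` with fields `points`, `kind`,
#'   `m`, `d`.
#' @export
support_set <- function(points, kind = c("location", "scale")) {
  kind <- match.arg(kind)
  if (!is.matrix(points)) points <- matrix(as.numeric(points), ncol = 1L)
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("non-finite grid point")
  if (kind == "scale") {
    if (ncol(points) != 1L) stop("scale grids are one-dimensional (variances)")
    if (any(points <= 0)) stop("scale grid variances must be positive")
  }
  ord <- do.call(order, lapply(seq_len(ncol(points)), function(j) points[, j]))
  points <- points[ord, , drop = FALSE]
  dup <- duplicated(points)
  if (any(dup)) points <- points[!dup, , drop = FALSE]
  if (nrow(points) < 2L) stop("a support grid needs at least 2 distinct points")
  structure(list(points = points, kind = kind,
                 m = nrow(points), d = ncol(points)),
            class = "support_set")
}

#' @export
print.support_set <- function(x, ...) {
  cat(sprintf("support_set: %d %s grid points in d = %d\n",
              x$m, x$kind, x$d))
  invisible(x)
}

#' Equally spaced one-dimensional location grid
#'
#' m equally spaced points on `[min Y, max Y]`, endpoints included — the
#' standard grid for univariate location mixtures.
#'
#' @param data a [mixture_data] with d = 1.
#' @param m number of grid points (>= 2).
#' @return a location [support_set].
#' @export
build_grid_1d <- function(data, m) {
  stopifnot(inherits(data, "mixture_data"))
  if (data$d != 1L) stop("build_grid_1d requires d = 1")
  if (m < 2L) stop("m must be at least 2")
  rng <- range(data$Y)
  if (rng[1] == rng[2])
    stop("all observations identical; supply an explicit grid instead")
  support_set(seq(rng[1], rng[2], length.out = m), kind = "location")
}

#' Axis-aligned box grid for multivariate data
#'
#' Cartesian product of per-coordinate equally spaced grids over the minimum
#' axis-aligned bounding box of the data; `per_dim^d` points in total.  The
#' bounding box is known to contain all support points of the NPMLE.
#'
#' @param data a [mixture_data] with d >= 2.
#' @param per_dim points per coordinate (>= 2).
#' @return a location [support_set] with `per_dim^d` points.
#' @export
build_grid_box <- function(data, per_dim) {
  stopifnot(inherits(data, "mixture_data"))
  if (data$d < 2L) stop("build_grid_box requires d >= 2; use build_grid_1d")
  if (per_dim < 2L) stop("per_dim must be at least 2")
  axes <- lapply(seq_len(data$d), function(j) {
    rng <- range(data$Y[, j])
    if (rng[1] == rng[2])
      stop(sprintf("coordinate %d is degenerate; supply an explicit grid", j))
    seq(rng[1], rng[2], length.out = per_dim)
  })
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  support_set(pts, kind = "location")
}

#' Geometric variance grid for Gaussian scale mixtures
#'
#' m variances geometrically spaced between a small positive floor and
#' `max(Y^2)`.  The floor defaults to `(0.05 * sd(Y))^2` so that the grid
#' brackets both light- and heavy-tailed components; geometric spacing is
#' the standard choice for scale mixtures.
#'
#' @param data a [mixture_data] with d = 1.
#' @param m number of variances (>= 2).
#' @param var_min optional positive lower endpoint override.
#' @return a scale [support_set].
#' @export
build_scale_grid <- function(data, m, var_min = NULL) {
  stopifnot(inherits(data, "mixture_data"))
  if (data$d != 1L) stop("build_scale_grid requires d = 1")
  if (m < 2L) stop("m must be at least 2")
  y <- data$Y[, 1L]
  var_max <- max(y^2)
  if (var_max == 0) stop("all observations are zero; no scale information")
  if (is.null(var_min)) var_min <- (0.05 * stats::sd(y))^2
  if (!is.finite(var_min) || var_min <= 0 || var_min >= var_max)
    stop("invalid variance floor; supply var_min explicitly")
  support_set(exp(seq(log(var_min), log(var_max), length.out = m)),
              kind = "scale")
}
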