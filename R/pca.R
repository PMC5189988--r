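#' Cartesian principal component analysis of a trajectory
#'
#' Builds the 3N x 3N covariance matrix of the selected atoms' Cartesian
#' coordinates over frames and diagonalises it.  The trajectory should first
#' be least-squares fitted to its first frame over the same selection
#' ([fit_trajectory()]); otherwise global rotation dominates the leading
#' components.  Eigenvector signs follow a fixed convention (the
#' largest-magnitude component of each eigenvector is positive) so results
#' are reproducible across eigensolvers.
#'
#' @param traj a fitted `Trajectory`.
#' @param sel `AtomSelection` of the N analysis atoms (typically C-alpha).
#' @return object of class `PCAModel`: list with `mean` (3N), `eigenvectors`
#'   (3N x m, orthonormal columns), `eigenvalues` (descending, >= 0 within
#'   numerical noise) and `variance_fraction`.
#' @export
fit_pca <- function(traj, sel = NULL) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  X <- .coord_matrix(traj, sel)
  if (nrow(X) <= ncol(X))
    warning("fewer frames than coordinate dimensions (F <= 3N); ",
            "trailing eigenvalues are rank-deficient zeros")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  obj <- list(mean = mu, eigenvectors = vecs, eigenvalues = vals,
              variance_fraction = if (sum(vals) > 0) vals / sum(vals) else vals)
  class(obj) <- "PCAModel"
  obj
}

.coord_matrix <- function(traj, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  f <- n_frames(traj)
  X <- matrix(0, f, 3L * length(idx))
  sub <- traj$coords[, idx, , drop = FALSE]
  # column layout: x1 y1 z1 x2 y2 z2 ...
  for (d in 1:3) X[, seq(d, by = 3L, length.out = length(idx))] <- sub[, , d]
  X
}

#' @export
print.PCAModel <- function(x, ...) {
  cat("PCAModel:", length(x$mean) / 3, "atoms,",
      length(x$eigenvalues), "modes\n")
  vf <- round(100 * x$variance_fraction[1:min(3, length(x$eigenvalues))], 1)
  cat("  variance captured by PC1-3:", paste0(vf, "%", collapse = " "), "\n")
  invisible(x)
}

#' Project a trajectory onto principal components
#'
#' Centred selected coordinates dotted with the leading `k` eigenvectors.
#'
#' @param traj a fitted `Trajectory` (same selection as the model fit).
#' @param model a `PCAModel`.
#' @param sel the `AtomSelection` used for the fit.
#' @param k number of components (default 2).
#' @return F x k numeric matrix of projections.
#' @export
project_pca <- function(traj, model, sel = NULL, k = 2L) {
  X <- .coord_matrix(traj, sel)
  if (ncol(X) != length(model$mean))
    stop("selection/model dimensionality mismatch: ", ncol(X), " vs ",
         length(model$mean))
  if (k > ncol(model$eigenvectors)) stop("k exceeds the number of components")
  sweep(X, 2, model$mean) %*% model$eigenvectors[, seq_len(k), drop = FALSE]
}

#' PCA-based free-energy landscape
#'
#' 2-D histogram density `rho` of the first two projections, converted to
#' `dG = -ln(rho / rho_max)` in kT units.  Empty bins are `Inf` (unbounded),
#' and the global minimum is exactly 0 kT by construction.
#'
#' @param projection F x 2 matrix of PC projections.
#' @param bins number of bins per axis (default 80).
#' @param temperature kelvin; recorded for unit conversion (dG values are in
#'   kT and do not depend on it; multiply by 0.0019872 * temperature for
#'   kcal/mol).
#' @return list with `dG` (bins x bins matrix, kT), `x_breaks`, `y_breaks`,
#'   `temperature`.
#' @export
free_energy_landscape <- function(projection, bins = 80L, temperature = 300) {
  projection <- as.matrix(projection)
  if (ncol(projection) < 2L) stop("projection must have two columns")
  if (bins < 2L) stop("bins must be >= 2")
  if (nrow(projection) < bins)
    warning("fewer frames than bins; landscape will be sparse")
  rng <- function(v) if (diff(range(v)) == 0) range(v) + c(-0.5, 0.5) else range(v)
  rx <- rng(projection[, 1]); ry <- rng(projection[, 2])
  xb <- seq(rx[1], rx[2], length.out = bins + 1L)
  yb <- seq(ry[1], ry[2], length.out = bins + 1L)
  ix <- pmin(findInterval(projection[, 1], xb, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(projection[, 2], yb, rightmost.closed = TRUE), bins)
  counts <- matrix(0, bins, bins)
  for (i in seq_len(nrow(projection)))
    counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  dG <- -log(counts / max(counts))
  list(dG = dG, x_breaks = xb, y_breaks = yb, temperature = temperature)
}
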