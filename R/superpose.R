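#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (optionally weighted) RMSD between `R %*% x + t` applied to `mobile` and
#' `reference`, via SVD of the weighted covariance matrix with the
#' determinant-corrected (Kabsch) sign convention.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix.
#' @param weights optional non-negative per-point weights.
#' @return object of class `SuperpositionResult`: list with `rotation` (3 x 3,
#'   det = +1), `translation` (length 3; the transform is
#'   `y = rotation %*% x + translation` for column vectors), `rmsd` (Angstrom,
#'   weighted) and `degenerate` flag for near-collinear inputs.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("point-count mismatch between mobile and reference")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be non-negative, one per point")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)
  if (degenerate)
    warning("degenerate (near-collinear) geometry; superposition is not unique")
  fitted <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  out <- list(rotation = R, translation = as.numeric(cr - R %*% cm),
              rmsd = rmsd, degenerate = degenerate)
  class(out) <- "SuperpositionResult"
  out
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A%s\n", x$rmsd,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param xyz n x 3 matrix.
#' @param sp a `SuperpositionResult`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, sp) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Root-mean-square fluctuation per atom
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` over frames.  The trajectory
#' must already be least-squares fitted to a reference frame (see
#' [fit_trajectory()]); this contract is not detectable from the coordinates
#' and is therefore documented rather than checked.
#'
#' @param traj a fitted `Trajectory`.
#' @param sel optional `AtomSelection`; default all atoms.
#' @return numeric vector of per-atom RMSF values (Angstrom).
#' @export
rmsf <- function(traj, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    xyz <- traj$coords[, idx[k], ]
    mu <- colMeans(xyz)
    out[k] <- sqrt(mean(rowSums(sweep(xyz, 2, mu)^2)))
  }
  names(out) <- traj$topology$atoms$name[idx]
  out
}

#' RMSD between two coordinate sets after optimal superposition
#' @inheritParams superpose
#' @export
rmsd_fit <- function(mobile, reference, weights = NULL) {
  superpose(mobile, reference, weights)$rmsd
}
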