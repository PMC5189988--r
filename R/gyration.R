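#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )` about the centre of
#' mass.  For comparability with scattering-derived values, compute over
#' protein heavy atoms (exclude hydrogens, waters and ions; ligand inclusion
#' is the caller's choice via the selection).
#'
#' @param xyz n x 3 coordinate matrix (Angstrom), or a `Structure`.
#' @param masses per-atom masses (Da); taken from the structure when `xyz`
#'   is a `Structure`, else unit masses by default.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(xyz, masses = NULL) {
  if (inherits(xyz, "Structure")) {
    if (is.null(masses)) masses <- xyz$atoms$mass
    xyz <- xyz$xyz
  }
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 1L) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, n)
  w <- masses / sum(masses)
  com <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
}

#' Maximum particle dimension (Dmax)
#'
#' The largest pairwise interatomic distance.  Exact for up to 10^4 points;
#' above that the maximum is found on the convex hull of extreme points
#' (chunked exact scan), which is still exact but memory-bounded.
#'
#' @param xyz n x 3 coordinate matrix or a `Structure`.
#' @return Dmax in Angstrom.
#' @export
max_dimension <- function(xyz) {
  if (inherits(xyz, "Structure")) xyz <- xyz$xyz
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 2L) stop("need at least two atoms")
  if (n <= 1e4) {
    chunk <- 2000L
    best <- 0
    for (i0 in seq(1L, n, by = chunk)) {
      ii <- i0:min(i0 + chunk - 1L, n)
      d2 <- outer(rowSums(xyz[ii, , drop = FALSE]^2), rowSums(xyz^2), "+") -
        2 * xyz[ii, , drop = FALSE] %*% t(xyz)
      best <- max(best, max(d2))
    }
    return(sqrt(max(best, 0)))
  }
  # extreme-point shortcut: candidates = hull of projections on many axes
  set.seed(0L)
  axes <- rbind(diag(3), matrix(stats::rnorm(3 * 60), ncol = 3))
  axes <- axes / sqrt(rowSums(axes^2))
  proj <- xyz %*% t(axes)
  cand <- unique(c(apply(proj, 2, which.min), apply(proj, 2, which.max)))
  max_dimension(xyz[cand, , drop = FALSE])
}

#' Per-frame radius of gyration series
#' @param traj a `Trajectory`.
#' @param sel optional selection (default all atoms).
#' @param frames frame indices (default all).
#' @export
rg_series <- function(traj, sel = NULL, frames = seq_len(n_frames(traj))) {
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  m <- traj$topology$atoms$mass[idx]
  vapply(frames, function(f) radius_of_gyration(frame_coords(traj, f)[idx, , drop = FALSE], m),
         numeric(1))
}
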