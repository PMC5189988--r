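#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius `r_vdw + probe` is sampled at `n_points`
#' quasi-uniform (Fibonacci spiral) points; the unoccluded fraction scales
#' the sphere area.  Default probe 1.4 Angstrom (water).
#'
#' @param xyz n x 3 coordinate matrix, or a `Structure` (radii taken from it).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sphere sample points (default 960; a warning is issued
#'   below 32 where the quadrature is too coarse).
#' @return list with `atom_sasa` (per-atom, Angstrom^2) and `total`.
#' @export
sasa <- function(xyz, radii = NULL, probe = 1.4, n_points = 960L) {
  if (inherits(xyz, "Structure")) {
    if (is.null(radii)) radii <- xyz$atoms$radius
    xyz <- xyz$xyz
  }
  xyz <- as.matrix(xyz)
  if (is.null(radii)) stop("radii required when xyz is a bare matrix")
  if (probe <= 0) stop("probe radius must be positive")
  if (any(radii <= 0)) stop("radii must be positive")
  if (n_points < 32L) warning("n_points < 32: SASA precision will be poor")
  v <- .sasa_cpp(xyz, as.numeric(radii), probe, as.integer(n_points))
  list(atom_sasa = v, total = sum(v))
}

#' Per-residue SASA time series
#'
#' @param traj a `Trajectory`.
#' @param resid residue number (summed over the residue's atoms).
#' @param chain optional chain id.
#' @param frames frame indices (default the 25-frame stride).
#' @inheritParams sasa
#' @return `AttributeSeries` of kind `"sasa"`.
#' @export
sasa_series <- function(traj, resid, chain = NULL,
                        frames = stride_frames(traj), probe = 1.4,
                        n_points = 240L) {
  at <- traj$topology$atoms
  if (is.null(chain)) chain <- at$chain[at$resid == resid][1]
  ridx <- which(at$resid == resid & at$chain == chain)
  if (length(ridx) == 0L) stop("residue not found")
  vals <- vapply(frames, function(f) {
    s <- sasa(frame_coords(traj, f), at$radius, probe, n_points)
    sum(s$atom_sasa[ridx])
  }, numeric(1))
  attribute_series(sprintf("sasa %s%d", chain, resid), "sasa", vals, frames)
}
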