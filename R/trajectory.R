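#' Build a trajectory object
#'
#' A `Trajectory` is an F x A x 3 coordinate array (Angstrom) with frame
#' times (ps) and a shared topology `Structure`.
#'
#' @param coords numeric array `[n_frames, n_atoms, 3]`.
#' @param topology a `Structure` with `n_atoms` atoms.
#' @param times frame timestamps in ps; default 1-ps spacing starting at 1.
#' @return object of class `Trajectory`.
#' @export
trajectory_new <- function(coords, topology, times = NULL) {
  stopifnot(inherits(topology, "Structure"))
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    stop("coords must be an [F x A x 3] array")
  if (d[1] < 2L) stop("trajectory error: need at least 2 frames")
  if (d[2] != n_atoms(topology))
    stop("topology error: trajectory has ", d[2], " atoms but topology has ",
         n_atoms(topology))
  if (is.null(times)) times <- as.numeric(seq_len(d[1]))
  if (length(times) != d[1]) stop("times length must equal n_frames")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  obj <- list(coords = coords, times = as.numeric(times), topology = topology)
  class(obj) <- "Trajectory"
  obj
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", dim(x$coords)[2], "atoms\n")
  cat("  time range:", x$times[1], "-", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' @rdname trajectory_new
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an A x 3 coordinate matrix
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = TRUE]
  dim(m) <- c(dim(traj$coords)[2], 3L)
  m
}

#' Remove global rotation/translation by least-squares fitting
#'
#' Superposes every frame onto a reference frame over a fit selection
#' (typically the C-alpha atoms) and applies the resulting rigid transform to
#' all atoms.  This is the standard preprocessing before PCA, RMSF and
#' cross-correlation analysis.
#'
#' @param traj a `Trajectory`.
#' @param sel `AtomSelection` (or indices) used for the fit; default all atoms.
#' @param ref_frame reference frame index (default 1, the first frame).
#' @return a fitted `Trajectory` with attribute `fitted = TRUE`.
#' @export
fit_trajectory <- function(traj, sel = NULL, ref_frame = 1L) {
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  ref <- frame_coords(traj, ref_frame)[idx, , drop = FALSE]
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, f)
    sp <- superpose(fr[idx, , drop = FALSE], ref)
    out[f, , ] <- apply_transform(fr, sp)
  }
  res <- trajectory_new(out, traj$topology, traj$times)
  attr(res, "fitted") <- TRUE
  res
}
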