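#' Dynamic cross-correlation matrix (DCCM)
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` with `dr` the
#' deviation of each selected atom (one per residue, typically C-alpha) from
#' its time mean.  The trajectory must be fitted to a reference frame first.
#'
#' @param traj a fitted `Trajectory`.
#' @param sel `AtomSelection` with one representative atom per residue.
#' @param frames frame subset (default all; pass the frames of one
#'   conformational state for per-state correlation maps).
#' @return object of class `CorrelationMatrix`: list with `values` (R x R,
#'   symmetric, unit diagonal), `indices` (atom indices) and `resids`.
#'   Rows of zero-variance (immobile) atoms are `NA` and flagged.
#' @export
dccm <- function(traj, sel = NULL, frames = seq_len(n_frames(traj))) {
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  R <- length(idx)
  f <- length(frames)
  cov3 <- matrix(0, R, R)
  for (d in 1:3) {
    Xd <- traj$coords[frames, idx, d]
    Xd <- sweep(Xd, 2, colMeans(Xd))
    cov3 <- cov3 + crossprod(Xd) / f
  }
  v <- diag(cov3)
  immobile <- v <= 1e-300
  denom <- sqrt(outer(v, v))
  vals <- cov3 / denom
  if (any(immobile)) {
    warning(sum(immobile), " immobile atom(s): correlation undefined (NA)")
    vals[immobile, ] <- NA_real_
    vals[, immobile] <- NA_real_
  }
  diag(vals)[!immobile] <- 1
  obj <- list(values = vals, indices = idx,
              resids = traj$topology$atoms$resid[idx], immobile = immobile)
  class(obj) <- "CorrelationMatrix"
  obj
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("CorrelationMatrix:", nrow(x$values), "x", ncol(x$values), "\n")
  invisible(x)
}

#' Running cross-correlation (RCC) of one residue pair
#'
#' The pair's cross-correlation coefficient computed inside a length-`window`
#' frame subset that advances one frame at a time; each window's means are
#' window-local (required for the series to track sign changes of the
#' coupling).  Values are indexed by the window midpoint.
#'
#' @param traj a fitted `Trajectory`.
#' @param sel selection of representative atoms (one per residue).
#' @param pair length-2 vector of *residue numbers* (matched against the
#'   selection) or, when `by = "index"`, positions within the selection.
#' @param window window length in frames (>= 10 recommended; `window = F`
#'   reproduces the full-trajectory DCCM entry as a single value).
#' @param by `"resid"` (default) or `"index"`.
#' @return object of class `RCCSeries`: `pair`, `window`, `midpoints`,
#'   `values` (length `F - window + 1`).
#' @export
running_cross_correlation <- function(traj, sel = NULL, pair, window,
                                      by = c("resid", "index")) {
  by <- match.arg(by)
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  f <- n_frames(traj)
  if (window > f) stop("window exceeds trajectory length")
  if (window < 10) warning("window < 10 frames: RCC will be very noisy")
  pos <- if (by == "resid") {
    match(pair, traj$topology$atoms$resid[idx])
  } else as.integer(pair)
  if (anyNA(pos)) stop("pair residues not found in selection")
  a <- traj$coords[, idx[pos[1]], ]
  b <- traj$coords[, idx[pos[2]], ]
  vals <- .rcc_pair(a, b, window)
  obj <- list(pair = pair, window = window,
              midpoints = seq_len(f - window + 1L) + (window - 1) / 2,
              values = vals)
  class(obj) <- "RCCSeries"
  obj
}

# windowed 3-D correlation via cumulative sums; a, b are F x 3
.rcc_pair <- function(a, b, W) {
  f <- nrow(a)
  wsum <- function(v) {
    cs <- cumsum(v)
    cs[W:f] - c(0, cs[seq_len(f - W)])
  }
  Sab <- wsum(rowSums(a * b))
  Saa <- wsum(rowSums(a * a))
  Sbb <- wsum(rowSums(b * b))
  ma <- matrix(vapply(1:3, function(d) wsum(a[, d]), numeric(f - W + 1)),
               ncol = 3)
  mb <- matrix(vapply(1:3, function(d) wsum(b[, d]), numeric(f - W + 1)),
               ncol = 3)
  cov_ab <- Sab / W - rowSums(ma * mb) / W^2
  var_a <- Saa / W - rowSums(ma * ma) / W^2
  var_b <- Sbb / W - rowSums(mb * mb) / W^2
  out <- cov_ab / sqrt(pmax(var_a, 0) * pmax(var_b, 0))
  out[!is.finite(out)] <- NA_real_
  out
}

#' @export
print.RCCSeries <- function(x, ...) {
  cat(sprintf("RCCSeries pair %s-%s, window %d: %d values, mean %.3f, sd %.3f\n",
              x$pair[1], x$pair[2], x$window, length(x$values),
              mean(x$values, na.rm = TRUE), stats::sd(x$values, na.rm = TRUE)))
  invisible(x)
}

#' RCC deviation map
#'
#' Standard deviation of every residue pair's running cross-correlation
#' series; pairs whose coupling changes along the trajectory (e.g. switching
#' sign at a conformational transition) attain large values.  Cost is
#' O(R^2 F) via a sliding-sum kernel; refuse beyond 1000 residues.
#'
#' @inheritParams running_cross_correlation
#' @return object of class `RCCDeviationMap`: `sigma` (R x R, symmetric,
#'   zero diagonal), `mean` (mean RCC per pair), `window`, `resids`.
#' @export
rcc_deviation_map <- function(traj, sel = NULL, window = max(10L, n_frames(traj) %/% 10L)) {
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  if (length(idx) > 1000L)
    stop("cost guard: > 1000 residues; pass a smaller selection (e.g. one ",
         "chain) or coarser node set")
  f <- n_frames(traj)
  if (window > f) stop("window exceeds trajectory length")
  st <- .rcc_stats_cpp(traj$coords[, idx, 1], traj$coords[, idx, 2],
                       traj$coords[, idx, 3], as.integer(window))
  obj <- list(sigma = st$sigma, mean = st$mean, window = window,
              resids = traj$topology$atoms$resid[idx])
  class(obj) <- "RCCDeviationMap"
  obj
}

#' @export
print.RCCDeviationMap <- function(x, ...) {
  cat(sprintf("RCCDeviationMap: %d residues, window %d, max sigma %.3f\n",
              nrow(x$sigma), x$window, max(x$sigma)))
  invisible(x)
}

#' Inter-residue distance-fluctuation map
#'
#' Standard deviation over frames of every pairwise distance between the
#' selected representative atoms.  Distances are invariant under rigid
#' motion, so no prior fitting is needed.
#'
#' @inheritParams dccm
#' @return R x R symmetric matrix of distance standard deviations (Angstrom).
#' @export
distance_fluctuation_map <- function(traj, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(dim(traj$coords)[2]) else
    sel_indices(sel, traj$topology)
  .distance_sd_cpp(traj$coords[, idx, 1], traj$coords[, idx, 2],
                   traj$coords[, idx, 3])
}
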