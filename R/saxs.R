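#' Construct a scattering curve
#'
#' @param q scattering vector magnitudes, 1/Angstrom, ascending.
#' @param intensity intensities (arbitrary units, >= 0).
#' @param sigma optional per-point uncertainties (> 0).
#' @export
scattering_curve <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (is.unsorted(q, strictly = FALSE)) stop("q must be ascending")
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) stop("sigma length differs")
    if (any(sigma <= 0)) stop("sigma must be positive")
  }
  obj <- list(q = q, intensity = intensity, sigma = sigma)
  class(obj) <- "ScatteringCurve"
  obj
}

#' @export
print.ScatteringCurve <- function(x, ...) {
  cat(sprintf("ScatteringCurve: %d points, q %.4g-%.4g 1/A%s\n", length(x$q),
              min(x$q), max(x$q), if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' Read / write SAXS curves in 3-column text (.dat dialect)
#'
#' Whitespace-separated `q I sigma` columns; lines starting with `#` (and
#' blank lines) are ignored.  The third column is optional.
#'
#' @param path file path.
#' @export
read_saxs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  scattering_curve(m[, 1], m[, 2], if (ncol(m) >= 3) m[, 3] else NULL)
}

#' @rdname read_saxs
#' @param curve a `ScatteringCurve`.
#' @export
write_saxs <- function(curve, path) {
  m <- cbind(curve$q, curve$intensity,
             if (is.null(curve$sigma)) NULL else curve$sigma)
  utils::write.table(format(m, digits = 8), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Theoretical scattering curve via the Debye formula
#'
#' `I(q) = sum_i sum_j f_i f_j sin(q r_ij)/(q r_ij)` with constant
#' (q-independent) per-element form factors equal to electron counts.
#' Hydration-shell and excluded-volume corrections are deliberately not
#' modelled, so absolute agreement with experimental curves of hydrated
#' proteins is not expected; the curve is internally consistent with
#' [pair_distribution()] and [guinier_rg()].  Inputs beyond 2e4 atoms are
#' refused (O(N^2)); coarse-grain to C-alpha per residue first.
#'
#' @param xyz n x 3 coordinates or a `Structure` (form factors from its
#'   elements).
#' @param q_grid q values, 1/Angstrom (>= 0).
#' @param f optional per-atom form factors (default: electron counts, or 1
#'   for bare matrices).
#' @return a `ScatteringCurve`.
#' @export
debye_curve <- function(xyz, q_grid, f = NULL) {
  if (inherits(xyz, "Structure")) {
    if (is.null(f)) f <- element_property(xyz$atoms$element, "electrons")
    xyz <- xyz$xyz
  }
  xyz <- as.matrix(xyz)
  if (is.null(f)) f <- rep(1, nrow(xyz))
  if (any(q_grid < 0)) stop("q must be >= 0")
  if (nrow(xyz) > 2e4)
    stop("O(N^2) guard: > 2e4 atoms; coarse-grain (e.g. C-alpha) first")
  scattering_curve(q_grid, .debye_cpp(xyz, as.numeric(f), as.numeric(q_grid)))
}

#' Guinier radius of gyration from a scattering curve
#'
#' Linear fit of `ln I` against `q^2` on the self-consistently determined
#' low-q range `q * Rg <= qmax_rg` (default 1.3, the standard Guinier
#' validity limit); `Rg = sqrt(-3 * slope)`.
#'
#' @param curve a `ScatteringCurve`.
#' @param qmax_rg dimensionless upper limit of `q * Rg` (default 1.3).
#' @return list with `rg` (Angstrom), `i0`, `fit_range` (indices used) and
#'   `n_iter`.
#' @export
guinier_rg <- function(curve, qmax_rg = 1.3) {
  q <- curve$q; I <- curve$intensity
  pos <- I > 0
  use <- which(pos)
  if (length(use) < 5L) stop("need >= 5 positive-intensity points")
  idx <- use[seq_len(min(20L, length(use)))]
  rg <- NA_real_
  for (it in 1:50) {
    fit <- stats::lm.fit(cbind(1, q[idx]^2), log(I[idx]))
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0)
      stop("invalid Guinier region: non-negative slope of ln I vs q^2")
    rg_new <- sqrt(-3 * slope)
    idx_new <- use[q[use] * rg_new <= qmax_rg]
    if (length(idx_new) < 5L) idx_new <- use[1:5]
    if (is.finite(rg) && abs(rg_new - rg) < 1e-6 * rg_new &&
        identical(idx_new, idx)) { rg <- rg_new; idx <- idx_new; break }
    rg <- rg_new; idx <- idx_new
  }
  list(rg = unname(rg), i0 = unname(exp(fit$coefficients[1])),
       fit_range = idx, n_iter = it)
}

#' Pair-distance distribution P(r) from coordinates
#'
#' Weighted histogram of all pairwise distances (weights `f_i f_j`), the
#' direct-space mate of the Debye curve; `dmax` is the exact maximum
#' pairwise distance.
#'
#' @inheritParams debye_curve
#' @param bin_width histogram bin width, Angstrom (default 1.0).
#' @return object of class `PofR`: `r` (bin midpoints), `p` (weights),
#'   `dmax`.
#' @export
pair_distribution <- function(xyz, bin_width = 1.0, f = NULL) {
  if (inherits(xyz, "Structure")) {
    if (is.null(f)) f <- element_property(xyz$atoms$element, "electrons")
    xyz <- xyz$xyz
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 2L) stop("need >= 2 atoms")
  if (is.null(f)) f <- rep(1, nrow(xyz))
  h <- .pair_hist_cpp(xyz, as.numeric(f), bin_width)
  nb <- length(h$counts)
  obj <- list(r = (seq_len(nb) - 0.5) * bin_width, p = h$counts,
              dmax = h$dmax, bin_width = bin_width)
  class(obj) <- "PofR"
  obj
}

#' @export
print.PofR <- function(x, ...) {
  cat(sprintf("PofR: %d bins of %.2f A, dmax %.2f A, peak at %.1f A\n",
              length(x$r), x$bin_width, x$dmax, x$r[which.max(x$p)]))
  invisible(x)
}

#' Scattering curve from a pair distribution
#'
#' `I(q) = f2_self + sum_bins 2 p(r) sin(qr)/(qr)`; the Fourier mate of the
#' direct Debye sum (agreement within ~1% for bin widths <= 0.5 A).
#'
#' @param pofr a `PofR`.
#' @param q_grid q values.
#' @param f_self sum of squared form factors (the self term, `sum f_i^2`);
#'   default 0 omits it, matching comparisons of pair terms only.
#' @export
curve_from_pofr <- function(pofr, q_grid, f_self = 0) {
  I <- vapply(q_grid, function(q) {
    x <- q * pofr$r
    s <- ifelse(x < 1e-9, 1, sin(x) / x)
    f_self + sum(2 * pofr$p * s)
  }, numeric(1))
  scattering_curve(q_grid, I)
}

#' Reduced chi-square fit of a theoretical curve to an experimental one
#'
#' `chi2 = 1/(N-1) sum ((I_exp - c I_calc)/sigma)^2` with the closed-form
#' least-squares scale `c`.  The theoretical curve is linearly interpolated
#' onto the experimental q grid; q ranges must overlap.
#'
#' @param exp_curve `ScatteringCurve` with `sigma`.
#' @param calc_curve `ScatteringCurve` (theoretical).
#' @return list with `chi2` and `scale`.
#' @export
chi_square_fit <- function(exp_curve, calc_curve) {
  if (is.null(exp_curve$sigma)) stop("experimental curve needs sigma")
  q <- exp_curve$q
  if (min(q) < min(calc_curve$q) - 1e-9 || max(q) > max(calc_curve$q) + 1e-9)
    stop("non-overlapping q ranges")
  Ic <- stats::approx(calc_curve$q, calc_curve$intensity, xout = q)$y
  Ie <- exp_curve$intensity
  s2 <- exp_curve$sigma^2
  cscale <- sum(Ie * Ic / s2) / sum(Ic^2 / s2)
  chi2 <- sum((Ie - cscale * Ic)^2 / s2) / (length(q) - 1)
  list(chi2 = chi2, scale = cscale)
}

#' Per-state chi-square statistics over a trajectory
#'
#' Computes a Debye curve for every (strided) frame, fits it to the
#' experimental curve, and summarises chi2 by conformational state,
#' including the best-fitting frame and its state.
#'
#' @param traj a `Trajectory`.
#' @param labels a `StateLabels` aligned to trajectory frames.
#' @param exp_curve experimental `ScatteringCurve` with `sigma`.
#' @param sel selection of atoms used in the Debye sums (default C-alpha
#'   coarse grain for tractability).
#' @param stride frame stride (default so that about 100 frames are used).
#' @return list with `per_frame` (data.frame frame/state/chi2), `by_state`
#'   (data.frame state/n/mean/sd), `best_frame`, `best_state`, `best_chi2`.
#' @export
per_state_chi2 <- function(traj, labels, exp_curve, sel = NULL,
                           stride = max(1L, n_frames(traj) %/% 100L)) {
  stopifnot(inherits(labels, "StateLabels"))
  if (is.null(sel)) sel <- select_atoms(traj$topology, "name CA")
  idx <- sel_indices(sel, traj$topology)
  f <- element_property(traj$topology$atoms$element[idx], "electrons")
  frames <- seq.int(1L, n_frames(traj), by = stride)
  qg <- exp_curve$q
  chi2 <- vapply(frames, function(fr) {
    calc <- scattering_curve(qg, .debye_cpp(frame_coords(traj, fr)[idx, , drop = FALSE],
                                            f, qg))
    chi_square_fit(exp_curve, calc)$chi2
  }, numeric(1))
  st <- labels$labels[frames]
  per_frame <- data.frame(frame = frames, state = st, chi2 = chi2)
  by_state <- do.call(rbind, lapply(sort(unique(st)), function(s) {
    v <- chi2[st == s]
    data.frame(state = s, n = length(v), mean_chi2 = mean(v),
               sd_chi2 = stats::sd(v))
  }))
  b <- which.min(chi2)
  list(per_frame = per_frame, by_state = by_state,
       best_frame = frames[b], best_state = st[b], best_chi2 = chi2[b])
}
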