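#' Hinge-axis (screw) decomposition of inter-domain motion
#'
#' Superposes conformer B onto conformer A over the fixed domain, then finds
#' the best rigid transform carrying the mobile domain of A onto the mobile
#' domain of aligned B and decomposes it into a screw motion: rotation axis
#' direction, a point on the axis, rotation angle and translation along the
#' axis.  This is the classic hinge analysis of clamshell-like two-lobe
#' domain motions.
#'
#' @param conf_a,conf_b n x 3 coordinate matrices of the two conformers
#'   (same atom order), or `Structure` objects.
#' @param domain_fixed,domain_mobile `AtomSelection`s (or index vectors) of
#'   the reference and moving domains; disjoint, each with >= 3 atoms.
#' @return object of class `HingeResult`: `axis_point` (Angstrom),
#'   `axis_direction` (unit vector), `angle` (degrees, in \[0, 180\]),
#'   `screw_translation` (Angstrom along the axis), `undefined` flag (TRUE
#'   when the mobile-domain rotation is below 1 degree, in which case the
#'   axis is meaningless).
#' @export
hinge_axis <- function(conf_a, conf_b, domain_fixed, domain_mobile) {
  if (inherits(conf_a, "Structure")) conf_a <- conf_a$xyz
  if (inherits(conf_b, "Structure")) conf_b <- conf_b$xyz
  fi <- sel_indices(domain_fixed)
  mi <- sel_indices(domain_mobile)
  if (length(intersect(fi, mi)) > 0L) stop("domain selections must be disjoint")
  if (length(fi) < 3L || length(mi) < 3L) stop("each domain needs >= 3 atoms")
  sp_fix <- superpose(conf_b[fi, , drop = FALSE], conf_a[fi, , drop = FALSE])
  b_al <- apply_transform(conf_b, sp_fix)
  sp_mob <- superpose(conf_a[mi, , drop = FALSE], b_al[mi, , drop = FALSE])
  R <- sp_mob$rotation
  tr <- sp_mob$translation
  cosang <- (sum(diag(R)) - 1) / 2
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (angle < 1) {
    out <- list(axis_point = c(NA_real_, NA_real_, NA_real_),
                axis_direction = c(NA_real_, NA_real_, NA_real_),
                angle = angle, screw_translation = NA_real_, undefined = TRUE)
    class(out) <- "HingeResult"
    return(out)
  }
  u <- .rotation_axis(R, angle)
  s <- sum(u * tr)                          # translation along the axis
  # point on the axis: solve (I - R) p = t_perp on the plane orthogonal to u;
  # adding u u^T makes the system nonsingular and pins p to that plane.
  A <- diag(3) - R + tcrossprod(u)
  p <- solve(A, tr - s * u)
  # report the axis point closest to the mobile-domain centroid
  cm <- colMeans(conf_a[mi, , drop = FALSE])
  p <- p + sum((cm - p) * u) * u
  out <- list(axis_point = as.numeric(p), axis_direction = as.numeric(u),
              angle = angle, screw_translation = s, undefined = FALSE)
  class(out) <- "HingeResult"
  out
}

.rotation_axis <- function(R, angle_deg) {
  if (angle_deg < 179) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    return(v / sqrt(sum(v^2)))
  }
  # near 180 degrees the skew part vanishes; use the +1 eigenvector
  eg <- eigen(R)
  k <- which.min(abs(eg$values - 1))
  v <- Re(eg$vectors[, k])
  v / sqrt(sum(v^2))
}

#' @export
print.HingeResult <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("HingeResult: rotation %.2f deg below 1 deg; axis undefined\n",
                x$angle))
  } else {
    cat(sprintf("HingeResult: %.2f deg about (%.3f, %.3f, %.3f), screw %.2f A\n",
                x$angle, x$axis_direction[1], x$axis_direction[2],
                x$axis_direction[3], x$screw_translation))
  }
  invisible(x)
}
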