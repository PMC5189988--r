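#' Configuration for the synthetic two-lobe hinge generator
#'
#' The generator emulates the statistical structure of a two-lobe (clamshell)
#' protein interconverting between a closed and an open conformation related
#' by a rigid hinge rotation of the second lobe: a sharp single-frame
#' transition, designed state-specific contact pairs, one designed
#' correlation-switching pair, designed state-dependent backbone psi
#' dihedrals, and isotropic Gaussian thermal noise.  It is a statistical
#' stand-in for an MD run, not a physical simulation.
#'
#' @param n_residues_per_lobe residues per lobe (default 100).
#' @param theta open-state hinge rotation, degrees in (0, 180) (default 25).
#' @param n_frames trajectory length (default 2000; 1-ps frame spacing).
#' @param transition_frame index of the first open frame (default
#'   `n_frames/2 + 1`; must leave both states non-empty).
#' @param noise_sigma isotropic Gaussian noise per coordinate, Angstrom
#'   (default 0.3).
#' @param hinge_point,hinge_direction point and unit direction of the hinge
#'   axis (defaults: origin, z axis; the lobes sit astride the origin on x).
#' @param contact_pairs data.frame with columns `res_a`, `res_b`, `closed`,
#'   `open` (target CA-CA distances, Angstrom); `NULL` selects 3 interface
#'   pairs automatically at 3.0 / 10.0 Angstrom.
#' @param dihedral_shifts data.frame with columns `resid`, `closed`, `open`
#'   (mean psi, degrees) and `kappa` (von Mises concentration); `NULL`
#'   designs one lobe-B residue at -45 / +120 with kappa 50.
#' @param corr_sigma amplitude of the shared displacement given to the first
#'   contact pair, whose cross-correlation is designed to switch sign
#'   (positive in the closed state, negative in the open state) at the
#'   transition (default 0.5 Angstrom).
#' @param seed integer RNG seed (default 42).
#' @return object of class `GeneratorConfig` (validated list).
#' @export
generator_config <- function(n_residues_per_lobe = 100L, theta = 25,
                             n_frames = 2000L, transition_frame = NULL,
                             noise_sigma = 0.3,
                             hinge_point = c(0, 0, 0),
                             hinge_direction = c(0, 0, 1),
                             contact_pairs = NULL, dihedral_shifts = NULL,
                             corr_sigma = 0.5, seed = 42L) {
  if (is.null(transition_frame)) transition_frame <- n_frames %/% 2L + 1L
  cfg <- list(n_residues_per_lobe = as.integer(n_residues_per_lobe),
              theta = theta, n_frames = as.integer(n_frames),
              transition_frame = as.integer(transition_frame),
              noise_sigma = noise_sigma, hinge_point = hinge_point,
              hinge_direction = hinge_direction / sqrt(sum(hinge_direction^2)),
              contact_pairs = contact_pairs,
              dihedral_shifts = dihedral_shifts,
              corr_sigma = corr_sigma, seed = as.integer(seed))
  if (cfg$n_residues_per_lobe < 8L) stop("need >= 8 residues per lobe")
  if (!(cfg$theta >= 0 && cfg$theta < 180)) stop("theta must be in [0, 180)")
  if (cfg$transition_frame <= 1L || cfg$transition_frame > cfg$n_frames)
    stop("transition_frame must leave both states non-empty")
  if (cfg$noise_sigma <= 0) stop("noise_sigma must be positive")
  n <- cfg$n_residues_per_lobe
  if (is.null(cfg$contact_pairs)) cfg$contact_pairs <- .default_contacts(n)
  if (is.null(cfg$dihedral_shifts))
    cfg$dihedral_shifts <- data.frame(
      resid = n + if (n >= 20L) min(30L, n - 4L) else 7L,
      closed = -45, open = 120, kappa = 50)
  class(cfg) <- "GeneratorConfig"
  cfg
}

.default_contacts <- function(n) {
  if (n >= 20L) {
    data.frame(res_a = c(n - 2L, n - 10L, n - 18L),
               res_b = n + c(3L, 11L, 19L),
               closed = 3.0, open = 10.0)
  } else {
    data.frame(res_a = c(n - 1L, n - 3L, n - 5L),
               res_b = n + c(2L, 4L, 6L),
               closed = 3.0, open = 10.0)
  }
}

# CA positions of one compact lobe: serpentine walk over a 3-D grid with
# 3.8-Angstrom spacing (the C-alpha virtual bond length).
.lobe_ca_path <- function(n, center) {
  k <- ceiling(n^(1 / 3))
  pts <- matrix(0, n, 3)
  i <- 0L
  for (z in 0:(k - 1)) {
    for (y in 0:(k - 1)) {
      xs <- 0:(k - 1)
      if (y %% 2 == 1) xs <- rev(xs)
      if (z %% 2 == 1) xs <- rev(xs)
      for (x in xs) {
        i <- i + 1L
        if (i > n) break
        pts[i, ] <- c(x, y, z) * 3.8
      }
      if (i >= n) break
    }
    if (i >= n) break
  }
  sweep(pts, 2, colMeans(pts))  |> sweep(2, center, "+")
}

# Full backbone (N, CA, C, O, H) around a CA path.
.build_backbone <- function(ca) {
  n <- nrow(ca)
  xyz <- matrix(0, n * 5L, 3)
  for (r in seq_len(n)) {
    d <- if (r < n) ca[r + 1, ] - ca[r, ] else ca[r, ] - ca[r - 1, ]
    d <- d / sqrt(sum(d^2))
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- .cross3(d, ref); u <- u / sqrt(sum(u^2))
    v <- .cross3(d, u)
    base <- (r - 1L) * 5L
    # N and C sit off the chain axis so backbone dihedrals are well defined
    xyz[base + 1L, ] <- ca[r, ] - 1.20 * d + 0.55 * u  # N
    xyz[base + 2L, ] <- ca[r, ]                        # CA
    xyz[base + 3L, ] <- ca[r, ] + 1.20 * d + 0.55 * u  # C
    xyz[base + 4L, ] <- ca[r, ] + 1.20 * d + 0.55 * u + 1.23 * v  # O
    xyz[base + 5L, ] <- ca[r, ] - 1.20 * d + 0.55 * u - 1.00 * v  # H on N
  }
  xyz
}

.rotate_about_axis <- function(xyz, point, dir, angle_deg) {
  u <- dir / sqrt(sum(dir^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, point) %*% t(R), 2, point, "+")
}

#' Build the closed and open reference conformations
#'
#' Two compact poly-alanine-like lobes (backbone N, CA, C, O and amide H per
#' residue, one chain); the open reference equals the closed one with lobe B
#' rigidly rotated by `theta` about the hinge axis.  Designed contact-pair
#' residues are then translated so each pair sits at its closed-state target
#' distance in the closed reference and its open-state target in the open
#' reference (these residues are the only deviation from the pure rotation).
#'
#' @param cfg a `GeneratorConfig`.
#' @return list with `closed`, `open` (both `Structure`), `lobe_assignment`
#'   (per-residue factor), `adjusted_residues` (contact residues moved off
#'   the pure rotation), `ca_index` (CA atom index per residue).
#' @export
make_two_lobe_model <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  n <- cfg$n_residues_per_lobe
  # lobe separation leaves an inter-lobe gap wider than the 4.5-A contact
  # cutoff in both states, so only designed pairs bridge the lobes
  caA <- .lobe_ca_path(n, c(-13, 0, 0))
  caB <- .lobe_ca_path(n, c(13, 0, 0))
  xyz <- rbind(.build_backbone(caA), .build_backbone(caB))
  nres <- 2L * n
  atoms <- data.frame(
    serial = seq_len(nres * 5L),
    name = rep(c("N", "CA", "C", "O", "H"), nres),
    element = rep(c("N", "C", "C", "O", "H"), nres),
    resname = "ALA",
    resid = rep(seq_len(nres), each = 5L),
    chain = "A", stringsAsFactors = FALSE
  )
  ca_index <- (seq_len(nres) - 1L) * 5L + 2L
  cp <- cfg$contact_pairs
  # place a designed pair's lobe-B residue at the target CA-CA distance,
  # sliding it along the inter-CA direction
  place_pair <- function(m, k, target) {
    if (target <= 0)
      stop("infeasible contact distance for pair ", cp$res_a[k], "-",
           cp$res_b[k])
    a_ca <- m[ca_index[cp$res_a[k]], ]
    b_res <- which(atoms$resid == cp$res_b[k])
    v <- m[ca_index[cp$res_b[k]], ] - a_ca
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6)
      stop("infeasible contact geometry for pair ", cp$res_a[k], "-",
           cp$res_b[k], ": coincident CA atoms")
    m[b_res, ] <- sweep(m[b_res, , drop = FALSE], 2, (target - nv) * v / nv, "+")
    m
  }
  closed_xyz <- xyz
  for (k in seq_len(nrow(cp)))
    closed_xyz <- place_pair(closed_xyz, k, cp$closed[k])
  # the open reference rotates lobe B of the (contact-adjusted) closed one,
  # then re-places the designed pairs at their open-state targets
  lobeB_atoms <- which(atoms$resid > n)
  open_xyz <- closed_xyz
  open_xyz[lobeB_atoms, ] <- .rotate_about_axis(
    closed_xyz[lobeB_atoms, , drop = FALSE],
    cfg$hinge_point, cfg$hinge_direction, cfg$theta)
  for (k in seq_len(nrow(cp)))
    open_xyz <- place_pair(open_xyz, k, cp$open[k])
  list(
    closed = structure_new(atoms, closed_xyz, "synthetic two-lobe (closed)"),
    open = structure_new(atoms, open_xyz, "synthetic two-lobe (open)"),
    lobe_assignment = factor(ifelse(seq_len(nres) <= n, "N-lobe", "C-lobe"),
                             levels = c("N-lobe", "C-lobe")),
    adjusted_residues = unique(cp$res_b),
    ca_index = ca_index
  )
}

#' Draw from a von Mises distribution (degrees)
#'
#' Best-Fisher rejection sampler.
#'
#' @param n sample size.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0; 0 is uniform).
#' @return angles in degrees in `[-180, 180)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  ((out * 180 / pi + mu + 180) %% 360) - 180
}

#' Simulate a two-state hinge trajectory with known ground truth
#'
#' Every frame is the state's reference conformation (closed before the
#' transition frame, open from it on) plus iid Gaussian displacement of
#' width `noise_sigma` per coordinate.  The first designed contact pair
#' additionally shares a correlated displacement whose sign flips at the
#' transition (so its running cross-correlation switches from positive to
#' negative), and designed psi residues are resampled each frame from the
#' state's von Mises distribution.  Deterministic given `cfg$seed`.
#'
#' @param cfg a `GeneratorConfig`.
#' @return list with `trajectory` (a `Trajectory`, 1-ps frames) and `truth`
#'   (a `GroundTruth`: `labels`, `hinge`, `designed_contacts`,
#'   `switching_pair`, `designed_dihedrals`, `lobe_assignment`, `ca_index`,
#'   `references`).
#' @export
simulate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  model <- make_two_lobe_model(cfg)
  A <- n_atoms(model$closed)
  F <- cfg$n_frames
  tf <- cfg$transition_frame
  open_frames <- seq_len(F) >= tf
  coords <- array(stats::rnorm(F * A * 3, sd = cfg$noise_sigma),
                  dim = c(F, A, 3L))
  for (d in 1:3) {
    m <- coords[, , d]
    m[!open_frames, ] <- sweep(m[!open_frames, , drop = FALSE], 2,
                               model$closed$xyz[, d], "+")
    m[open_frames, ] <- sweep(m[open_frames, , drop = FALSE], 2,
                              model$open$xyz[, d], "+")
    coords[, , d] <- m
  }
  at <- model$closed$atoms
  # correlation-switching pair: shared displacement, sign flips when open
  cp <- cfg$contact_pairs
  sw <- if (nrow(cp)) c(cp$res_a[1], cp$res_b[1]) else NULL
  if (cfg$corr_sigma > 0 && !is.null(sw)) {
    g <- matrix(stats::rnorm(F * 3, sd = cfg$corr_sigma), F, 3)
    ia <- which(at$resid == sw[1]); ib <- which(at$resid == sw[2])
    sgn <- ifelse(open_frames, -1, 1)
    for (d in 1:3) {
      coords[, ia, d] <- coords[, ia, d] + g[, d]
      coords[, ib, d] <- coords[, ib, d] + sgn * g[, d]
    }
  }
  # designed psi dihedrals: rotate residue r+1 about the CA(r)-C(r) axis
  ds <- cfg$dihedral_shifts
  for (k in seq_len(nrow(ds))) {
    r <- ds$resid[k]
    target <- numeric(F)
    target[!open_frames] <- rvonmises(sum(!open_frames), ds$closed[k], ds$kappa[k])
    target[open_frames] <- rvonmises(sum(open_frames), ds$open[k], ds$kappa[k])
    iN <- which(at$resid == r & at$name == "N")
    iCA <- which(at$resid == r & at$name == "CA")
    iC <- which(at$resid == r & at$name == "C")
    iNext <- which(at$resid == r + 1L)
    iNn <- which(at$resid == r + 1L & at$name == "N")
    if (!length(iNext)) stop("designed psi residue must have a successor")
    for (t in seq_len(F)) {
      fr <- coords[t, , ]
      cur <- dihedral_angle(fr[iN, ], fr[iCA, ], fr[iC, ], fr[iNn, ])
      axis <- fr[iC, ] - fr[iCA, ]
      rot <- .rotate_about_axis(fr[iNext, , drop = FALSE], fr[iCA, ], axis,
                                target[t] - cur)
      coords[t, iNext, ] <- rot
    }
  }
  traj <- trajectory_new(coords, model$closed)
  labels <- state_labels(as.integer(open_frames), "ground-truth", tf)
  hinge <- list(axis_point = cfg$hinge_point,
                axis_direction = cfg$hinge_direction, angle = cfg$theta,
                screw_translation = 0, undefined = cfg$theta == 0)
  class(hinge) <- "HingeResult"
  truth <- list(labels = labels, hinge = hinge,
                designed_contacts = cp, switching_pair = sw,
                designed_dihedrals = ds,
                lobe_assignment = model$lobe_assignment,
                ca_index = model$ca_index,
                references = model[c("closed", "open")],
                adjusted_residues = model$adjusted_residues)
  class(truth) <- "GroundTruth"
  list(trajectory = traj, truth = truth)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth: transition at frame", x$labels$transition_frame, "\n")
  cat("  designed contacts:",
      paste(x$designed_contacts$res_a, x$designed_contacts$res_b, sep = "-",
            collapse = ", "), "\n")
  invisible(x)
}

#' Designed-contact and decoy attribute series for screening
#'
#' Builds binary contact series for the generator's designed pairs plus
#' label-independent intra-lobe decoy pairs whose CA-CA distances sit close
#' to the contact cutoff (so decoys carry noise-driven flicker rather than
#' state signal).
#'
#' @param traj the synthetic `Trajectory`.
#' @param truth its `GroundTruth`.
#' @param n_decoys number of decoy pairs (default 20).
#' @param cutoff contact cutoff, Angstrom (default 4.5).
#' @param frames frame indices (default all).
#' @return list of `AttributeSeries`; designed series ids start `designed:`.
#' @export
contact_screen_attributes <- function(traj, truth, n_decoys = 20L,
                                      cutoff = 4.5,
                                      frames = seq_len(n_frames(traj))) {
  ca <- truth$ca_index
  cp <- truth$designed_contacts
  out <- list()
  for (k in seq_len(nrow(cp))) {
    s <- contact_series(traj, ca[cp$res_a[k]], ca[cp$res_b[k]], cutoff,
                        frames,
                        id = sprintf("designed:%d-%d", cp$res_a[k], cp$res_b[k]))
    out[[length(out) + 1L]] <- s
  }
  # decoys: sequence-separated intra-lobe pairs at grid-neighbour distance
  n <- length(ca) %/% 2L
  skip <- unique(c(cp$res_a, cp$res_b, truth$adjusted_residues))
  ref <- truth$references$closed$xyz
  cand <- list()
  for (i in seq_len(n - 4L)) {
    if (i %in% skip) next
    for (j in (i + 3L):min(i + 40L, n)) {
      if (j %in% skip) next
      d <- sqrt(sum((ref[ca[i], ] - ref[ca[j], ])^2))
      if (d < cutoff) cand[[length(cand) + 1L]] <- c(i, j)
      if (length(cand) >= n_decoys) break
    }
    if (length(cand) >= n_decoys) break
  }
  for (p in cand) {
    out[[length(out) + 1L]] <- contact_series(
      traj, ca[p[1]], ca[p[2]], cutoff, frames,
      id = sprintf("decoy:%d-%d", p[1], p[2]))
  }
  out
}
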