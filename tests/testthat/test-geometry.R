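euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# brute-force best-fit RMSD by searching a discretised rotation space
grid_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  eval_r <- function(a, b, c) sqrt(mean(rowSums((X %*% t(euler_rot(a, b, c)) - Y)^2)))
  best <- c(0, 0, 0); best_v <- Inf
  step <- 0.25
  for (a in seq(0, 2 * pi, by = step)) for (b in seq(0, pi, by = step))
    for (c in seq(0, 2 * pi, by = step)) {
      v <- eval_r(a, b, c)
      if (v < best_v) { best_v <- v; best <- c(a, b, c) }
    }
  for (step in c(0.05, 0.01, 0.002, 0.0004)) {
    for (da in seq(-step * 6, step * 6, by = step))
      for (db in seq(-step * 6, step * 6, by = step))
        for (dc in seq(-step * 6, step * 6, by = step)) {
          v <- eval_r(best[1] + da, best[2] + db, best[3] + dc)
          if (v < best_v) { best_v <- v; best2 <- best + c(da, db, dc) }
        }
    if (exists("best2")) { best <- best2; rm(best2) }
  }
  best_v
}

test_that("superpose recovers exact matches and known rotations", {
  set.seed(1)
  A <- matrix(rnorm(15), 5, 3)
  sp <- superpose(A, A)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  Rz90 <- euler_rot(pi / 2, 0, 0)
  B <- A %*% t(Rz90) + matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  sp2 <- superpose(A, B)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_transform(A, sp2), B, tolerance = 1e-8)
  expect_error(superpose(A, A[1:4, ]), "mismatch")
})

test_that("Kabsch RMSD matches the rotation-grid search oracle", {
  set.seed(42)
  for (rep in 1:2) {
    A <- matrix(rnorm(15, sd = 2), 5, 3)
    B <- A %*% t(random_rotation()) + matrix(rnorm(15, sd = 0.6), 5, 3)
    expect_equal(superpose(A, B)$rmsd, grid_rmsd(A, B), tolerance = 1e-3)
  }
})

test_that("superposition RMSD is symmetric and degeneracy is flagged", {
  set.seed(2)
  A <- matrix(rnorm(21), 7, 3)
  B <- matrix(rnorm(21), 7, 3)
  expect_equal(superpose(A, B)$rmsd, superpose(B, A)$rmsd, tolerance = 1e-8)
  line <- cbind(1:5, 0, 0)
  expect_warning(sp <- superpose(line, line + 1), "degenerate")
  expect_true(sp$degenerate)
})

test_that("rmsf: zero for static, closed form for oscillation, lobe contrast", {
  top <- structure_new(make_atoms(rep("CA", 2), 1:2), matrix(0, 2, 3))
  static <- traj_from_frames(rep(list(matrix(0, 2, 3)), 6), top)
  expect_equal(unname(rmsf(static)), c(0, 0))
  # atom 1 oscillates +/- d along x around its mean
  d <- 1.7
  fr <- lapply(1:6, function(i) {
    m <- matrix(0, 2, 3); m[1, 1] <- ifelse(i %% 2 == 0, d, -d); m
  })
  expect_equal(unname(rmsf(traj_from_frames(fr, top)))[1], d)
  # two-lobe trajectory: mobile lobe fluctuates more than static lobe
  sim <- small_sim(seed = 9, n_frames = 100)
  truth <- sim$truth
  ca <- atom_selection(truth$ca_index)
  ft <- fit_trajectory(sim$trajectory, ca)
  r <- rmsf(ft, ca)
  lob <- truth$lobe_assignment
  expect_gt(mean(r[lob == "C-lobe"]), mean(r[lob == "N-lobe"]))
})

test_that("distance_series: constants, designed steps, i == j", {
  top <- structure_new(make_atoms(rep("CA", 2), 1:2),
                       rbind(c(0, 0, 0), c(5, 0, 0)))
  traj <- traj_from_frames(rep(list(top$xyz), 4), top)
  expect_equal(distance_series(traj, 1, 2)$values, rep(5, 4))
  expect_warning(z <- distance_series(traj, 1, 1), "zero-distance")
  expect_equal(z$values, rep(0, 4))
  # designed contact pair steps at the transition frame
  sim <- small_sim(seed = 13, n_frames = 80)
  cp <- sim$truth$designed_contacts
  ca <- sim$truth$ca_index
  ds <- distance_series(sim$trajectory, ca[cp$res_a[2]], ca[cp$res_b[2]])
  tf <- sim$truth$labels$transition_frame
  expect_lt(max(ds$values[1:(tf - 1)]), 5)
  expect_gt(min(ds$values[tf:80]), 7)
})

test_that("dihedrals: planar trans case, chirality, independent oracle", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
  dih <- mdstates:::dihedral_angle
  expect_equal(dih(p[1, ], p[2, ], p[3, ], p[4, ]), 180)
  # an oracle built from the two-plane normal formula with triple-product sign
  oracle <- function(p1, p2, p3, p4) {
    n1 <- pracma::cross(p2 - p1, p3 - p2)
    n2 <- pracma::cross(p3 - p2, p4 - p3)
    ang <- acos(sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))) * 180 / pi
    s <- sign(sum(pracma::cross(n1, n2) * (p3 - p2)))
    if (s < 0) -ang else ang
  }
  set.seed(7)
  for (i in 1:20) {
    q <- matrix(rnorm(12), 4, 3)
    got <- dih(q[1, ], q[2, ], q[3, ], q[4, ])
    want <- oracle(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_equal(got, want, tolerance = 1e-8)
    # mirror image flips the sign (chirality)
    qm <- q; qm[, 3] <- -qm[, 3]
    gm <- dih(qm[1, ], qm[2, ], qm[3, ], qm[4, ])
    if (abs(abs(want) - 180) > 1e-6) expect_equal(gm, -want, tolerance = 1e-8)
  }
})

test_that("backbone_dihedrals recovers designed psi distributions", {
  sim <- small_sim(seed = 21, n_frames = 60)
  ds <- sim$truth$designed_dihedrals
  ang <- backbone_dihedrals(sim$trajectory, ds$resid[1])
  tf <- sim$truth$labels$transition_frame
  closed_psi <- ang$psi$values[seq_len(tf - 1)]
  open_psi <- ang$psi$values[tf:60]
  circ_mean <- function(a) atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi
  expect_lt(abs(circ_mean(closed_psi) - ds$closed[1]), 10)
  expect_lt(abs(circ_mean(open_psi) - ds$open[1]), 10)
  expect_true(all(ang$psi$values > -180 & ang$psi$values <= 180))
  # terminal residue: no preceding C -> phi undefined
  first <- backbone_dihedrals(sim$trajectory, 1, frames = 1:2)
  expect_true(all(is.na(first$phi$values)))
  expect_false(anyNA(first$psi$values))
})

test_that("SASA matches analytic spheres and a dense-grid oracle", {
  # isolated atom: full sphere area
  one <- sasa(matrix(0, 1, 3), radii = 1.6, n_points = 960)
  expect_equal(one$total, 4 * pi * 3^2, tolerance = 0.01)
  # two coincident atoms expose exactly one atom's area in total
  two <- sasa(matrix(0, 2, 3), radii = c(1.6, 1.6), n_points = 960)
  expect_equal(two$total, 4 * pi * 3^2, tolerance = 0.01)
  expect_warning(sasa(matrix(0, 1, 3), radii = 1.0, n_points = 16), "precision")
  # 5-atom cluster vs high-density oracle (independent R implementation)
  set.seed(3)
  xyz <- matrix(rnorm(15, sd = 1.5), 5, 3)
  radii <- runif(5, 1.2, 1.9)
  probe <- 1.4
  dense_oracle <- function(xyz, radii, probe, npts = 2e4) {
    # uniform random points on each expanded sphere (independent sampling
    # scheme, distinct from the deterministic spiral in the implementation)
    tot <- 0
    for (i in seq_len(nrow(xyz))) {
      ri <- radii[i] + probe
      u <- matrix(rnorm(npts * 3), npts, 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * ri, 2, xyz[i, ], "+")
      free <- rep(TRUE, npts)
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        rj <- radii[j] + probe
        free <- free & (rowSums(sweep(pts, 2, xyz[j, ])^2) >= rj^2)
      }
      tot <- tot + 4 * pi * ri^2 * mean(free)
    }
    tot
  }
  set.seed(4)
  want <- dense_oracle(xyz, radii, probe)
  got <- sasa(xyz, radii, probe, n_points = 960)$total
  expect_equal(got, want, tolerance = 0.02)
})

test_that("SASA of existing atoms never increases when an occluder is added", {
  set.seed(8)
  xyz <- matrix(rnorm(12, sd = 2), 4, 3)
  radii <- rep(1.7, 4)
  base <- sasa(xyz, radii)$atom_sasa
  with_occ <- sasa(rbind(xyz, c(0.5, 0.5, 0.5)), c(radii, 1.7))$atom_sasa[1:4]
  expect_true(all(with_occ <= base + 1e-9))
})

test_that("hydrogen bonds follow the 3.2 A / 20 degree criterion", {
  # donor N with H, acceptor O of another residue, colinear N-H...O
  mk <- function(d_no, bend_deg = 0) {
    # place H 1 A from N along x; O at distance d_no, with D-H-A angle
    # 180 - bend_deg
    th <- bend_deg * pi / 180
    o <- c(1 + (d_no - 1) * cos(th), (d_no - 1) * sin(th), 0)
    at <- make_atoms(c("N", "H", "O"), c(1, 1, 2), resnames = "GLY")
    structure_new(at, rbind(c(0, 0, 0), c(1, 0, 0), o))
  }
  expect_equal(nrow(detect_hbonds(mk(2.9))), 1L)
  expect_equal(nrow(detect_hbonds(mk(3.3))), 0L)      # beyond 3.2 A
  expect_equal(nrow(detect_hbonds(mk(2.9, 30))), 0L)  # D-H-A 150 deg
  expect_equal(nrow(detect_hbonds(mk(2.9, 15))), 1L)  # within 20 deg of linear
  # hydrogen-free structure: capability error unless fallback requested
  nh <- mk(2.9)
  noH <- structure_new(nh$atoms[-2, ], nh$xyz[-2, ])
  expect_error(detect_hbonds(noH), "no hydrogens")
  expect_equal(nrow(detect_hbonds(noH, heavy_fallback = TRUE)), 1L)
})

test_that("hbond detection equals brute-force enumeration on a synthetic frame", {
  sim <- small_sim(seed = 17, n_frames = 4, n_res = 10)
  s <- sim$trajectory$topology
  xyz <- frame_coords(sim$trajectory, 2)
  got <- detect_hbonds(s, xyz)
  # independent brute force: all N(donor)/O(acceptor) pairs, all hydrogens
  at <- s$atoms
  ang <- function(a, b, c) {
    v1 <- a - b; v2 <- c - b
    acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
  }
  want <- 0L
  for (d in which(at$name == "N")) for (a in which(at$name == "O")) {
    if (at$resid[d] == at$resid[a]) next
    if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > 3.2) next
    for (h in which(at$name == "H"))
      if (sqrt(sum((xyz[h, ] - xyz[d, ])^2)) < 1.25 &&
          ang(xyz[d, ], xyz[h, ], xyz[a, ]) >= 160) { want <- want + 1L; break }
  }
  expect_equal(nrow(got), want)
})

test_that("salt bridges follow the 3.5 A cutoff with acid/base partners", {
  mk <- function(d, basic = TRUE) {
    if (basic) {
      at <- make_atoms(c("OD1", "NZ"), c(1, 2), resnames = c("ASP", "LYS"))
    } else {
      at <- make_atoms(c("OD1", "OD1"), c(1, 2), resnames = c("ASP", "ASP"))
    }
    structure_new(at, rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  expect_equal(nrow(detect_salt_bridges(mk(3.4))), 1L)
  expect_equal(nrow(detect_salt_bridges(mk(3.6))), 0L)
  expect_equal(nrow(detect_salt_bridges(mk(3.0, basic = FALSE))), 0L)
})

test_that("Rg and Dmax: closed forms and rigid-motion invariance", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  expect_equal(max_dimension(rbind(c(0, 0, 0), c(0, 5, 0))), 5)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(max_dimension(cube), sqrt(3))
  expect_error(max_dimension(matrix(0, 1, 3)), "two atoms")
  set.seed(5)
  cloud <- matrix(rnorm(300), 100, 3)
  m <- runif(100, 1, 16)
  for (i in 1:5) {
    Rr <- random_rotation()
    t0 <- rnorm(3, sd = 20)
    moved <- sweep(cloud %*% t(Rr), 2, t0, "+")
    expect_equal(radius_of_gyration(moved, m), radius_of_gyration(cloud, m),
                 tolerance = 1e-8)
    expect_equal(max_dimension(moved), max_dimension(cloud), tolerance = 1e-8)
  }
})

test_that("per-pair hbond and salt-bridge series track presence over frames", {
  # donor/acceptor geometry that alternates between bonded and broken
  at <- make_atoms(c("N", "H", "O"), c(1, 1, 2), resnames = "GLY")
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(5.0, 0, 0))
  top <- structure_new(at, near)
  traj <- traj_from_frames(list(near, far, near, far), top)
  hb <- hbond_series(traj, 1, 2, frames = 1:4)
  expect_equal(hb$values, c(1, 0, 1, 0))
  at2 <- make_atoms(c("OD1", "NZ"), c(1, 2), resnames = c("ASP", "LYS"))
  n2 <- rbind(c(0, 0, 0), c(3.2, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(4.2, 0, 0))
  top2 <- structure_new(at2, n2)
  traj2 <- traj_from_frames(list(n2, n2, f2), top2)
  sb <- saltbridge_series(traj2, 1, 2, frames = 1:3)
  expect_equal(sb$values, c(1, 1, 0))
})
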