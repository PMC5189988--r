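test_that("fit_pca: rank-1 motion, static limit, variance conservation", {
  # one atom moving only along x
  fr <- lapply(1:10, function(i) {
    m <- matrix(0, 3, 3); m[2, ] <- c(3, 1, 0); m[3, ] <- c(6, 0, 2)
    m[1, 1] <- i * 0.5
    m
  })
  traj <- traj_from_frames(fr)
  mod <- suppressWarnings(fit_pca(traj))
  expect_equal(mod$variance_fraction[1], 1, tolerance = 1e-10)
  # static trajectory: all eigenvalues zero
  stat <- traj_from_frames(rep(list(fr[[1]]), 5))
  expect_equal(max(suppressWarnings(fit_pca(stat))$eigenvalues), 0,
               tolerance = 1e-12)
  # eigenvalue sum equals total coordinate variance
  set.seed(6)
  fr2 <- lapply(1:40, function(i) matrix(rnorm(9), 3, 3))
  traj2 <- traj_from_frames(fr2)
  mod2 <- fit_pca(traj2)
  X <- do.call(rbind, lapply(fr2, function(m) as.numeric(t(m))))
  expect_equal(sum(mod2$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-6)
  # orthonormal columns, descending eigenvalues
  G <- crossprod(mod2$eigenvectors)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8)
  expect_true(all(diff(mod2$eigenvalues) <= 1e-12))
})

test_that("fit_pca matches a direct covariance eigendecomposition oracle", {
  set.seed(10)
  fr <- lapply(1:10, function(i) matrix(rnorm(9, sd = 2), 3, 3))
  traj <- traj_from_frames(fr)
  mod <- suppressWarnings(fit_pca(traj))
  X <- do.call(rbind, lapply(fr, function(m) as.numeric(t(m))))
  C <- stats::cov(X)
  want <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  expect_equal(mod$eigenvalues, pmax(want, 0), tolerance = 1e-10)
})

test_that("projection identities hold and synthetic PC1 is bimodal", {
  set.seed(12)
  fr <- lapply(1:60, function(i) matrix(rnorm(12), 4, 3))
  traj <- traj_from_frames(fr)
  mod <- fit_pca(traj)
  pr <- project_pca(traj, mod, k = 5)
  for (j in 1:5)
    expect_equal(var(pr[, j]), mod$eigenvalues[j], tolerance = 1e-8)
  # projecting the mean structure gives the zero vector
  mean_traj <- traj_from_frames(list(
    matrix(mod$mean, 4, 3, byrow = TRUE), matrix(mod$mean, 4, 3, byrow = TRUE)),
    traj$topology)
  expect_equal(max(abs(project_pca(mean_traj, mod, k = 3))), 0,
               tolerance = 1e-8)
  # two-state trajectory: PC1 bimodal, modes > 4 pooled SDs apart
  sim <- small_sim(seed = 19, n_frames = 150)
  ca <- atom_selection(sim$truth$ca_index)
  ft <- fit_trajectory(sim$trajectory, ca)
  m2 <- suppressWarnings(fit_pca(ft, ca))
  p1 <- project_pca(ft, m2, ca, 1)[, 1]
  lab <- sim$truth$labels$labels
  pooled_sd <- sqrt(mean(c(var(p1[lab == 0]), var(p1[lab == 1]))))
  expect_gt(abs(mean(p1[lab == 1]) - mean(p1[lab == 0])), 4 * pooled_sd)
})

test_that("kmeans_states separates two Gaussians and the elbow sits at k = 2", {
  set.seed(31)
  x <- c(rnorm(500, -5, 0.5), rnorm(500, 5, 0.5))
  truth <- rep(c(0L, 1L), each = 500)
  km <- kmeans_states(cbind(x), 2, seed = 5)
  acc <- max(mean(km$labels$labels == truth), mean(km$labels$labels != truth))
  expect_gte(acc, 0.99)
  expect_gte(km$bss_tss, 0.95)
  expect_equal(kmeans_states(cbind(x), 1, seed = 5)$bss_tss, 0)
  scan <- bss_tss_scan(cbind(x), 1:6, n_restarts = 10, seed = 2)
  gains <- diff(scan$bss_tss)
  expect_equal(which.max(gains), 1L)  # largest gain moving from k=1 to k=2
  # deterministic given seed
  km2 <- kmeans_states(cbind(x), 2, seed = 5)
  expect_identical(km$labels$labels, km2$labels$labels)
})

test_that("k-means label accuracy holds across 20 seeds", {
  set.seed(77)
  x <- c(rnorm(500, -5, 0.5), rnorm(500, 5, 0.5))
  truth <- rep(c(0L, 1L), each = 500)
  for (s in 1:20) {
    km <- kmeans_states(cbind(x), 2, n_restarts = 5, seed = s)
    acc <- max(mean(km$labels$labels == truth), mean(km$labels$labels != truth))
    expect_gte(acc, 0.99)
  }
})

test_that("cluster 0 is anchored to the first frame (closed start)", {
  x <- c(rnorm(50, -3, 0.2), rnorm(50, 3, 0.2))
  km <- kmeans_states(cbind(x), 2, seed = 1)
  expect_equal(km$labels$labels[1], 0L)
  # flipping the series still labels frame 1 as closed
  km_rev <- kmeans_states(cbind(rev(x)), 2, seed = 1)
  expect_equal(km_rev$labels$labels[1], 0L)
})

test_that("distance-threshold state assignment finds the transition", {
  const <- assign_states_by_distance(rep(3, 50), 4)
  expect_true(all(const$labels == 0L))
  expect_null(const$transition_frame)
  expect_match(const$method, "no transition")
  step <- c(rep(3, 99), rep(10, 101))
  st <- assign_states_by_distance(step, 4)
  expect_equal(st$transition_frame, 100L)
  # generator ground truth from a designed contact-pair distance
  sim <- small_sim(seed = 23, n_frames = 200)
  cp <- sim$truth$designed_contacts
  ca <- sim$truth$ca_index
  ds <- distance_series(sim$trajectory, ca[cp$res_a[2]], ca[cp$res_b[2]])
  got <- assign_states_by_distance(ds, mean(c(cp$closed[2], cp$open[2])))
  expect_gte(mean(got$labels == sim$truth$labels$labels), 0.98)
})

test_that("free-energy landscape is normalised, flat for uniform, two-welled", {
  set.seed(41)
  u <- cbind(runif(20000), runif(20000))
  fel <- free_energy_landscape(u, bins = 4)
  expect_equal(min(fel$dG), 0)
  expect_lt(max(fel$dG), log(2))
  # single point: one zero bin, everything else unbounded
  one <- suppressWarnings(free_energy_landscape(cbind(0, 0), bins = 5))
  expect_equal(sum(is.finite(one$dG)), 1L)
  expect_equal(min(one$dG), 0)
  expect_error(free_energy_landscape(u, bins = 1), "bins")
  # two Gaussian wells with a >= 1 kT barrier between them
  n <- 10000
  g <- cbind(c(rnorm(n, -5, 0.8), rnorm(n, 5, 0.8)), rnorm(2 * n, 0, 0.8))
  fel2 <- free_energy_landscape(g, bins = 30)
  mid_col <- which.min(abs((fel2$x_breaks[-1] + head(fel2$x_breaks, -1)) / 2))
  barrier <- min(fel2$dG[mid_col, ], na.rm = TRUE)
  expect_gte(barrier, 1)
  expect_equal(min(fel2$dG), 0)
})

test_that("hinge_axis recovers a constructed rotation and flags identity", {
  set.seed(51)
  fixed <- matrix(rnorm(30, sd = 3), 10, 3)
  mobile <- sweep(matrix(rnorm(30, sd = 3), 10, 3), 2, c(8, 0, 0), "+")
  conf_a <- rbind(fixed, mobile)
  rot <- mdstates:::.rotate_about_axis(mobile, c(0, 0, 0), c(0, 0, 1), 20)
  conf_b <- rbind(fixed, rot)
  h <- hinge_axis(conf_a, conf_b, 1:10, 11:20)
  expect_equal(h$angle, 20, tolerance = 0.1)
  axis_err <- acos(abs(sum(h$axis_direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(axis_err, 1)
  expect_false(h$undefined)
  # identical conformers: axis undefined
  h0 <- hinge_axis(conf_a, conf_a, 1:10, 11:20)
  expect_true(h0$undefined)
  expect_error(hinge_axis(conf_a, conf_b, 1:10, 8:20), "disjoint")
})

test_that("hinge angle is invariant under global rigid motion", {
  set.seed(52)
  fixed <- matrix(rnorm(30, sd = 3), 10, 3)
  mobile <- sweep(matrix(rnorm(30, sd = 3), 10, 3), 2, c(8, 0, 0), "+")
  conf_a <- rbind(fixed, mobile)
  conf_b <- rbind(fixed, mdstates:::.rotate_about_axis(mobile, c(1, 2, 0),
                                                       c(0, 1, 1), 35))
  h <- hinge_axis(conf_a, conf_b, 1:10, 11:20)
  Rg <- random_rotation(); tg <- rnorm(3, sd = 10)
  move <- function(m) sweep(m %*% t(Rg), 2, tg, "+")
  h2 <- hinge_axis(move(conf_a), move(conf_b), 1:10, 11:20)
  expect_equal(h2$angle, h$angle, tolerance = 0.1)
})

test_that("hinge_axis recovers the generator's hinge from the references", {
  cfg <- generator_config(seed = 3)
  mod <- make_two_lobe_model(cfg)
  refs <- mod[c("closed", "open")]
  at <- refs$closed$atoms
  n <- cfg$n_residues_per_lobe
  # the designed contact residues deviate from the rigid rotation by
  # construction; the hinge ground truth applies to the rigid remainder
  keep <- !(at$resid %in% mod$adjusted_residues)
  h <- hinge_axis(refs$closed, refs$open,
                  atom_selection(which(at$resid <= n & keep)),
                  atom_selection(which(at$resid > n & keep)))
  expect_lt(abs(h$angle - cfg$theta) / cfg$theta, 0.10)
  axis_err <- acos(abs(sum(h$axis_direction * cfg$hinge_direction))) * 180 / pi
  expect_lt(axis_err, 5)
})
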