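# trajectory of independent 3-D signals per "residue", from an F x R list of
# displacement matrices added to fixed positions
disp_traj <- function(disp, spacing = 10) {
  R <- length(disp)
  f <- nrow(disp[[1]])
  frames <- lapply(seq_len(f), function(t) {
    m <- matrix(0, R, 3)
    for (r in seq_len(R)) m[r, ] <- c(spacing * r, 0, 0) + disp[[r]][t, ]
    m
  })
  traj_from_frames(frames)
}

test_that("dccm: perfect correlation, anticorrelation, direct-sum oracle", {
  set.seed(26)
  e <- matrix(rnorm(60), 20, 3)
  same <- disp_traj(list(e, e))
  expect_equal(dccm(same)$values[1, 2], 1, tolerance = 1e-12)
  mirror <- disp_traj(list(e, -e))
  expect_equal(dccm(mirror)$values[1, 2], -1, tolerance = 1e-12)
  # 3-atom, 5-frame toy against explicit summation
  disp <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3),
               matrix(rnorm(15), 5, 3))
  traj <- disp_traj(disp)
  got <- dccm(traj)$values
  oracle <- function(i, j) {
    di <- sweep(disp[[i]], 2, colMeans(disp[[i]]))
    dj <- sweep(disp[[j]], 2, colMeans(disp[[j]]))
    num <- mean(rowSums(di * dj))
    num / sqrt(mean(rowSums(di * di)) * mean(rowSums(dj * dj)))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(got[i, j], oracle(i, j), tolerance = 1e-12)
  expect_true(isSymmetric(got, tol = 1e-10))
  expect_equal(diag(got), rep(1, 3))
})

test_that("dccm is invariant under uniform global translation", {
  set.seed(27)
  disp <- list(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3))
  traj <- disp_traj(disp)
  shift <- traj
  for (t in 1:10) shift$coords[t, , ] <- shift$coords[t, , ] + 5
  expect_equal(dccm(shift)$values, dccm(traj)$values, tolerance = 1e-10)
})

test_that("immobile atoms yield flagged NA correlation rows", {
  set.seed(28)
  disp <- list(matrix(rnorm(30), 10, 3), matrix(0, 10, 3))
  expect_warning(cm <- dccm(disp_traj(disp)), "immobile")
  expect_true(all(is.na(cm$values[2, ])))
  expect_equal(cm$values[1, 1], 1)
})

# correlated pair with common-signal construction: corr = s2c/(s2c + s2i)
corr_pair_disp <- function(f, rho, flip_at = NULL, seed = 1) {
  set.seed(seed)
  s2c <- rho; s2i <- 1 - rho
  g <- matrix(rnorm(f * 3, sd = sqrt(s2c)), f, 3)
  e1 <- matrix(rnorm(f * 3, sd = sqrt(s2i)), f, 3)
  e2 <- matrix(rnorm(f * 3, sd = sqrt(s2i)), f, 3)
  sgn <- rep(1, f)
  if (!is.null(flip_at)) sgn[flip_at:f] <- -1
  list(g + e1, sgn * g + e2)
}

test_that("RCC with window = F equals the full-trajectory DCCM entry", {
  d <- corr_pair_disp(200, 0.8, seed = 29)
  traj <- disp_traj(d)
  full <- dccm(traj)$values[1, 2]
  rcc <- running_cross_correlation(traj, pair = c(1, 2), window = 200,
                                   by = "index")
  expect_equal(length(rcc$values), 1L)
  expect_equal(rcc$values, full, tolerance = 1e-12)
})

test_that("RCC of a stationary pair hovers at its correlation; sd shrinks", {
  d <- corr_pair_disp(2000, 0.8, seed = 30)
  traj <- disp_traj(d)
  full <- dccm(traj)$values[1, 2]
  r200 <- running_cross_correlation(traj, pair = c(1, 2), window = 200,
                                    by = "index")
  r600 <- running_cross_correlation(traj, pair = c(1, 2), window = 600,
                                    by = "index")
  expect_lt(abs(mean(r200$values) - full), 0.05)
  expect_lt(sd(r600$values), sd(r200$values))
  expect_equal(r200$midpoints[1], 1 + 199 / 2)
  expect_error(running_cross_correlation(traj, pair = c(1, 2), window = 3000,
                                         by = "index"), "window")
})

test_that("RCC crosses zero near a designed correlation switch", {
  f <- 1000
  d <- corr_pair_disp(f, 0.9, flip_at = f / 2, seed = 33)
  traj <- disp_traj(d)
  W <- 100
  rcc <- running_cross_correlation(traj, pair = c(1, 2), window = W,
                                   by = "index")
  crossing <- rcc$midpoints[min(which(rcc$values < 0))]
  expect_lt(abs(crossing - f / 2), W / 2 + 1)
  expect_gt(mean(rcc$values[rcc$midpoints < f / 2 - W]), 0.7)
  expect_lt(mean(rcc$values[rcc$midpoints > f / 2 + W]), -0.7)
})

test_that("RCC deviation map: stationary noise floor and switching maximum", {
  set.seed(34)
  f <- 3000
  # five stationary pairs plus one switching pair (residues 1 and 2)
  disp <- c(corr_pair_disp(f, 0.9, flip_at = f / 2, seed = 35),
            lapply(1:4, function(i) matrix(rnorm(f * 3), f, 3)))
  traj <- disp_traj(disp)
  m <- rcc_deviation_map(traj, window = f / 10)
  expect_equal(m$sigma, t(m$sigma))
  expect_equal(diag(m$sigma), rep(0, 6))
  # all-stationary sub-map stays at the sampling noise floor
  stationary <- m$sigma[3:6, 3:6]
  expect_lte(max(stationary), 0.05 + 3 / sqrt(f / 10))
  # the switching pair attains the global maximum
  mx <- which(m$sigma == max(m$sigma), arr.ind = TRUE)[1, ]
  expect_setequal(as.integer(mx), c(1L, 2L))
})

test_that("RCC deviation mean map equals the averaged single-pair RCC", {
  d <- corr_pair_disp(400, 0.6, seed = 36)
  traj <- disp_traj(d)
  m <- rcc_deviation_map(traj, window = 40)
  r <- running_cross_correlation(traj, pair = c(1, 2), window = 40,
                                 by = "index")
  expect_equal(m$mean[1, 2], mean(r$values), tolerance = 1e-10)
  expect_equal(m$sigma[1, 2], sd(r$values) * sqrt((length(r$values) - 1) /
                                                  length(r$values)),
               tolerance = 1e-10)
})

test_that("distance fluctuations: rigidity, rigid-motion invariance, oracle", {
  set.seed(37)
  base <- matrix(rnorm(15, sd = 4), 5, 3)
  rigid <- lapply(1:8, function(i) {
    sweep(base %*% t(random_rotation()), 2, rnorm(3, sd = 5), "+")
  })
  m <- distance_fluctuation_map(traj_from_frames(rigid))
  expect_lt(max(m), 1e-8)
  # explicit 2-residue 3-frame hand computation (population sd)
  fr <- list(rbind(c(0, 0, 0), c(3, 0, 0)),
             rbind(c(0, 0, 0), c(4, 0, 0)),
             rbind(c(0, 0, 0), c(5, 0, 0)))
  m2 <- distance_fluctuation_map(traj_from_frames(fr))
  expect_equal(m2[1, 2], sqrt(mean((c(3, 4, 5) - 4)^2)), tolerance = 1e-12)
  # two-lobe synthetic: inter-lobe fluctuations exceed intra-lobe ones
  sim <- small_sim(seed = 38, n_frames = 100)
  ca <- atom_selection(sim$truth$ca_index)
  dm <- distance_fluctuation_map(sim$trajectory, ca)
  lob <- sim$truth$lobe_assignment
  inter <- dm[lob == "N-lobe", lob == "C-lobe"]
  intraA <- dm[lob == "N-lobe", lob == "N-lobe"]
  expect_gt(mean(inter), mean(intraA[upper.tri(intraA)]))
})
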