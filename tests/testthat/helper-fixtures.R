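# Fixture builders shared across test files.  Everything is generated in
# code; nothing binary is stored.

# quick atom-table builder
make_atoms <- function(names, resids, resnames = "ALA", chains = "A",
                       elements = NULL) {
  n <- length(names)
  if (is.null(elements)) elements <- guess_element(names, rep(resnames, length.out = n))
  data.frame(serial = seq_len(n), name = names, element = elements,
             resname = rep(resnames, length.out = n),
             resid = rep(resids, length.out = n),
             chain = rep(chains, length.out = n), stringsAsFactors = FALSE)
}

# a 3-residue peptide-like structure (N, CA, C, O per residue, no H)
make_tripeptide <- function() {
  names <- rep(c("N", "CA", "C", "O"), 3)
  resids <- rep(1:3, each = 4)
  xyz <- matrix(0, 12, 3)
  for (r in 1:3) {
    base <- (r - 1) * 4
    x0 <- (r - 1) * 3.8
    xyz[base + 1, ] <- c(x0 - 1.2, 0.5, 0)
    xyz[base + 2, ] <- c(x0, 0, 0)
    xyz[base + 3, ] <- c(x0 + 1.2, 0.5, 0)
    xyz[base + 4, ] <- c(x0 + 1.2, 0.5, 1.23)
  }
  structure_new(make_atoms(names, resids), xyz, "tripeptide")
}

# trajectory with explicit per-frame coordinates from a list of matrices
traj_from_frames <- function(frames, topology = NULL) {
  A <- nrow(frames[[1]])
  if (is.null(topology)) {
    topology <- structure_new(
      make_atoms(rep("CA", A), seq_len(A)),
      frames[[1]])
  }
  arr <- array(0, dim = c(length(frames), A, 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  trajectory_new(arr, topology)
}

# small synthetic system used by several modules
small_sim <- function(seed = 11, n_frames = 120, n_res = 20) {
  simulate_trajectory(generator_config(
    n_residues_per_lobe = n_res, n_frames = n_frames, seed = seed))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3)
}

minimal_pdb_text <- function() {
  c("HEADER    TEST",
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00  0.00           C",
    "END")
}
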