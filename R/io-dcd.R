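#' Read a CHARMM/NAMD DCD trajectory file
#'
#' Minimal reader for the CHARMM binary DCD dialect (single precision,
#' Fortran record markers, optional per-frame unit-cell records).  The header
#' timestep (DELTA, stored here in ps) and save frequency are used to build
#' frame times; when DELTA is absent or zero, 1-ps spacing is assumed.
#'
#' @param path DCD file path.
#' @return list with `coords` (`[F x A x 3]` array, Angstrom) and `times` (ps).
#' @export
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- .Platform$endian
  m <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (m != 84L) {
    endian <- if (endian == "little") "big" else "little"
    seek(con, 0)
    m <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (m != 84L) stop("not a DCD file (bad header record length)")
  }
  magic <- readChar(con, 4, useBytes = TRUE)
  if (magic != "CORD") stop("not a DCD file (missing CORD magic)")
  icntrl_raw <- readBin(con, "raw", 80)
  readBin(con, "integer", 1, size = 4, endian = endian)  # trailing marker
  icntrl <- readBin(icntrl_raw, "integer", 20, size = 4, endian = endian)
  nset <- icntrl[1]; istart <- icntrl[2]; nsavc <- icntrl[3]
  charmm_version <- icntrl[20]
  delta <- if (charmm_version > 0) {
    readBin(icntrl_raw[37:40], "numeric", 1, size = 4, endian = endian)
  } else {
    readBin(icntrl_raw[37:44], "numeric", 1, size = 8, endian = endian)
  }
  has_cell <- charmm_version > 0 && icntrl[11] == 1L
  # title block
  n <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "raw", n)
  readBin(con, "integer", 1, size = 4, endian = endian)
  # natom block
  readBin(con, "integer", 1, size = 4, endian = endian)
  natom <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  frames <- list()
  repeat {
    if (has_cell) {
      mk <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (length(mk) == 0L) break
      readBin(con, "raw", mk)
      readBin(con, "integer", 1, size = 4, endian = endian)
    }
    xyz <- matrix(0, natom, 3)
    ok <- TRUE
    for (d in 1:3) {
      mk <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (length(mk) == 0L) { ok <- FALSE; break }
      v <- readBin(con, "numeric", natom, size = 4, endian = endian)
      readBin(con, "integer", 1, size = 4, endian = endian)
      xyz[, d] <- v
    }
    if (!ok) break
    frames[[length(frames) + 1L]] <- xyz
  }
  nf <- length(frames)
  if (nf < 2L) stop("trajectory error: DCD contains fewer than 2 frames")
  coords <- array(0, dim = c(nf, natom, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  dt <- if (is.finite(delta) && delta > 0) delta * max(nsavc, 1L) else 1
  t0 <- if (is.finite(delta) && delta > 0) delta * istart else 1
  list(coords = coords, times = t0 + dt * (seq_len(nf) - 1L))
}

#' Write a Trajectory to a CHARMM-dialect DCD file
#'
#' Single-precision coordinates; the header DELTA field stores the frame
#' spacing in ps so that [read_dcd()] round-trips frame times.
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  natom <- dim(traj$coords)[2]
  dt <- traj$times[2] - traj$times[1]
  icntrl <- integer(20)
  icntrl[1] <- nf          # NSET
  icntrl[2] <- 1L          # ISTART
  icntrl[3] <- 1L          # NSAVC
  icntrl[20] <- 24L        # CHARMM version flag -> DELTA is float32
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, 4, eos = NULL)
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(as.numeric(dt), con, size = 4)
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", "written by mdstates")
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, 80, eos = NULL)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(natom, con, size = 4)
  writeBin(4L, con, size = 4)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    for (d in 1:3) {
      writeBin(4L * natom, con, size = 4)
      writeBin(as.numeric(fr[, d]), con, size = 4)
      writeBin(4L * natom, con, size = 4)
    }
  }
  invisible(path)
}
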