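#' Read a PDB file into a Structure
#'
#' Parses ATOM/HETATM records of the first MODEL (via bio3d), infers elements
#' from columns 77-78 or the atom name, assigns masses and Bondi van der
#' Waals radii from the bundled element table, and resolves alternate
#' locations by keeping the highest-occupancy copy (ties: first in file).
#'
#' @param path PDB file path.
#' @param keep_hetatm keep HETATM records (default TRUE).
#' @return a `Structure`.
#' @export
read_pdb <- function(path, keep_hetatm = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  .check_pdb_coords(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)
  # alternate locations: keep highest occupancy, tie -> first occurrence
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$chain, at$resid, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt])) {
      rows <- which(key == k)
      if (length(rows) > 1L) {
        best <- rows[which.max(occ[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- guess_element(at$elety[miss], at$resid[miss])
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = toupper(trimws(elem)),
    resname = trimws(at$resid), resid = at$resno, chain = ifelse(is.na(at$chain), "", at$chain),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  structure_new(atoms, cbind(at$x, at$y, at$z), title = basename(path))
}

# Fail with the offending line when a coordinate field is non-numeric.
.check_pdb_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  endmdl <- which(grepl("^ENDMDL", lines))
  if (length(endmdl)) rec[seq_along(lines) > endmdl[1]] <- FALSE
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("PDB parse error at line ", i, ": record too short")
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("PDB parse error at line ", i, ": non-numeric coordinate field in '",
             trimws(ln), "'")
    }
  }
  invisible(TRUE)
}

#' Write a Structure (or Trajectory) as a (multi-model) PDB file
#'
#' @param x a `Structure` or `Trajectory`.
#' @param path output path.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "Structure")) {
    .write_pdb_models(x, list(x$xyz), path)
  } else if (inherits(x, "Trajectory")) {
    frames <- lapply(seq_len(n_frames(x)), function(f) frame_coords(x, f))
    .write_pdb_models(x$topology, frames, path)
  } else stop("x must be a Structure or Trajectory")
  invisible(path)
}

.write_pdb_models <- function(s, frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- s$atoms
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]
    nm <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                 sprintf("%-4s", at$name))
    lines <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000L, nm, "", substr(at$resname, 1, 3),
      substr(paste0(at$chain, "A"), 1, 1), at$resid %% 10000L, "",
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, at$element
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

#' Read a trajectory from a multi-model PDB or DCD file
#'
#' @param path multi-model PDB (`.pdb`) or CHARMM/NAMD DCD (`.dcd`) file.
#' @param topology a `Structure` whose atom count matches the file.
#' @param times optional explicit frame times (ps); otherwise DCD header
#'   times are used when present, else 1-ps spacing.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, topology, times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    dcd <- read_dcd(path)
    if (dim(dcd$coords)[2] != n_atoms(topology))
      stop("topology error: DCD has ", dim(dcd$coords)[2], " atoms, topology ",
           n_atoms(topology))
    if (is.null(times)) times <- dcd$times
    return(trajectory_new(dcd$coords, topology, times))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  if (nf < 2L) stop("trajectory error: file contains fewer than 2 frames")
  na <- ncol(xyz) / 3L
  if (na != n_atoms(topology))
    stop("topology error: file has ", na, " atoms, topology ", n_atoms(topology))
  coords <- array(0, dim = c(nf, na, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  trajectory_new(coords, topology, times)
}
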