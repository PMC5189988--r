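#' Build a molecular structure object
#'
#' A `Structure` couples an atom metadata table with an A x 3 coordinate
#' matrix (Angstrom).  It is the topology shared by every trajectory frame.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain` (and optionally `mass`, `radius`; these are
#'   filled from [element_table()] when absent).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param title free-text description.
#' @return object of class `Structure`.
#' @export
structure_new <- function(atoms, xyz, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(c("serial", "name", "element", "resname", "resid", "chain")
           %in% names(atoms)))
    stop("atoms table missing required columns")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("xyz must be an n_atoms x 3 matrix")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(atoms$mass))   atoms$mass   <- element_property(atoms$element, "mass")
  if (is.null(atoms$radius)) atoms$radius <- element_property(atoms$element, "radius")
  if (any(atoms$mass <= 0) || any(atoms$radius <= 0))
    stop("masses and radii must be positive")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  obj <- list(atoms = atoms, xyz = xyz, title = as.character(title))
  class(obj) <- "Structure"
  obj
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", if (nzchar(x$title)) x$title else "<untitled>", "\n")
  cat("  atoms:   ", nrow(x$atoms), "\n")
  cat("  residues:", length(unique(paste(x$atoms$chain, x$atoms$resid))), "\n")
  cat("  chains:  ", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

#' Select atoms with a minimal query grammar
#'
#' The grammar supports clauses `name <atom names>`, `resid <ids or a:b
#' ranges>`, `resname <residue names>`, `chain <chain ids>`, and `elety`-free
#' conjunction with the keyword `and`.  Values within a clause are
#' whitespace-separated alternatives (an implicit OR), e.g.
#' `"name CA CB and chain A"` or `"resid 44 and name OG"`.
#'
#' @param s a `Structure`.
#' @param query selection expression string.
#' @param label optional label stored on the selection.
#' @return an `AtomSelection`: list with sorted unique `indices` (1-based into
#'   the atom table) and `label`.  An empty selection is allowed and flagged
#'   with a warning.
#' @export
select_atoms <- function(s, query, label = query) {
  stopifnot(inherits(s, "Structure"))
  clauses <- strsplit(trimws(query), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0L || !nzchar(clauses[1]))
    stop("selection grammar error: empty query")
  keep <- rep(TRUE, n_atoms(s))
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    key <- toks[1]
    vals <- toks[-1]
    if (length(vals) == 0L)
      stop("selection grammar error: clause '", cl, "' has no value")
    keep <- keep & switch(key,
      name    = toupper(s$atoms$name) %in% toupper(vals),
      resname = toupper(s$atoms$resname) %in% toupper(vals),
      chain   = s$atoms$chain %in% vals,
      resid   = s$atoms$resid %in% .parse_resid_values(vals),
      stop("selection grammar error: unknown keyword '", key, "'")
    )
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    warning("selection '", query, "' matched no atoms")
  atom_selection(idx, label = label)
}

.parse_resid_values <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+[:-][0-9]+$", v)) {
      ab <- as.integer(strsplit(v, "[:-]")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop("selection grammar error: bad resid token '", v, "'")
    }
  }
  out
}

#' Construct an atom selection from explicit indices
#'
#' @param indices integer atom indices (1-based); deduplicated and sorted.
#' @param label free text.
#' @export
atom_selection <- function(indices, label = "") {
  indices <- sort(unique(as.integer(indices)))
  if (any(indices < 1L)) stop("selection indices must be >= 1")
  obj <- list(indices = indices, label = label)
  class(obj) <- "AtomSelection"
  obj
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat("AtomSelection '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

# Resolve a selection-ish argument to integer indices.
sel_indices <- function(sel, s = NULL) {
  if (inherits(sel, "AtomSelection")) {
    idx <- sel$indices
  } else {
    idx <- sort(unique(as.integer(sel)))
  }
  if (!is.null(s) && length(idx) && max(idx) > n_atoms(s))
    stop("selection index out of range")
  idx
}
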