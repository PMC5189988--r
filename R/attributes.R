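#' Construct an attribute time series
#'
#' An `AttributeSeries` is one structural attribute tracked over (possibly
#' strided) frames: a hydrogen bond, salt bridge, contact, dihedral, SASA or
#' distance.  Binary kinds (`hbond`, `saltbridge`, `contact`) contain only
#' 0/1 values.
#'
#' @param id attribute identifier string.
#' @param kind one of `"hbond"`, `"saltbridge"`, `"contact"`, `"phi"`,
#'   `"psi"`, `"sasa"`, `"distance"`.
#' @param values numeric values, one per entry of `frame_index`.
#' @param frame_index integer frame indices the values were computed at.
#' @export
attribute_series <- function(id, kind, values, frame_index) {
  kind <- match.arg(kind, c("hbond", "saltbridge", "contact", "phi", "psi",
                            "sasa", "distance"))
  values <- as.numeric(values)
  frame_index <- as.integer(frame_index)
  if (length(values) != length(frame_index))
    stop("values and frame_index must have equal length")
  if (kind %in% c("hbond", "saltbridge", "contact") &&
      !all(values[!is.na(values)] %in% c(0, 1)))
    stop("binary attribute kinds must contain only 0/1")
  obj <- list(id = id, kind = kind, values = values, frame_index = frame_index)
  class(obj) <- "AttributeSeries"
  obj
}

#' @export
print.AttributeSeries <- function(x, ...) {
  cat(sprintf("AttributeSeries [%s] %s: %d frames, mean %.3f\n",
              x$kind, x$id, length(x$values), mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Interatomic distance time series
#'
#' @param traj a `Trajectory`.
#' @param i,j atom indices (1-based).
#' @param frames frame indices to evaluate (default all).
#' @return `AttributeSeries` of kind `"distance"` (Angstrom).
#' @export
distance_series <- function(traj, i, j, frames = seq_len(n_frames(traj))) {
  a <- dim(traj$coords)[2]
  if (i < 1 || j < 1 || i > a || j > a) stop("atom index out of range")
  if (i == j) warning("i == j: zero-distance series")
  d <- sqrt(rowSums((traj$coords[frames, i, , drop = FALSE] -
                     traj$coords[frames, j, , drop = FALSE])^2))
  attribute_series(sprintf("dist %d-%d", i, j), "distance", as.numeric(d), frames)
}

#' Binary contact time series (distance cutoff)
#'
#' 1 when the `i`-`j` distance is at most `cutoff` Angstrom, else 0.  Used to
#' track designed state-specific contact pairs.
#'
#' @inheritParams distance_series
#' @param cutoff contact distance cutoff in Angstrom (default 4.5, the
#'   dynamical-network contact cutoff).
#' @param id optional identifier.
#' @export
contact_series <- function(traj, i, j, cutoff = 4.5,
                           frames = seq_len(n_frames(traj)), id = NULL) {
  d <- distance_series(traj, i, j, frames)
  attribute_series(id %||% sprintf("contact %d-%d", i, j), "contact",
                   as.numeric(d$values <= cutoff), frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Signed dihedral angle in degrees for four points (rows of a matrix or four
# 3-vectors), IUPAC sign convention, range (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  # IUPAC sign convention (matches bio3d::torsion.xyz)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone Phi/Psi dihedral time series for one residue
#'
#' Phi is C(prev)-N-CA-C, Psi is N-CA-C-N(next); both signed, in degrees,
#' range (-180, 180].  A chain-terminal residue missing the needed neighbour
#' atom gets an all-`NA` series for the undefined angle.
#'
#' @param traj a `Trajectory`.
#' @param resid residue number.
#' @param chain optional chain id (default: first chain containing `resid`).
#' @param frames frame indices (default all; use [stride_frames()] for the
#'   25-ps attribute stride).
#' @return list with elements `phi` and `psi`, both `AttributeSeries`.
#' @export
backbone_dihedrals <- function(traj, resid, chain = NULL,
                               frames = seq_len(n_frames(traj))) {
  at <- traj$topology$atoms
  if (is.null(chain)) chain <- at$chain[at$resid == resid][1]
  f_idx <- function(rid, name) {
    w <- which(at$resid == rid & at$chain == chain & toupper(at$name) == name)
    if (length(w)) w[1] else NA_integer_
  }
  iN <- f_idx(resid, "N"); iCA <- f_idx(resid, "CA"); iC <- f_idx(resid, "C")
  if (is.na(iN) || is.na(iCA) || is.na(iC))
    stop("residue ", resid, " lacks backbone N/CA/C atoms")
  iCp <- f_idx(resid - 1L, "C"); iNn <- f_idx(resid + 1L, "N")
  nf <- length(frames)
  phi <- rep(NA_real_, nf); psi <- rep(NA_real_, nf)
  for (k in seq_len(nf)) {
    fr <- frame_coords(traj, frames[k])
    if (!is.na(iCp)) phi[k] <- dihedral_angle(fr[iCp, ], fr[iN, ], fr[iCA, ], fr[iC, ])
    if (!is.na(iNn)) psi[k] <- dihedral_angle(fr[iN, ], fr[iCA, ], fr[iC, ], fr[iNn, ])
  }
  list(phi = attribute_series(sprintf("phi %s%d", chain, resid), "phi", phi, frames),
       psi = attribute_series(sprintf("psi %s%d", chain, resid), "psi", psi, frames))
}

#' Strided frame indices for attribute extraction
#'
#' Attribute time series are conventionally computed every 25 ps; with 1-ps
#' frames that is every 25th frame.
#'
#' @param traj a `Trajectory`.
#' @param stride frame stride (default 25).
#' @export
stride_frames <- function(traj, stride = 25L) {
  seq.int(1L, n_frames(traj), by = as.integer(stride))
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor heavy-atom distance at most `d_cut`
#' and donor-hydrogen-acceptor angle within `a_cut` degrees of linear
#' (so >= 160 degrees at the default 20-degree cutoff).  Donor/acceptor heavy
#' atoms come from a bundled per-residue table; backbone N (non-proline) and
#' O are always included.  Hydrogens must be present (they are in synthetic
#' topologies); for hydrogen-free crystal structures set
#' `heavy_fallback = TRUE` to use the flagged heavy-atom variant
#' (D...A distance plus antecedent-D-A angle > 90 degrees).
#'
#' @param s a `Structure`.
#' @param xyz coordinates to analyse (default `s$xyz`).
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 3.2).
#' @param a_cut deviation-from-linear angle cutoff, degrees (default 20).
#' @param heavy_fallback use the hydrogen-free variant (default FALSE).
#' @param table donor/acceptor table (see source of `.hbond_table`).
#' @return data.frame with donor, hydrogen and acceptor atom indices plus
#'   residue identifiers, one row per bond.
#' @export
detect_hbonds <- function(s, xyz = s$xyz, d_cut = 3.2, a_cut = 20,
                          heavy_fallback = FALSE, table = .hbond_table()) {
  at <- s$atoms
  don <- which(
    (toupper(at$name) == "N" & toupper(at$resname) != "PRO") |
      mapply(function(nm, rn) nm %in% (table$donors[[rn]] %||% character(0)),
             toupper(at$name), toupper(at$resname))
  )
  acc <- which(
    toupper(at$name) == "O" |
      mapply(function(nm, rn) nm %in% (table$acceptors[[rn]] %||% character(0)),
             toupper(at$name), toupper(at$resname))
  )
  hyd <- which(at$element == "H")
  if (!heavy_fallback && length(hyd) == 0L)
    stop("structure has no hydrogens; rerun with heavy_fallback = TRUE ",
         "(flagged heavy-atom criterion) or add hydrogens")
  res <- list()
  for (d in don) {
    for (a in acc) {
      if (a == d) next
      same_res <- at$resid[a] == at$resid[d] && at$chain[a] == at$chain[d]
      if (same_res) next
      dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dda > d_cut) next
      if (heavy_fallback) {
        ante <- .donor_antecedent(s, d)
        ok <- if (is.na(ante)) TRUE else
          .angle3(xyz[ante, ], xyz[d, ], xyz[a, ]) > 90
        if (ok) res[[length(res) + 1L]] <- c(d, NA_integer_, a)
      } else {
        # hydrogens covalently bonded to this donor
        hd <- hyd[sqrt(rowSums(sweep(xyz[hyd, , drop = FALSE], 2, xyz[d, ])^2)) < 1.25]
        for (h in hd) {
          if (.angle3(xyz[d, ], xyz[h, ], xyz[a, ]) >= 180 - a_cut) {
            res[[length(res) + 1L]] <- c(d, h, a)
            break
          }
        }
      }
    }
  }
  .hbond_result(s, res)
}

.hbond_result <- function(s, res) {
  at <- s$atoms
  if (length(res) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_res = character(0),
                      acceptor_res = character(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, res)
  data.frame(
    donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3],
    donor_res = paste0(at$resname[m[, 1]], at$resid[m[, 1]]),
    acceptor_res = paste0(at$resname[m[, 3]], at$resid[m[, 3]]),
    stringsAsFactors = FALSE
  )
}

.donor_antecedent <- function(s, d) {
  # heaviest non-hydrogen atom within covalent range of the donor
  xyz <- s$xyz
  heavy <- which(s$atoms$element != "H")
  heavy <- setdiff(heavy, d)
  dd <- sqrt(rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[d, ])^2))
  cand <- heavy[dd < 1.8]
  if (length(cand) == 0L) NA_integer_ else cand[1]
}

.angle3 <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Per-frame presence series of one hydrogen bond or salt bridge
#'
#' Binary time course (1 = interaction present in that frame) for a specific
#' residue pair, computed by running the per-frame detector at each (possibly
#' strided) frame.
#'
#' @param traj a `Trajectory`.
#' @param res_a,res_b residue numbers of the two partners (donor/acceptor
#'   order does not matter; for salt bridges, acidic/basic order does not
#'   matter).
#' @param frames frame indices (default the 25-frame stride).
#' @param ... passed to [detect_hbonds()] / [detect_salt_bridges()].
#' @return `AttributeSeries` of kind `"hbond"` / `"saltbridge"`.
#' @export
hbond_series <- function(traj, res_a, res_b, frames = stride_frames(traj), ...) {
  s <- traj$topology
  vals <- vapply(frames, function(f) {
    hb <- detect_hbonds(s, frame_coords(traj, f), ...)
    rd <- s$atoms$resid[hb$donor]; ra <- s$atoms$resid[hb$acceptor]
    as.numeric(any((rd == res_a & ra == res_b) | (rd == res_b & ra == res_a)))
  }, numeric(1))
  attribute_series(sprintf("hbond %d-%d", res_a, res_b), "hbond", vals, frames)
}

#' @rdname hbond_series
#' @export
saltbridge_series <- function(traj, res_a, res_b,
                              frames = stride_frames(traj), ...) {
  s <- traj$topology
  num <- function(x) as.integer(gsub("[^0-9-]", "", x))
  vals <- vapply(frames, function(f) {
    sb <- detect_salt_bridges(s, frame_coords(traj, f), ...)
    if (nrow(sb) == 0L) return(0)
    ra <- num(sb$acidic_res); rb <- num(sb$basic_res)
    as.numeric(any((ra == res_a & rb == res_b) | (ra == res_b & rb == res_a)))
  }, numeric(1))
  attribute_series(sprintf("saltbridge %d-%d", res_a, res_b), "saltbridge",
                   vals, frames)
}

#' Detect salt bridges in one frame
#'
#' A pair is reported when any side-chain carboxylate oxygen of Asp/Glu lies
#' within `d_cut` Angstrom of any side-chain nitrogen of Lys/Arg/His.
#'
#' @param s a `Structure`.
#' @param xyz coordinates (default `s$xyz`).
#' @param d_cut distance cutoff, Angstrom (default 3.5).
#' @return data.frame with acidic/basic residue identifiers and the minimal
#'   O-N distance, one row per bridged pair.
#' @export
detect_salt_bridges <- function(s, xyz = s$xyz, d_cut = 3.5) {
  at <- s$atoms
  sb <- .saltbridge_atoms()
  is_listed <- function(lst) mapply(
    function(nm, rn) nm %in% (lst[[rn]] %||% character(0)),
    toupper(at$name), toupper(at$resname))
  ac <- which(is_listed(sb$acidic))
  ba <- which(is_listed(sb$basic))
  out <- list()
  if (length(ac) && length(ba)) {
    key_a <- paste(at$chain[ac], at$resid[ac])
    key_b <- paste(at$chain[ba], at$resid[ba])
    for (ka in unique(key_a)) {
      ia <- ac[key_a == ka]
      for (kb in unique(key_b)) {
        ib <- ba[key_b == kb]
        dmat <- sqrt(outer(rowSums(xyz[ia, , drop = FALSE]^2),
                           rowSums(xyz[ib, , drop = FALSE]^2), "+") -
                     2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE]))
        dmin <- min(dmat)
        if (dmin <= d_cut)
          out[[length(out) + 1L]] <- data.frame(
            acidic_res = paste0(at$resname[ia[1]], at$resid[ia[1]]),
            basic_res = paste0(at$resname[ib[1]], at$resid[ib[1]]),
            distance = dmin, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(acidic_res = character(0), basic_res = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
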