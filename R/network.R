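#' Build a dynamical network from a trajectory
#'
#' One node per residue (centred on its representative atom, typically the
#' C-alpha; ligand nodes may be supplied the same way).  An edge joins two
#' nodes when any heavy-atom pair between the residues lies within `d_cut`
#' Angstrom in at least a fraction `f_cut` of frames; nearest sequence
#' neighbours (|delta resid| <= 1, same chain) are excluded.  Edge weights
#' are `-log(|C_ij|)` with `C` the cross-correlation of the representative
#' atoms, so strongly correlated contacts are "short"; edges with zero
#' correlation (infinite weight) are dropped with a warning.
#'
#' @param traj a `Trajectory`.
#' @param sel selection of representative atoms, one per node (default: all
#'   C-alpha atoms).
#' @param d_cut contact distance cutoff, Angstrom (default 4.5).
#' @param f_cut minimal contact fraction of frames (default 0.75, applied
#'   as >=).
#' @param corr optional precomputed `CorrelationMatrix` over the same
#'   selection; computed from the fitted trajectory when missing.
#' @param frames frame indices used for the contact census (default all).
#' @param exclude_neighbors exclude |delta resid| <= this value on the same
#'   chain (default 1).
#' @return object of class `DynamicalNetwork`: `graph` (igraph, weighted),
#'   `nodes` (data.frame), `edges` (data.frame with `contact_fraction`,
#'   `correlation`, `weight`), `communities` (NULL until
#'   [girvan_newman()] is run), `modularity`.
#' @export
build_network <- function(traj, sel = NULL, d_cut = 4.5, f_cut = 0.75,
                          corr = NULL, frames = seq_len(n_frames(traj)),
                          exclude_neighbors = 1L) {
  at <- traj$topology$atoms
  if (is.null(sel)) sel <- select_atoms(traj$topology, "name CA")
  idx <- sel_indices(sel, traj$topology)
  R <- length(idx)
  node_res <- at$resid[idx]
  node_chain <- at$chain[idx]
  if (is.null(corr)) {
    ftraj <- fit_trajectory(traj, sel)
    corr <- dccm(ftraj, sel)
  }
  if (!identical(dim(corr$values), c(R, R)))
    stop("correlation matrix does not cover the node selection")
  # heavy atoms per node's residue
  res_atoms <- lapply(seq_len(R), function(k)
    which(at$resid == node_res[k] & at$chain == node_chain[k] & at$element != "H"))
  # candidate pairs: representative atoms ever within d_cut + slack
  slack <- 12
  cand <- list()
  ref1 <- frame_coords(traj, frames[1])[idx, , drop = FALSE]
  ref2 <- frame_coords(traj, frames[length(frames)])[idx, , drop = FALSE]
  for (i in seq_len(R - 1L)) {
    d1 <- sqrt(rowSums(sweep(ref1[(i + 1):R, , drop = FALSE], 2, ref1[i, ])^2))
    d2 <- sqrt(rowSums(sweep(ref2[(i + 1):R, , drop = FALSE], 2, ref2[i, ])^2))
    js <- which(pmin(d1, d2) <= d_cut + slack) + i
    near <- abs(node_res[js] - node_res[i]) <= exclude_neighbors &
      node_chain[js] == node_chain[i]
    js <- js[!near]
    if (length(js)) cand[[length(cand) + 1L]] <- cbind(i, js)
  }
  pairs <- if (length(cand)) do.call(rbind, cand) else
    matrix(integer(0), 0, 2)
  edges <- data.frame(i = integer(0), j = integer(0),
                      contact_fraction = numeric(0), correlation = numeric(0),
                      weight = numeric(0))
  if (nrow(pairs)) {
    frac <- .contact_fraction_cpp(
      traj$coords[frames, , 1], traj$coords[frames, , 2],
      traj$coords[frames, , 3], res_atoms,
      matrix(as.integer(pairs), ncol = 2), d_cut)
    keep <- frac >= f_cut
    pairs <- pairs[keep, , drop = FALSE]
    frac <- frac[keep]
    cij <- corr$values[pairs]
    zero <- is.na(cij) | abs(cij) <= 0
    if (any(zero)) {
      warning(sum(zero), " retained contact(s) with zero correlation dropped ",
              "(infinite weight)")
      pairs <- pairs[!zero, , drop = FALSE]
      frac <- frac[!zero]; cij <- cij[!zero]
    }
    edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        contact_fraction = frac, correlation = cij,
                        weight = -log(abs(cij)))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$i, to = edges$j, weight = edges$weight),
    directed = FALSE,
    vertices = data.frame(name = seq_len(R), resid = node_res,
                          chain = node_chain, atom = idx))
  obj <- list(graph = g,
              nodes = data.frame(node = seq_len(R), resid = node_res,
                                 chain = node_chain, atom = idx),
              edges = edges, communities = NULL, modularity = NA_real_)
  class(obj) <- "DynamicalNetwork"
  obj
}

#' @export
print.DynamicalNetwork <- function(x, ...) {
  cat("DynamicalNetwork:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges")
  if (!is.null(x$communities))
    cat(";", length(unique(x$communities)), "communities, modularity",
        round(x$modularity, 3))
  cat("\n")
  invisible(x)
}

#' Girvan-Newman community detection
#'
#' Divisive partitioning: repeatedly remove the edge with the highest
#' betweenness (edge weights act as path lengths), tracking the component
#' partition after every removal, and keep the partition with maximal
#' modularity (computed on the original unweighted contact graph).  Ties in
#' betweenness are broken deterministically by the lexicographically
#' smallest (i, j) edge.
#'
#' A geometric contact graph of a large domain almost always contains
#' modularity substructure finer than the domain partition itself, so the
#' maximum-modularity partition typically subdivides domains.  To compare
#' against a known domain count, request the dendrogram cut with exactly
#' `n_communities` components instead.
#'
#' @param net a `DynamicalNetwork` (or a bare igraph).
#' @param weighted use edge weights as betweenness path lengths
#'   (default TRUE; FALSE gives the unweighted classic variant).
#' @param n_communities optional: return the first divisive-dendrogram
#'   partition with at least this many components instead of the
#'   maximum-modularity one (pre-existing components, e.g. isolated
#'   residues, count).
#' @return the network with `communities` (named integer vector, one id per
#'   node) and `modularity` filled in.
#' @export
girvan_newman <- function(net, weighted = TRUE, n_communities = NULL) {
  g0 <- if (inherits(net, "DynamicalNetwork")) net$graph else net
  if (igraph::vcount(g0) == 0L) stop("empty graph")
  g <- g0
  best_mod <- -Inf
  best_mem <- igraph::components(g0)$membership
  # include the unsplit partition as a candidate
  best_mod <- igraph::modularity(g0, best_mem, weights = NULL)
  if (!is.null(n_communities) &&
      max(best_mem) >= n_communities) {
    if (inherits(net, "DynamicalNetwork")) {
      net$communities <- best_mem; net$modularity <- best_mod
      return(net)
    }
    return(list(communities = best_mem, modularity = best_mod))
  }
  while (igraph::ecount(g) > 0L) {
    w <- if (weighted) igraph::E(g)$weight else NULL
    eb <- igraph::edge_betweenness(g, weights = w)
    mx <- max(eb)
    cand <- which(eb >= mx - 1e-12)
    if (length(cand) > 1L) {
      ends <- igraph::ends(g, igraph::E(g)[cand], names = FALSE)
      key <- apply(ends, 1, function(r) sprintf("%09d_%09d", min(r), max(r)))
      cand <- cand[order(key)][1]
    }
    g <- igraph::delete_edges(g, cand[1])
    mem <- igraph::components(g)$membership
    mod <- igraph::modularity(g0, mem, weights = NULL)
    if (!is.null(n_communities)) {
      if (max(mem) >= n_communities) { best_mem <- mem; best_mod <- mod; break }
    } else if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_mem <- mem
    }
  }
  if (inherits(net, "DynamicalNetwork")) {
    net$communities <- best_mem
    net$modularity <- best_mod
    net
  } else {
    list(communities = best_mem, modularity = best_mod)
  }
}
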