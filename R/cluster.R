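#' Construct per-frame state labels
#'
#' @param labels integer vector, 0 = closed, 1 = open (higher cluster ids are
#'   allowed for k > 2 segmentations).
#' @param method labelling method string.
#' @param transition_frame first frame of the longest open run, or `NULL`
#'   when no transition occurred.
#' @export
state_labels <- function(labels, method = "manual", transition_frame = NULL) {
  obj <- list(labels = as.integer(labels), method = method,
              transition_frame = transition_frame)
  class(obj) <- "StateLabels"
  obj
}

#' @export
print.StateLabels <- function(x, ...) {
  tb <- table(x$labels)
  cat("StateLabels (", x$method, "): ", paste(names(tb), tb, sep = "=",
      collapse = ", "), "\n", sep = "")
  if (!is.null(x$transition_frame))
    cat("  transition at frame", x$transition_frame, "\n")
  invisible(x)
}

# first index of the longest run of 1s; NULL when no 1s
.longest_open_run_start <- function(lab) {
  r <- rle(lab)
  if (!any(r$values == 1L)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  open <- which(r$values == 1L)
  starts[open[which.max(r$lengths[open])]]
}

#' k-means state segmentation of a PC projection
#'
#' Best of `n_restarts` k-means runs with k-means++ seeding; cluster quality
#' is reported as `BSS/TSS = 1 - within-SS / total-SS` (the elbow-criterion
#' fraction).  The cluster containing frame 1 is labelled 0 ("closed", the
#' simulation's starting crystal-like state); remaining clusters are numbered
#' in order of first appearance.
#'
#' @param projection F x k projection matrix (or vector).
#' @param n_clusters number of clusters (default 2).
#' @param n_restarts k-means++ restarts (default 25).
#' @param seed integer RNG seed; results are deterministic given it.
#' @return list with `labels` (a `StateLabels`) and `bss_tss` (fraction).
#' @export
kmeans_states <- function(projection, n_clusters = 2L, n_restarts = 25L,
                          seed = 1L) {
  X <- as.matrix(projection)
  f <- nrow(X)
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  if (f <= n_clusters) stop("need more frames than clusters")
  if (n_clusters == 1L) {
    lab <- state_labels(rep(0L, f), "kmeans-pc", NULL)
    return(list(labels = lab, bss_tss = 0))
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- .kmeanspp_centers(X, n_clusters)
    km <- tryCatch(
      stats::kmeans(X, centers = centers, iter.max = 200L),
      error = function(e) NULL
    )
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed in all restarts (empty clusters)")
  cl <- best$cluster
  # relabel: frame 1's cluster -> 0, others by first appearance
  order_seen <- unique(c(cl[1], cl))
  relab <- match(cl, order_seen) - 1L
  lab <- state_labels(relab, "kmeans-pc",
                      if (n_clusters == 2L) .longest_open_run_start(relab) else NULL)
  list(labels = lab, bss_tss = best$betweenss / best$totss)
}

.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' BSS/TSS elbow scan over cluster counts
#'
#' @inheritParams kmeans_states
#' @param k_range integer vector of cluster counts (default 1:6).
#' @return data.frame with `k` and `bss_tss`.
#' @export
bss_tss_scan <- function(projection, k_range = 1:6, n_restarts = 25L, seed = 1L) {
  data.frame(
    k = k_range,
    bss_tss = vapply(k_range, function(k)
      kmeans_states(projection, k, n_restarts, seed)$bss_tss, numeric(1))
  )
}

#' Assign states by thresholding a distance series
#'
#' Frames whose distance exceeds `threshold` are labelled open (1).  The
#' transition frame is the first index of the longest open run.  When the
#' whole series is one label, no transition is reported (valid outcome,
#' flagged in the `method` field).
#'
#' @param series an `AttributeSeries` of kind `"distance"` (or a numeric
#'   vector).
#' @param threshold distance threshold, Angstrom.
#' @return a `StateLabels`.
#' @export
assign_states_by_distance <- function(series, threshold) {
  v <- if (inherits(series, "AttributeSeries")) series$values else as.numeric(series)
  lab <- as.integer(v > threshold)
  tf <- .longest_open_run_start(lab)
  method <- if (length(unique(lab)) == 1L) "distance-threshold (no transition)"
            else "distance-threshold"
  state_labels(lab, method, tf)
}
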