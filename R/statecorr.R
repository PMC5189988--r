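#' Phi coefficient of two binary series
#'
#' `phi = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)` from the 2x2
#' contingency table; equal to the Pearson correlation of the two 0/1
#' series.  Returns `NA` (undefined) when either series is constant.
#'
#' @param a,b binary (0/1) vectors of equal length.
#' @return phi in \[-1, 1\], or `NA`.
#' @export
phi_coefficient <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  a <- as.numeric(a); b <- as.numeric(b)
  if (!all(c(a, b) %in% c(0, 1))) stop("inputs must be binary 0/1")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) return(NA_real_)
  n11 <- as.numeric(sum(a == 1 & b == 1)); n00 <- as.numeric(sum(a == 0 & b == 0))
  n10 <- as.numeric(sum(a == 1 & b == 0)); n01 <- as.numeric(sum(a == 0 & b == 1))
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

#' Point-biserial correlation
#'
#' `r_pb = (M1 - M0) / s_n * sqrt(n1 n0 / n^2)` with `s_n` the population
#' standard deviation of `x`; identical to the Pearson correlation of `x`
#' against the 0/1 labels.  `NA` when one group is empty or `x` is constant.
#'
#' @param labels binary (0/1) group labels.
#' @param x continuous values, same length.
#' @return r in \[-1, 1\], or `NA`.
#' @export
point_biserial <- function(labels, x) {
  if (length(labels) != length(x)) stop("inputs must have equal length")
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  if (stats::sd(x) == 0) return(NA_real_)
  n <- n1 + n0
  s_n <- sqrt(sum((x - mean(x))^2) / n)
  (mean(x[labels == 1]) - mean(x[labels == 0])) / s_n * sqrt(n1 * n0 / n^2)
}

#' Sine transform for circular attributes
#'
#' Backbone dihedrals are circular; their sine is used as the linear variable
#' in correlation analysis.
#'
#' @param angles angles in degrees.
#' @return element-wise sine.
#' @export
circular_correlation_input <- function(angles) {
  sin(angles * pi / 180)
}

#' Welch two-sample t-test (two-tailed)
#'
#' Thin wrapper over [stats::t.test()] with the unequal-variance (Welch)
#' statistic, plus the degenerate-input convention: when both groups have
#' zero variance and equal means, `t = 0`, `p = 1`.
#'
#' @param x0,x1 numeric samples (each n >= 2).
#' @return list with `t` and `p`.
#' @export
two_sample_t <- function(x0, x1) {
  if (length(x0) < 2L || length(x1) < 2L) stop("each group needs n >= 2")
  if (stats::sd(x0) == 0 && stats::sd(x1) == 0) {
    if (mean(x0) == mean(x1)) return(list(t = 0, p = 1))
    return(list(t = Inf * sign(mean(x1) - mean(x0)), p = 0))
  }
  tt <- stats::t.test(x1, x0, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Watson-Williams high-concentration F test for two circular samples
#'
#' Tests equality of mean directions.  With resultant lengths `R1`, `R2` of
#' the groups and `R` of the pooled sample (N observations),
#' `F = K (N - 2) (R1 + R2 - R) / (N - R1 - R2)` where `K = 1 + 3/(8 kappa)`
#' and `kappa` is the maximum-likelihood von Mises concentration estimated
#' from the mean weighted resultant `(R1 + R2)/N` by the standard three-regime
#' rational approximation of the inverse of `A(kappa) = I1/I0`.  p-values come
#' from `F(1, N - 2)`.  The test assumes high concentration; a warning is
#' issued when the weighted mean resultant length is below 0.45.
#'
#' @param angles0,angles1 samples in degrees (each n >= 5).
#' @return list with `F`, `p`, `kappa`, `rbar` (weighted mean resultant
#'   length) and `valid` (FALSE when the concentration assumption fails).
#' @export
watson_williams <- function(angles0, angles1) {
  if (length(angles0) < 5L || length(angles1) < 5L)
    stop("each group needs n >= 5")
  a0 <- angles0 * pi / 180; a1 <- angles1 * pi / 180
  n0 <- length(a0); n1 <- length(a1); N <- n0 + n1
  res_len <- function(a) sqrt(sum(cos(a))^2 + sum(sin(a))^2)
  R0 <- res_len(a0); R1 <- res_len(a1); R <- res_len(c(a0, a1))
  if (R0 == n0 && R1 == n1 && isTRUE(all.equal(R, N)))
    return(list(F = NA_real_, p = NA_real_, kappa = Inf, rbar = 1, valid = FALSE))
  rbar <- (R0 + R1) / N
  valid <- rbar >= 0.45
  if (!valid)
    warning("mean resultant length ", signif(rbar, 3),
            " < 0.45: high-concentration assumption questionable")
  kappa <- .vonmises_kappa(rbar)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * (N - 2) * (R0 + R1 - R) / (N - R0 - R1)
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = stats::pf(Fstat, 1, N - 2, lower.tail = FALSE),
       kappa = kappa, rbar = rbar, valid = valid)
}

# ML inverse of A(kappa) = I1(kappa)/I0(kappa), three-regime approximation
# (Fisher, Statistical Analysis of Circular Data, eq. 4.40-4.42).
.vonmises_kappa <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Screen attributes for conformational-state correlation
#'
#' Scores every attribute series against per-frame state labels: binary
#' kinds (hbond, saltbridge, contact) by the phi coefficient, dihedrals by
#' point-biserial correlation of the sine-transformed angles, continuous
#' kinds (sasa, distance) by point-biserial correlation.  Attributes with
#' `|statistic| > r_threshold` are flagged as state-correlated; a positive
#' statistic means the attribute is elevated (or present) in the open state
#' (label 1).  p-values come from the exact correspondence of phi and
#' point-biserial to Pearson r (t distribution with n - 2 df); a
#' Benjamini-Hochberg adjusted column is reported for transparency but not
#' used for flagging.
#'
#' @param attrs list of `AttributeSeries`.
#' @param labels a `StateLabels` over full-trajectory frames.
#' @param r_threshold flagging threshold on `|statistic|` (default 0.5).
#' @return data.frame sorted by decreasing `|statistic|` with columns
#'   `attribute_id`, `kind`, `statistic_kind`, `statistic_value`, `p_value`,
#'   `p_adjusted`, `flagged`, `associated_state`.
#' @export
screen_attributes <- function(attrs, labels, r_threshold = 0.5) {
  stopifnot(inherits(labels, "StateLabels"))
  if (inherits(attrs, "AttributeSeries")) attrs <- list(attrs)
  rows <- lapply(attrs, function(a) {
    if (any(a$frame_index > length(labels$labels)))
      stop("alignment error: attribute '", a$id,
           "' indexes frames beyond the label series")
    lab <- labels$labels[a$frame_index]
    ok <- !is.na(a$values)
    lab <- lab[ok]; v <- a$values[ok]
    if (a$kind %in% c("hbond", "saltbridge", "contact")) {
      stat <- phi_coefficient(lab, v)
      kind_stat <- "phi"
    } else if (a$kind %in% c("phi", "psi")) {
      stat <- point_biserial(lab, circular_correlation_input(v))
      kind_stat <- "point_biserial"
    } else {
      stat <- point_biserial(lab, v)
      kind_stat <- "point_biserial"
    }
    n <- length(v)
    p <- if (is.na(stat) || n < 3) NA_real_ else {
      tstat <- abs(stat) * sqrt((n - 2) / max(1 - stat^2, 1e-300))
      2 * stats::pt(tstat, n - 2, lower.tail = FALSE)
    }
    data.frame(attribute_id = a$id, kind = a$kind, statistic_kind = kind_stat,
               statistic_value = stat, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$flagged <- !is.na(out$statistic_value) &
    abs(out$statistic_value) > r_threshold
  out$associated_state <- ifelse(!out$flagged, "none",
                                 ifelse(out$statistic_value > 0, "open", "closed"))
  out[order(-abs(out$statistic_value), out$attribute_id, na.last = TRUE), ,
      drop = FALSE]
}
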