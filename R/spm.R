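#' Paired t-statistic field over curve nodes
#'
#' Node-wise paired t-test for two matched sets of curves: per node `q`,
#' with differences `d = A[, q] - B[, q]`, the statistic is
#' `t = mean(d) / (sd(d) / sqrt(n))` (sample sd, `n - 1` denominator) with
#' `n - 1` degrees of freedom. Nodes where the differences have zero
#' spread but a non-zero mean are flagged and set to +/-Inf.
#'
#' @param A,B numeric matrices, one row per pair member, equal dimensions;
#'   rows matched (e.g. by subject).
#' @return list: `t` (per-node statistic), `df`, `residuals` (centred
#'   differences), `flagged` (indices of zero-variance, non-zero-mean
#'   nodes).
#' @export
paired_t_field <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    gs_error("gaitsym_invalid_arg", "curve matrices must have equal dimensions")
  n <- nrow(A)
  if (n < 2) gs_error("gaitsym_invalid_arg", "need at least 2 pairs")
  D <- A - B
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  t <- rep(0, ncol(D))
  ok <- s > 0
  t[ok] <- m[ok] / (s[ok] / sqrt(n))
  flagged <- which(!ok & m != 0)
  t[flagged] <- sign(m[flagged]) * Inf
  list(t = t, df = n - 1L, residuals = sweep(D, 2, m), flagged = flagged)
}

#' Estimate residual-field smoothness (FWHM)
#'
#' Residual-gradient smoothness estimator: residuals are scaled to unit
#' variance per node, gradients taken along the node axis (unit spacing),
#' and `fwhm = sqrt(4 log 2 / mean squared gradient)`. For Gaussian
#' autocorrelation this recovers the FWHM of the smoothing kernel that
#' generated the field. Zero-variance nodes are excluded; an all-zero
#' residual field returns the upper clip (infinitely smooth). The result
#' is clipped to \[1, 1000\] nodes.
#'
#' @param residuals matrix of residual curves (rows = replicates).
#' @return FWHM in nodes.
#' @export
estimate_fwhm <- function(residuals) {
  R <- as.matrix(residuals)
  if (nrow(R) < 2) gs_error("gaitsym_invalid_arg", "need at least 2 residual rows")
  s <- sqrt(colMeans(R^2))
  if (all(s == 0)) return(1000)
  V <- sweep(R, 2, ifelse(s > 0, s, NA), "/")
  G <- V[, -1, drop = FALSE] - V[, -ncol(V), drop = FALSE]
  msq <- mean(G^2, na.rm = TRUE)
  if (!is.finite(msq) || msq == 0) return(1000)
  min(1000, max(1, sqrt(4 * log(2) / msq)))
}

# Expected Euler characteristic of a thresholded 1D t-field:
# tail probability plus the 1D resel term.
expected_ec <- function(t, df, resels) {
  pt(t, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + t^2 / df)^(-(df - 1) / 2)
}

#' Random-field-theory critical threshold for a 1D t-field
#'
#' Smallest `t*` with expected Euler characteristic equal to the test
#' level, found by bisection: `E[EC](t) = P(T_df >= t) +
#' resels * sqrt(4 log 2)/(2 pi) * (1 + t^2/df)^(-(df-1)/2)`. Two-tailed
#' tests solve at `alpha / 2`. With `resels = 0` this reduces to the
#' Student quantile (no multiplicity correction).
#'
#' @param alpha familywise significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @param resels field length in smoothness units, `(nodes - 1) / fwhm`.
#' @param tails 1 or 2.
#' @return critical threshold `t*`.
#' @export
rft_threshold <- function(alpha = 0.05, df, resels, tails = 2) {
  if (alpha <= 0 || alpha >= 1) gs_error("gaitsym_invalid_arg", "alpha must be in (0, 1)")
  if (df < 1) gs_error("gaitsym_invalid_arg", "df must be >= 1")
  if (resels < 0) gs_error("gaitsym_invalid_arg", "resels must be >= 0")
  target <- if (tails == 2) alpha / 2 else alpha
  lo <- 0; hi <- 100
  if (expected_ec(hi, df, resels) > target)
    gs_error("gaitsym_no_root", "no threshold in [0, 100] attains the requested level")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected_ec(mid, df, resels) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Suprathreshold clusters of a t-field
#'
#' Maximal runs of nodes exceeding the critical threshold (`|t| > t*` for
#' two-tailed tests, `t > t*` for one-tailed), reported as inclusive
#' stance-percentage intervals with node extents. Cluster edges snap to
#' nodes; no fractional-node interpolation is performed.
#'
#' @param t numeric t-field (101 nodes by convention).
#' @param t_critical critical threshold.
#' @param tails 1 or 2.
#' @return data.frame: `start_pct`, `end_pct`, `extent`.
#' @export
suprathreshold_clusters <- function(t, t_critical, tails = 2) {
  excess <- if (tails == 2) abs(t) else t
  runs <- logical_runs(excess > t_critical)
  data.frame(start_pct = runs[, "start"] - 1L, end_pct = runs[, "end"] - 1L,
             extent = runs[, "end"] - runs[, "start"] + 1L)
}

# Max suprathreshold cluster extent of a paired-difference matrix D under
# one sign assignment.
max_extent <- function(D, signs, t_critical, tails) {
  n <- nrow(D)
  S <- D * signs                      # signs recycle down rows (row-wise flip)
  m <- colMeans(S)
  s2 <- (colSums(S^2) - n * m^2) / (n - 1)
  t <- ifelse(s2 > 0, m / sqrt(s2 / n), ifelse(m == 0, 0, sign(m) * Inf))
  cl <- suprathreshold_clusters(t, t_critical, tails)
  if (nrow(cl) == 0) 0L else max(cl$extent)
}

#' Sign-flip permutation p-values for suprathreshold clusters
#'
#' Cluster-level inference by permuting the signs of the paired
#' differences: the null distribution of the maximum suprathreshold
#' cluster extent is built over random sign assignments, and each observed
#' cluster gets `p = (1 + #{null extent >= observed}) / (n_perm + 1)`.
#' When `n_perm` reaches `2^n` all sign patterns are enumerated exactly
#' and `p = #{null extent >= observed} / 2^n`.
#'
#' @param A,B paired curve matrices as in [paired_t_field()].
#' @param t_critical cluster-forming threshold.
#' @param n_perm number of random permutations (>= 100).
#' @param seed integer seed.
#' @param tails 1 or 2.
#' @return list: `clusters` (data.frame with `p` added), `n_perm_used`,
#'   `exact` (logical).
#' @export
permutation_cluster_p <- function(A, B, t_critical, n_perm = 999, seed = 1L,
                                  tails = 2) {
  if (n_perm < 100) gs_error("gaitsym_invalid_arg", "n_perm must be >= 100")
  A <- as.matrix(A); B <- as.matrix(B)
  D <- A - B
  n <- nrow(D)
  obs <- suprathreshold_clusters(paired_t_field(A, B)$t, t_critical, tails)
  exact <- n <= 30 && n_perm >= 2^n
  if (exact) {
    patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_max <- apply(patterns, 1, function(sg) max_extent(D, sg, t_critical, tails))
    p <- vapply(obs$extent, function(e) mean(null_max >= e), 0)
    used <- 2L^n
  } else {
    null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      max_extent(D, sample(c(-1, 1), n, replace = TRUE), t_critical, tails), 0L))
    p <- vapply(obs$extent, function(e) (1 + sum(null_max >= e)) / (n_perm + 1), 0)
    used <- n_perm
  }
  obs$p <- p
  list(clusters = obs, n_perm_used = used, exact = exact)
}

#' One-dimensional SPM paired t-test
#'
#' Full statistical-parametric-mapping inference for paired 1D curves:
#' computes the paired t-field, estimates residual smoothness, derives the
#' random-field-theory critical threshold at level `alpha`, extracts
#' suprathreshold clusters and attaches sign-flip permutation cluster
#' p-values. Zero-variance nodes are excluded from the smoothness estimate
#' and reported in `flagged`.
#'
#' @param A,B paired curve matrices (rows = subjects, columns = nodes).
#' @param alpha familywise significance level.
#' @param tails 1 or 2 (default two-tailed).
#' @param n_perm permutations for cluster p-values.
#' @param seed integer seed for the permutation stream.
#' @return object of class `"spm_t"`: list with `t`, `df`, `fwhm`,
#'   `resels`, `alpha`, `tails`, `t_critical`, `clusters` (with
#'   p-values), `flagged`, `n`.
#' @examples
#' a <- matrix(rnorm(10 * 101), 10)
#' fit <- spm_paired_test(a, a + 0.1, n_perm = 199)
#' print(fit)
#' @export
spm_paired_test <- function(A, B, alpha = 0.05, tails = 2, n_perm = 999,
                            seed = 1L) {
  tf <- paired_t_field(A, B)
  res <- tf$residuals
  if (length(tf$flagged)) res <- res[, -tf$flagged, drop = FALSE]
  fwhm <- estimate_fwhm(res)
  resels <- (length(tf$t) - 1) / fwhm
  tcrit <- rft_threshold(alpha, tf$df, resels, tails)
  perm <- permutation_cluster_p(A, B, tcrit, n_perm, seed, tails)
  structure(list(t = tf$t, df = tf$df, fwhm = fwhm, resels = resels,
                 alpha = alpha, tails = tails, t_critical = tcrit,
                 clusters = perm$clusters, exact_perm = perm$exact,
                 n_perm_used = perm$n_perm_used, flagged = tf$flagged,
                 n = nrow(as.matrix(A))),
            class = "spm_t")
}

#' @export
print.spm_t <- function(x, ...) {
  cat(sprintf("SPM paired t-test (1D), n = %d pairs, df = %d, %d-tailed\n",
              x$n, x$df, x$tails))
  cat(sprintf("  residual FWHM = %.2f nodes, resels = %.2f\n", x$fwhm, x$resels))
  cat(sprintf("  RFT critical threshold t* = %.3f (alpha = %g)\n",
              x$t_critical, x$alpha))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    cat(sprintf("  %d suprathreshold cluster(s) [%s permutation p]:\n",
                nrow(x$clusters), if (x$exact_perm) "exact" else "Monte-Carlo"))
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("    %d%%-%d%% of stance (extent %d, p = %.4f)\n",
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$extent[i], x$clusters$p[i]))
  }
  if (length(x$flagged))
    cat(sprintf("  %d zero-variance node(s) flagged\n", length(x$flagged)))
  invisible(x)
}

#' @export
summary.spm_t <- function(object, ...) {
  print(object)
  invisible(list(t_critical = object$t_critical, clusters = object$clusters,
                 fwhm = object$fwhm, df = object$df))
}

#' Plot an SPM t-field
#'
#' Draws the t-statistic against stance percentage with the critical
#' threshold and shaded suprathreshold clusters.
#'
#' @param x an `"spm_t"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spm_t <- function(x, ...) {
  pct <- seq_along(x$t) - 1
  tt <- x$t
  tt[!is.finite(tt)] <- NA
  graphics::plot(pct, tt, type = "l", xlab = "stance (%)", ylab = "t",
                 main = "SPM paired t-field", ...)
  graphics::abline(h = c(-1, 1) * x$t_critical, lty = 2, col = "red")
  if (nrow(x$clusters))
    for (i in seq_len(nrow(x$clusters)))
      graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3],
                     x$clusters$end_pct[i], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
  invisible(x)
}
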