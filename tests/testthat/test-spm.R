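test_that("the paired t-field matches the scalar paired-t oracle node-wise", {
  set.seed(11)
  A <- matrix(rnorm(5 * 101), 5)
  B <- matrix(rnorm(5 * 101), 5)
  tf <- paired_t_field(A, B)
  oracle <- vapply(seq_len(101), function(q)
    unname(stats::t.test(A[, q], B[, q], paired = TRUE)$statistic), 0)
  expect_equal(tf$t, oracle, tolerance = 1e-10)
  expect_equal(tf$df, 4L)

  expect_equal(paired_t_field(A, A)$t, rep(0, 101))

  # constant non-zero difference: flagged +/-Inf nodes (integer-valued
  # columns keep the differences exactly constant in floating point)
  A[, 5] <- 1:5; A[, 9] <- 2 * (1:5)
  Bc <- A; Bc[, 5] <- A[, 5] - 2; Bc[, 9] <- A[, 9] + 3
  tf2 <- paired_t_field(A, Bc)
  expect_equal(sort(tf2$flagged), c(5L, 9L))
  expect_identical(tf2$t[5], Inf)
  expect_identical(tf2$t[9], -Inf)

  expect_error(paired_t_field(A[1, , drop = FALSE], B[1, , drop = FALSE]),
               class = "gaitsym_invalid_arg")
})

test_that("residual smoothness estimation is monotone and recovers known FWHM", {
  set.seed(21)
  white <- matrix(rnorm(20 * 101), 20)
  smoothed <- noise_field(20, 101, 10)
  expect_gt(estimate_fwhm(smoothed), estimate_fwhm(white))

  est <- estimate_fwhm(noise_field(20, 101, 10))
  expect_gt(est, 7.5)
  expect_lt(est, 12.5)

  expect_equal(estimate_fwhm(matrix(0, 5, 101)), 1000)
})

test_that("RFT threshold reduces to the Student quantile and is monotone in resels", {
  expect_equal(rft_threshold(0.05, 13, resels = 0, tails = 1),
               qt(0.95, 13), tolerance = 1e-6)
  expect_equal(rft_threshold(0.05, 13, resels = 0, tails = 2),
               qt(0.975, 13), tolerance = 1e-6)
  expect_gt(rft_threshold(0.05, 13, 10), rft_threshold(0.05, 13, 1))

  # forward/inverse round trip at the df the study design implies: pick t*
  # in the 3.5-3.6 band, invert E[EC] for the resel count, recompute
  tstar <- 3.55
  ec1 <- sqrt(4 * log(2)) / (2 * pi) * (1 + tstar^2 / 13)^(-6)
  resels <- (0.025 - pt(tstar, 13, lower.tail = FALSE)) / ec1
  expect_gt(resels, 0)
  expect_equal(rft_threshold(0.05, 13, resels, tails = 2), tstar,
               tolerance = 1e-6)
})

test_that("suprathreshold clusters are maximal runs with node-snapped edges", {
  t_field <- rep(0, 101)
  expect_equal(nrow(suprathreshold_clusters(t_field, 3.5)), 0)

  t_field[59:91] <- 5                      # nodes 58..90 (0-based)
  cl <- suprathreshold_clusters(t_field, 3.5)
  expect_equal(cl$start_pct, 58)
  expect_equal(cl$end_pct, 90)
  expect_equal(cl$extent, 33)

  t_field[75] <- 0                         # split by one sub-threshold node
  expect_equal(nrow(suprathreshold_clusters(t_field, 3.5)), 2)

  # negative excursions count under two tails only
  t2 <- rep(0, 101); t2[10:20] <- -6
  expect_equal(nrow(suprathreshold_clusters(t2, 3.5, tails = 2)), 1)
  expect_equal(nrow(suprathreshold_clusters(t2, 3.5, tails = 1)), 0)
})

test_that("permutation p-values are exact for n = 4 via full enumeration", {
  set.seed(31)
  A <- noise_field(4, 101, 8)
  B <- noise_field(4, 101, 8)
  B[, 40:60] <- B[, 40:60] + 1.2
  tcrit <- 2.5
  res <- permutation_cluster_p(A, B, tcrit, n_perm = 100000, seed = 1)
  expect_true(res$exact)
  expect_equal(res$n_perm_used, 16L)

  # independent oracle: enumerate the 16 sign patterns by hand
  D <- A - B
  max_ext <- function(t) {
    r <- rle(abs(t) > tcrit)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }
  null_max <- apply(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1), c(-1, 1)), 1,
                    function(sg) {
                      S <- D * as.numeric(sg)
                      m <- colMeans(S); s <- apply(S, 2, sd)
                      max_ext(ifelse(s > 0, m / (s / 2), 0))
                    })
  obs <- suprathreshold_clusters(paired_t_field(A, B)$t, tcrit)
  expect_gt(nrow(obs), 0)
  expect_equal(res$clusters$p,
               vapply(obs$extent, function(e) mean(null_max >= e), 0))
})

test_that("a massive localized effect reaches the resolution-bound p-value", {
  # only (near-)mirror sign patterns can reproduce the observed extent
  # under a 20-sd effect; at n = 14 none is sampled and p hits the
  # Monte-Carlo floor 1 / (n_perm + 1)
  set.seed(32)
  A <- noise_field(14, 101, 10)
  B <- noise_field(14, 101, 10)
  B[, 45:55] <- B[, 45:55] + 20
  fit <- spm_paired_test(B, A, n_perm = 199, seed = 2)
  expect_gt(nrow(fit$clusters), 0)
  expect_equal(min(fit$clusters$p), 1 / (199 + 1))
})

test_that("identical groups produce an empty SPM result", {
  A <- noise_field(8, 101, 10)
  fit <- spm_paired_test(A, A, n_perm = 199, seed = 3)
  expect_equal(fit$t, rep(0, 101))
  expect_equal(nrow(fit$clusters), 0)
})
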