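test_that("kernel evaluations match their closed forms", {
  expect_equal(kernel_eval(kernel_spec("linear"), c(1, 2), c(3, 4)), 11)
  expect_equal(kernel_eval(kernel_spec("poly", d = 2), c(1, 2), c(3, 4)), 144)
  u <- rnorm(7)
  expect_equal(kernel_eval(kernel_spec("rbf", G = 0.3), u, u), 1)
  expect_equal(kernel_eval(kernel_spec("rbf", G = 2), c(0, 0), c(1, 0)), exp(-2))
  expect_error(kernel_eval(kernel_spec("linear"), 1:3, 1:4),
               class = "gaitsym_invalid_arg")
  expect_error(kernel_spec("rbf"), class = "gaitsym_invalid_kernel")
})

test_that("the SMO solver separates toy problems and satisfies dual feasibility", {
  set.seed(41)
  X <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1)
  y <- rep(c(-1, 1), each = 20)
  m <- svm_train(X, y, kernel_spec("linear"), C = 1)
  expect_true(m$converged)
  expect_equal(unname(predict(m, X)), y)
  # decision boundary sign changes between the clusters
  expect_lt(predict(m, matrix(-5), type = "decision"), 0)
  expect_gt(predict(m, matrix(5), type = "decision"), 0)

  # XOR needs the non-linear kernel
  Xx <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  yx <- c(-1, -1, 1, 1)
  mx <- svm_train(Xx, yx, kernel_spec("rbf", G = 1), C = 100, standardize = FALSE)
  expect_equal(unname(predict(mx, Xx)), yx)

  # dual feasibility on random problems with assorted kernels
  for (i in 1:8) {
    set.seed(100 + i)
    n <- 30; p <- 6
    Xr <- matrix(rnorm(n * p), n)
    yr <- ifelse(Xr[, 1] + rnorm(n, 0, 0.6) > 0, 1, -1)
    if (length(unique(yr)) < 2) next
    spec <- list(kernel_spec("linear"), kernel_spec("rbf", G = 0.2),
                 kernel_spec("poly", d = 3))[[1 + i %% 3]]
    Cc <- c(0.1, 1, 10)[1 + i %% 3]
    mr <- suppressWarnings(svm_train(Xr, yr, spec, Cc))
    expect_true(all(mr$alpha >= -1e-10))
    expect_true(all(mr$alpha <= Cc + 1e-10))
    expect_lt(abs(sum(mr$alpha * mr$y)), 1e-6)
  }
})

test_that("predictions agree with an independent SVM implementation", {
  library(e1071)
  agree <- c()
  for (i in 1:20) {
    set.seed(200 + i)
    n <- 40; p <- 5
    Xr <- matrix(rnorm(n * p), n)
    yr <- ifelse(Xr[, 1] + rnorm(n, 0, 0.5) > 0, 1, -1)
    if (length(unique(yr)) < 2) next
    Xt <- matrix(rnorm(20 * p), 20)
    G <- 0.2; Cc <- 10
    ours <- svm_train(Xr, yr, kernel_spec("rbf", G = G), C = Cc)
    ref <- e1071::svm(Xr, factor(yr, levels = c(-1, 1)), kernel = "radial",
                      gamma = G, cost = Cc, scale = TRUE)
    agree <- c(agree, mean(predict(ours, Xt) ==
                             as.numeric(as.character(predict(ref, Xt)))))
  }
  expect_gte(mean(agree), 0.95)
})

test_that("ties at decision value zero go to +1", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- c(-1, 1)
  m <- svm_train(X, y, kernel_spec("linear"), C = 1, standardize = FALSE)
  expect_equal(unname(predict(m, matrix(0))), 1)
  expect_equal(unname(predict(m, matrix(0), type = "decision")), 0,
               tolerance = 1e-9)
})

test_that("classification metrics use the published cross-denominator forms", {
  m <- evaluate_classification(c(-1, -1, 1, 1), c(-1, -1, 1, 1))
  expect_equal(c(m$ACC, m$SEN, m$SEP), c(1, 1, 1))

  # frozen from the uniquely invertible published triple at n = 34
  truth <- c(rep(-1, 17), rep(1, 17))
  pred <- c(rep(-1, 16), 1, rep(1, 12), rep(-1, 5))
  m2 <- evaluate_classification(truth, pred)
  expect_equal(c(m2$T1, m2$T2, m2$F1, m2$F2), c(16, 12, 1, 5))
  expect_equal(m2$ACC, 28 / 34)
  expect_equal(m2$SEN, 16 / 21)
  expect_equal(m2$SEP, 12 / 13)

  # undefined denominator -> NA with classed warning, not zero
  expect_warning(m3 <- evaluate_classification(c(1, 1), c(1, 1)),
                 class = "gaitsym_undefined_metric")
  expect_true(is.na(m3$SEN))
  expect_equal(m3$SEP, 1)
})

test_that("cross-validation is stratified, seeded and calibrated", {
  set.seed(51)
  X <- matrix(c(rnorm(30, -4), rnorm(30, 4)), ncol = 1)
  y <- rep(c(-1, 1), each = 30)
  expect_equal(cross_validate(X, y, "linear", C = 1, seed = 1), 1.0)
  expect_identical(cross_validate(X, y, "rbf", C = 1, G = 0.5, seed = 9),
                   cross_validate(X, y, "rbf", C = 1, G = 0.5, seed = 9))
  expect_error(cross_validate(X[1:6, , drop = FALSE], y[c(1:3, 31:33)],
                              k = 5), class = "gaitsym_class_too_small")
})

test_that("grid search returns the brute-force argmax with the stated tie rule", {
  set.seed(52)
  X <- matrix(rnorm(60 * 4), 60)
  y <- ifelse(X[, 1] + rnorm(60, 0, 1.2) > 0, 1, -1)
  C_grid <- c(0.5, 2, 8); G_grid <- c(0.05, 0.5)
  gs <- grid_search(X, y, "rbf", C_grid, G_grid, k = 5, seed = 3)
  # brute force re-evaluation of every cell
  brute <- outer(seq_along(C_grid), seq_along(G_grid), Vectorize(function(i, j)
    cross_validate(X, y, "rbf", C_grid[i], G_grid[j], k = 5, seed = 3)))
  expect_equal(gs$cv_accuracy, max(brute))
  hit <- which(brute == max(brute), arr.ind = TRUE)
  hit <- hit[order(C_grid[hit[, 1]], G_grid[hit[, 2]]), , drop = FALSE]
  expect_equal(gs$best_C, C_grid[hit[1, 1]])
  expect_equal(gs$best_G, G_grid[hit[1, 2]])

  # grid of one point returns it
  g1 <- grid_search(X, y, "rbf", C_grid = 4, G_grid = 0.1, k = 5, seed = 3)
  expect_equal(g1$best_C, 4)
  expect_equal(g1$best_G, 0.1)

  # tie between two C values on separable data -> smaller C
  Xs <- matrix(c(rnorm(30, -6), rnorm(30, 6)), ncol = 1)
  ys <- rep(c(-1, 1), each = 30)
  gt <- grid_search(Xs, ys, "linear", C_grid = c(1, 4), G_grid = 1, k = 5, seed = 1)
  expect_equal(gt$best_C, 1)
})

test_that("feature-set construction yields the factorial row counts", {
  curves <- study_curves()
  fs <- build_feature_sets(curves, "lr", "X")
  expect_equal(dim(fs$X), c(168, 101))
  expect_equal(sum(fs$y == -1), 84)
  expect_equal(sum(fs$y == 1), 84)

  sfb <- build_feature_sets(study_sf(), "fatigue", "Z")
  expect_equal(dim(sfb$X), c(84, 101))
  expect_equal(sum(sfb$y == -1), 42)

  # null dataset: class means of the fatigue features nearly coincide
  cvn <- simulate_curves(4, 2, "null", noise_spec(0.02, 10), seed = 61)
  fb <- build_feature_sets(sf_dataset(cvn), "fatigue", "X")
  gap <- abs(colMeans(fb$X[fb$y == 1, ]) - colMeans(fb$X[fb$y == -1, ]))
  expect_lt(max(gap), 0.5)   # within the noise floor, no systematic effect

  expect_error(build_feature_sets(curves[curves$condition == "pre", ],
                                  "fatigue", "X"))
})

test_that("confusion recovery certifies unique, ambiguous and impossible triples", {
  # ACC 54.167%, SEP 52.2% at n = 24 force (1, 12, 11, 0) and SEN = 100%
  r1 <- recover_confusion(24, acc = 0.54167, sep = 0.522,
                          digits = c(acc = 5, sep = 3))
  expect_equal(r1$status, "unique")
  expect_equal(unlist(r1$solutions[1, 1:4]), c(T1 = 1, T2 = 12, F1 = 11, F2 = 0))
  expect_equal(r1$solutions$sen[1], 1.0)

  # two metrics alone can be ambiguous; the third printed value resolves it
  r2 <- recover_confusion(24, acc = 0.625, sen = 0.667)
  expect_equal(r2$status, "ambiguous")
  expect_equal(nrow(r2$solutions), 7)
  r3 <- recover_confusion(24, acc = 0.625, sen = 0.667, sep = 0.60)
  expect_equal(r3$status, "unique")
  expect_equal(unlist(r3$solutions[1, 1:4]), c(T1 = 6, T2 = 9, F1 = 6, F2 = 3))

  # jointly inconsistent printed triple at n = 34
  r4 <- recover_confusion(34, acc = 0.85294, sen = 0.842, sep = 0.933,
                          digits = c(acc = 5, sen = 3, sep = 3))
  expect_equal(r4$status, "none")

  expect_error(recover_confusion(24, acc = 0.5), class = "gaitsym_invalid_arg")
})
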