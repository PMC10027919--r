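#' Confusion counts and ACC/SEN/SEP
#'
#' Feature 1 is encoded as label -1, feature 2 as +1. `T1`/`T2` count
#' correctly recognized feature-1/feature-2 samples and `F1`/`F2` count
#' misrecognized feature-1/feature-2 samples. The metrics follow the
#' cross-denominator convention used in the gait-recognition literature:
#' `ACC = (T1 + T2) / (T1 + F1 + T2 + F2)`, `SEN = T1 / (T1 + F2)`,
#' `SEP = T2 / (T2 + F1)`. A metric whose denominator is zero is reported
#' as `NA` (undefined, not 0) with a classed warning.
#'
#' @param truth,pred label vectors in `{-1, +1}`, equal length.
#' @return object of class `"svm_metrics"`: list with `T1`, `T2`, `F1`,
#'   `F2`, `ACC`, `SEN`, `SEP`.
#' @export
evaluate_classification <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (!all(c(truth, pred) %in% c(-1, 1)))
    gs_error("gaitsym_invalid_arg", "labels must be in {-1, +1}")
  T1 <- sum(truth == -1 & pred == -1); F1 <- sum(truth == -1 & pred == 1)
  T2 <- sum(truth == 1 & pred == 1);  F2 <- sum(truth == 1 & pred == -1)
  ACC <- (T1 + T2) / (T1 + F1 + T2 + F2)
  SEN <- if (T1 + F2 == 0) NA_real_ else T1 / (T1 + F2)
  SEP <- if (T2 + F1 == 0) NA_real_ else T2 / (T2 + F1)
  if (is.na(SEN) || is.na(SEP))
    warning(warningCondition("a metric denominator is zero; reported as NA",
                             class = "gaitsym_undefined_metric"))
  structure(list(T1 = T1, T2 = T2, F1 = F1, F2 = F2,
                 ACC = ACC, SEN = SEN, SEP = SEP), class = "svm_metrics")
}

#' @export
print.svm_metrics <- function(x, ...) {
  cat(sprintf("confusion: T1=%d T2=%d F1=%d F2=%d | ACC=%.3f SEN=%.3f SEP=%.3f\n",
              x$T1, x$T2, x$F1, x$F2, x$ACC, x$SEN, x$SEP))
  invisible(x)
}

# Seeded stratified fold assignment: within each class, shuffled indices
# receive fold ids 1..k cyclically.
stratified_folds <- function(y, k, seed) {
  if (k < 2) gs_error("gaitsym_invalid_arg", "k must be >= 2")
  fold <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        gs_error("gaitsym_class_too_small",
                 sprintf("class %g has %d samples, fewer than k = %d folds",
                         cl, length(idx), k))
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Shared CV engine: evaluates every (C, G) grid cell with the same seeded
# folds, per-fold standardization (training statistics only) and per-fold
# precomputed base matrices (inner products, or squared distances for RBF).
cv_grid <- function(X, y, kind, C_grid, G_grid = NA_real_, k = 5, seed = 1L,
                    d = 3L, tol = 1e-6, max_updates = 1e5) {
  X <- as.matrix(X)
  if (kind != "rbf") G_grid <- NA_real_
  fold <- stratified_folds(y, k, seed)
  acc <- array(0, dim = c(length(C_grid), length(G_grid), k))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, sd); scl[scl == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], ctr, scl)
    Xte <- scale(X[te, , drop = FALSE], ctr, scl)
    Ptr <- Xtr %*% t(Xtr); Pte <- Xte %*% t(Xtr)
    if (kind == "rbf") {
      D2tr <- pmax(outer(diag(Ptr), diag(Ptr), "+") - 2 * Ptr, 0)
      D2te <- pmax(outer(rowSums(Xte^2), diag(Ptr), "+") - 2 * Pte, 0)
    }
    ytr <- y[tr]; yte <- y[te]
    for (gi in seq_along(G_grid)) {
      Ktr <- switch(kind, linear = Ptr, poly = (Ptr + 1)^d,
                    rbf = exp(-G_grid[gi] * D2tr))
      Kte <- switch(kind, linear = Pte, poly = (Pte + 1)^d,
                    rbf = exp(-G_grid[gi] * D2te))
      for (ci in seq_along(C_grid)) {
        fit <- smo_solve(Ktr, ytr, C_grid[ci], tol, as.integer(max_updates))
        dec <- as.numeric(Kte %*% (fit$alpha * ytr)) + fit$b
        acc[ci, gi, f] <- mean(ifelse(dec >= 0, 1, -1) == yte)
      }
    }
  }
  apply(acc, c(1, 2), mean)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Mean held-out accuracy over `k` seeded, class-stratified folds.
#' Features are standardized inside each fold using training-fold
#' statistics only, so no information leaks from the held-out fold.
#'
#' @param X feature matrix; `y` labels in `{-1, +1}`.
#' @param y labels.
#' @param kind kernel type (`"linear"`, `"rbf"`, `"poly"`).
#' @param C soft-margin penalty.
#' @param G RBF width (ignored for other kernels).
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @param d polynomial order.
#' @return scalar cross-validated accuracy.
#' @export
cross_validate <- function(X, y, kind = "linear", C = 1, G = NULL, k = 5,
                           seed = 1L, d = 3L) {
  cv_grid(X, y, kind, C_grid = C, G_grid = G %||% NA_real_, k = k,
          seed = seed, d = d)[1, 1]
}

#' Grid search over C (and G) by cross-validation
#'
#' Evaluates every grid cell with [cross_validate()]'s folds and returns
#' the argmax; ties are broken toward the smaller `C`, then the smaller
#' `G`. `G_grid` is only searched for the RBF kernel.
#'
#' @inheritParams cross_validate
#' @param C_grid,G_grid numeric candidate grids (non-empty).
#' @return list: `best_C`, `best_G` (`NA` for non-RBF), `cv_accuracy`,
#'   `cv_table` (accuracy matrix, C by G).
#' @export
grid_search <- function(X, y, kind = "rbf", C_grid = 2^seq(-5, 15, 2),
                        G_grid = 2^seq(-15, 3, 2), k = 5, seed = 1L, d = 3L) {
  if (length(C_grid) == 0 || (kind == "rbf" && length(G_grid) == 0))
    gs_error("gaitsym_invalid_arg", "parameter grids must be non-empty")
  C_grid <- sort(C_grid)
  G_grid <- if (kind == "rbf") sort(G_grid) else NA_real_
  tab <- cv_grid(X, y, kind, C_grid, G_grid, k, seed, d)
  # argmax with smaller-C-then-smaller-G tie break: first max in column-major
  # order of the C-by-G table scanned G-outer... scan C fastest within G,
  # compare across: take all cells attaining the max, order by (C, G).
  hits <- which(tab == max(tab), arr.ind = TRUE)
  hits <- hits[order(C_grid[hits[, 1]], G_grid[hits[, 2]]), , drop = FALSE]
  list(best_C = C_grid[hits[1, 1]],
       best_G = if (kind == "rbf") G_grid[hits[1, 2]] else NA_real_,
       cv_accuracy = max(tab),
       cv_table = tab)
}

#' Build classification feature sets from curve or SF tables
#'
#' For the left-vs-right task (`"lr"`), each row is one trial's 101-node
#' GRF curve for the chosen axis (both conditions pooled by default) and
#' the label is -1 for left (feature 1), +1 for right (feature 2). For
#' the fatigue task (`"fatigue"`), each row is one trial's 101-node
#' Symmetry Function curve and the label is -1 for pre-fatigue, +1 for
#' post-fatigue.
#'
#' @param table tidy curve table ([preprocess_dataset()]) for `"lr"`, or
#'   SF table ([sf_dataset()]) for `"fatigue"`.
#' @param task `"lr"` or `"fatigue"`.
#' @param axis `"X"`, `"Y"` or `"Z"`.
#' @param conditions for `"lr"`: which conditions to pool (default both).
#' @return list: `X` (feature matrix), `y` (labels), `groups` (subject
#'   ids, for grouped splitting).
#' @export
build_feature_sets <- function(table, task = c("lr", "fatigue"), axis = "X",
                               conditions = c("pre", "post")) {
  task <- match.arg(task)
  if (task == "lr") {
    stopifnot(all(c("side", "value_bw") %in% names(table)))
    d <- table[table$axis == axis & table$condition %in% conditions, ]
    if (nrow(d) == 0) gs_error("gaitsym_invalid_arg", "no rows for the requested axis/conditions")
    key <- interaction(d$subject, d$condition, d$trial, d$side, drop = TRUE)
    rows <- split(d, key)
    n_nodes <- length(unique(d$node))
    X <- t(vapply(rows, function(r) r$value_bw[order(r$node)], numeric(n_nodes)))
    y <- vapply(rows, function(r) if (r$side[1] == "L") -1 else 1, 0)
    groups <- vapply(rows, function(r) as.character(r$subject[1]), "")
  } else {
    stopifnot("sf" %in% names(table))
    d <- table[table$axis == axis, ]
    if (nrow(d) == 0) gs_error("gaitsym_invalid_arg", "no rows for the requested axis")
    if (!all(c("pre", "post") %in% d$condition))
      gs_error("gaitsym_invalid_arg", "fatigue task needs both pre and post conditions")
    key <- interaction(d$subject, d$condition, d$trial, drop = TRUE)
    rows <- split(d, key)
    X <- t(vapply(rows, function(r) r$sf[order(r$node)],
                  numeric(length(unique(d$node)))))
    y <- vapply(rows, function(r) if (r$condition[1] == "pre") -1 else 1, 0)
    groups <- vapply(rows, function(r) as.character(r$subject[1]), "")
  }
  list(X = unname(X), y = unname(y), groups = unname(groups))
}

# Seeded stratified hold-out: about test_n samples, balanced across
# classes; grouped = TRUE holds out whole subjects instead (no subject
# appears in both sets).
holdout_split <- function(y, test_n, seed, groups = NULL, grouped = FALSE) {
  n <- length(y)
  if (test_n <= 0 || test_n >= n)
    gs_error("gaitsym_invalid_arg", "test_n must be in (0, n)")
  with_seed(derive_seed(seed, "split"), {
    if (grouped) {
      if (is.null(groups)) gs_error("gaitsym_invalid_arg", "grouped split needs group ids")
      gs <- sample(unique(groups))
      test <- logical(n)
      for (g in gs) {
        if (sum(test) >= test_n) break
        test[groups == g] <- TRUE
      }
    } else {
      test <- logical(n)
      per <- round(test_n * table(y) / n)
      for (cl in names(per)) {
        idx <- which(y == as.numeric(cl))
        test[sample(idx, min(per[[cl]], length(idx) - 1))] <- TRUE
      }
    }
    list(train = which(!test), test = which(test))
  })
}

#' Full SVM task evaluation: split, grid search, fit, test metrics
#'
#' Stratified hold-out split, C/G grid search by stratified five-fold
#' cross-validation on the training portion, final fit at the selected
#' parameters, and ACC/SEN/SEP on the held-out test set.
#'
#' @param X,y features and labels (see [build_feature_sets()]).
#' @param kind kernel type.
#' @param C_grid,G_grid search grids.
#' @param k CV folds.
#' @param test_n held-out test-set size.
#' @param seed integer seed (folds and split).
#' @param d polynomial order.
#' @param groups,grouped optional subject-grouped splitting (keeps each
#'   subject wholly in train or test; guards identity leakage).
#' @return object of class `"svm_eval"`: kernel, `best_C`, `best_G`,
#'   `cv_accuracy`, `metrics` (an `"svm_metrics"`), `n_train`, `n_test`.
#' @export
svm_evaluate <- function(X, y, kind = "rbf", C_grid = 2^seq(-5, 15, 2),
                         G_grid = 2^seq(-15, 3, 2), k = 5, test_n = NULL,
                         seed = 1L, d = 3L, groups = NULL, grouped = FALSE) {
  X <- as.matrix(X)
  test_n <- test_n %||% round(0.2 * length(y))
  sp <- holdout_split(y, test_n, seed, groups, grouped)
  gs <- grid_search(X[sp$train, , drop = FALSE], y[sp$train], kind,
                    C_grid, G_grid, k, seed, d)
  spec <- switch(kind,
    linear = kernel_spec("linear"),
    poly = kernel_spec("poly", d = d),
    rbf = kernel_spec("rbf", G = gs$best_G))
  model <- svm_train(X[sp$train, , drop = FALSE], y[sp$train], spec, gs$best_C)
  pred <- predict(model, X[sp$test, , drop = FALSE])
  metrics <- evaluate_classification(y[sp$test], pred)
  structure(list(kernel = kind, best_C = gs$best_C, best_G = gs$best_G,
                 cv_accuracy = gs$cv_accuracy, metrics = metrics,
                 n_train = length(sp$train), n_test = length(sp$test),
                 d = d, grouped = grouped),
            class = "svm_eval")
}

#' @export
print.svm_eval <- function(x, ...) {
  cat(sprintf("<svm_eval> kernel %s | best C = %g, best G = %s, CVAcc = %.3f\n",
              x$kernel, x$best_C,
              if (is.na(x$best_G)) "-" else format(x$best_G), x$cv_accuracy))
  cat(sprintf("  test (n = %d): ", x$n_test)); print(x$metrics)
  invisible(x)
}

#' Recover a confusion matrix from printed metrics
#'
#' Exhaustively enumerates all non-negative integer confusion matrices
#' `(T1, T2, F1, F2)` with the given total whose ACC/SEN/SEP
#' (cross-denominator convention, see [evaluate_classification()]) round
#' to the supplied values at their printed precision. Used to audit
#' published metric triples: the report states whether the printed values
#' are uniquely invertible, ambiguous, or internally inconsistent.
#'
#' @param total_n total test-set size.
#' @param acc,sen,sep printed metric values as proportions (e.g. `0.625`);
#'   `NULL` means unknown. At least two must be given.
#' @param digits printed decimal places used for rounding comparison;
#'   a single integer or a named vector like `c(acc = 5, sen = 3)`.
#' @return object of class `"confusion_recovery"`: list with `status`
#'   (`"unique"`, `"ambiguous"` or `"none"`) and `solutions` (data.frame
#'   of all consistent matrices with their exact metrics).
#' @examples
#' # printed triple ACC = 54.167%, SEP = 52.2% at n = 24 forces SEN = 100%
#' recover_confusion(24, acc = 0.54167, sep = 0.522, digits = c(acc = 5, sep = 3))
#' @export
recover_confusion <- function(total_n, acc = NULL, sen = NULL, sep = NULL,
                              digits = 3) {
  known <- c(acc = !is.null(acc), sen = !is.null(sen), sep = !is.null(sep))
  if (sum(known) < 2)
    gs_error("gaitsym_invalid_arg", "need at least two known metrics")
  dig <- function(m) {
    if (length(digits) == 1 && is.null(names(digits))) return(as.integer(digits))
    as.integer(digits[[m]] %||% 3)
  }
  g <- expand.grid(T1 = 0:total_n, T2 = 0:total_n, F1 = 0:total_n)
  g <- g[g$T1 + g$T2 + g$F1 <= total_n, ]
  g$F2 <- total_n - g$T1 - g$T2 - g$F1
  g$acc <- (g$T1 + g$T2) / total_n
  g$sen <- ifelse(g$T1 + g$F2 > 0, g$T1 / (g$T1 + g$F2), NA)
  g$sep <- ifelse(g$T2 + g$F1 > 0, g$T2 / (g$T2 + g$F1), NA)
  ok <- rep(TRUE, nrow(g))
  match_metric <- function(x, v, d) !is.na(x) & abs(round(x, d) - round(v, d)) < 1e-9
  if (known["acc"]) ok <- ok & match_metric(g$acc, acc, dig("acc"))
  if (known["sen"]) ok <- ok & match_metric(g$sen, sen, dig("sen"))
  if (known["sep"]) ok <- ok & match_metric(g$sep, sep, dig("sep"))
  sols <- g[ok, c("T1", "T2", "F1", "F2", "acc", "sen", "sep")]
  rownames(sols) <- NULL
  status <- if (nrow(sols) == 0) "none" else if (nrow(sols) == 1) "unique" else "ambiguous"
  structure(list(status = status, total_n = total_n, solutions = sols),
            class = "confusion_recovery")
}

#' @export
print.confusion_recovery <- function(x, ...) {
  cat(sprintf("<confusion_recovery> n = %d: %s", x$total_n,
              switch(x$status,
                     unique = "unique solution\n",
                     ambiguous = sprintf("%d consistent matrices (ambiguous)\n",
                                         nrow(x$solutions)),
                     none = "no consistent matrix (printed metrics are internally inconsistent)\n")))
  if (nrow(x$solutions)) print(x$solutions, row.names = FALSE)
  invisible(x)
}
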