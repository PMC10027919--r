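#' Kernel specification
#'
#' The three kernels used for gait classification:
#' \describe{
#'   \item{linear}{`K(u, v) = u . v`}
#'   \item{rbf}{`K(u, v) = exp(-||u - v||^2 / (2 sigma^2))` with the width
#'     parameterised libsvm-style as `sigma^2 = 1 / (2 G)`, i.e.
#'     `K = exp(-G ||u - v||^2)`. Larger `G` means a narrower kernel and a
#'     higher-dimensional effective mapping.}
#'   \item{poly}{`K(u, v) = (u . v + 1)^d` of order `d` (default 3).}
#' }
#'
#' @param kind kernel type.
#' @param G RBF width parameter (> 0; required for `"rbf"`).
#' @param d polynomial order (integer >= 1).
#' @return object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf", "poly"), G = NULL, d = 3L) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.null(G) || G <= 0)
      gs_error("gaitsym_invalid_kernel", "RBF kernel requires G > 0")
  }
  if (kind == "poly" && (d < 1 || d != round(d)))
    gs_error("gaitsym_invalid_kernel", "poly order d must be an integer >= 1")
  structure(list(kind = kind, G = G, d = as.integer(d)), class = "kernel_spec")
}

#' Evaluate a kernel on two feature vectors
#'
#' @param spec a [kernel_spec()].
#' @param u,v numeric vectors of equal length.
#' @return scalar kernel value.
#' @examples
#' kernel_eval(kernel_spec("poly", d = 2), c(1, 2), c(3, 4))  # (11 + 1)^2
#' @export
kernel_eval <- function(spec, u, v) {
  if (length(u) != length(v))
    gs_error("gaitsym_invalid_arg", "feature vectors must have equal length")
  switch(spec$kind,
    linear = sum(u * v),
    rbf = exp(-spec$G * sum((u - v)^2)),
    poly = (sum(u * v) + 1)^spec$d)
}

# Kernel Gram matrix between the rows of X and Y.
kernel_matrix <- function(spec, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  P <- X %*% t(Y)
  switch(spec$kind,
    linear = P,
    poly = (P + 1)^spec$d,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * P
      exp(-spec$G * pmax(d2, 0))
    })
}

#' Train a soft-margin kernel SVM
#'
#' Solves the dual quadratic program
#' `min_beta  -sum(beta) + 0.5 beta' (y y' * K) beta` subject to
#' `0 <= beta_i <= C` and `sum(beta_i y_i) = 0` with a deterministic SMO
#' solver, and classifies by
#' `f(x) = sign(sum_i beta_i y_i K(x_i, x) + b)`. Features are
#' standardized per column with training means and standard deviations
#' (stored in the model and reapplied at prediction).
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels in `{-1, +1}`; both classes must be present.
#' @param kernel a [kernel_spec()].
#' @param C soft-margin penalty (> 0).
#' @param standardize standardize columns with training statistics.
#' @param tol KKT violation tolerance.
#' @param max_updates SMO pair-update budget.
#' @return object of class `"gait_svm"`.
#' @export
svm_train <- function(X, y, kernel = kernel_spec("linear"), C = 1,
                      standardize = TRUE, tol = 1e-6, max_updates = 5e5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2 || !all(sort(unique(y)) %in% c(-1, 1)) || length(unique(y)) < 2)
    gs_error("gaitsym_invalid_arg",
             "need >= 2 samples with labels in {-1, +1} and both classes present")
  if (C <= 0) gs_error("gaitsym_invalid_arg", "C must be positive")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, ctr, scl)
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    Xs <- X
  }
  K <- kernel_matrix(kernel, Xs)
  fit <- smo_solve(K, y, C, tol, as.integer(max_updates))
  if (!fit$converged)
    warning("SMO did not reach KKT tolerance within the update budget",
            call. = FALSE)
  structure(list(alpha = fit$alpha, b = fit$b, y = y, X = unclass(Xs),
                 center = ctr, scale = scl, C = C, kernel = kernel,
                 converged = fit$converged, updates = fit$updates),
            class = "gait_svm")
}

#' Decision values and class predictions
#'
#' @param object a `"gait_svm"` model.
#' @param newdata feature matrix on the original (unstandardized) scale.
#' @param type `"class"` for labels in `{-1, +1}` (ties, decision exactly
#'   0, go to +1) or `"decision"` for raw decision values.
#' @param ... unused.
#' @return numeric vector of labels or decision values.
#' @export
predict.gait_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != length(object$center))
    gs_error("gaitsym_invalid_arg", "feature length mismatch with the trained model")
  Xn <- scale(Xn, object$center, object$scale)
  dec <- as.numeric(kernel_matrix(object$kernel, Xn, object$X) %*%
                      (object$alpha * object$y)) + object$b
  if (type == "decision") dec else ifelse(dec >= 0, 1, -1)
}

#' @export
print.gait_svm <- function(x, ...) {
  cat(sprintf("<gait_svm> kernel %s%s, C = %g, %d samples, %d support vectors\n",
              x$kernel$kind,
              if (x$kernel$kind == "rbf") sprintf(" (G = %g)", x$kernel$G)
              else if (x$kernel$kind == "poly") sprintf(" (d = %d)", x$kernel$d)
              else "",
              x$C, length(x$y), sum(x$alpha > 1e-8)))
  invisible(x)
}
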