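#' Single-task linear ridge regression
#'
#' Fits `w = argmin sum_i (w'x_i - y_i)^2 + lambda ||w||^2` by the primal
#' closed form, using a symmetric positive-definite (Cholesky) solve. There
#' is no intercept by default, matching the penalised least-squares form;
#' `center = TRUE` subtracts the training-label mean before fitting and adds
#' it back at prediction, which is the only intercept policy supported.
#'
#' @param x a [task_dataset()], or a numeric n x d matrix.
#' @param y response vector (ignored when `x` is a task).
#' @param lambda ridge regularisation, a positive number. The default 10 is
#'   the value selected once by five-fold cross-validation over the five
#'   standard grid regions and then held fixed for all comparisons.
#' @param center subtract the mean of `y` before fitting (default `FALSE`).
#' @return an object of class `sirna_ridge` with components `coefficients`
#'   (the weight vector `w`), `lambda`, `center`, `mu` (the training-label
#'   mean used, 0 when uncentred), `fitted.values`, `residuals`, and the
#'   training data (`x`, `y`) needed for dual-form prediction.
#' @seealso [predict.sirna_ridge()] for primal and dual prediction,
#'   [cv_select_lambda()] for the cross-validation search.
#' @export
ridge_fit <- function(x, y = NULL, lambda = 10, center = FALSE) {
  if (inherits(x, "task_dataset")) {
    y <- x$y
    x <- x$X
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in the training data")
  }
  mu <- if (center) mean(y) else 0
  yc <- y - mu
  d <- ncol(x)
  A <- crossprod(x) + diag(lambda, d)
  w <- drop(.spd_solve(A, crossprod(x, yc)))
  names(w) <- colnames(x)
  fitted <- drop(x %*% w) + mu
  structure(
    list(coefficients = w, lambda = lambda, center = center, mu = mu,
         fitted.values = fitted, residuals = y - fitted,
         x = x, y = y, call = match.call()),
    class = "sirna_ridge"
  )
}

## Solve A b = c for symmetric positive-definite A via Cholesky.
.spd_solve <- function(A, b) {
  R <- chol(A)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' Predict from a ridge fit, primal or dual form
#'
#' The primal form evaluates `w'x`. The dual form evaluates
#' `kappa' (K + lambda I)^{-1} y` with `K` the Gram matrix of training dot
#' products and `kappa` the dot products of the query with the training
#' points; both forms agree to numerical precision and the dual never forms
#' `w` explicitly.
#'
#' @param object a `sirna_ridge` fit.
#' @param newdata numeric matrix (or vector) of query points.
#' @param method `"primal"` (default) or `"dual"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.sirna_ridge <- function(object, newdata,
                                method = c("primal", "dual"), ...) {
  method <- match.arg(method)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    stop("newdata has ", ncol(newdata), " columns, expected ", ncol(object$x))
  }
  if (method == "primal") {
    return(drop(newdata %*% object$coefficients) + object$mu)
  }
  K <- tcrossprod(object$x)
  alpha <- .spd_solve(K + diag(object$lambda, nrow(K)),
                      object$y - object$mu)
  kappa <- tcrossprod(newdata, object$x)
  drop(kappa %*% alpha) + object$mu
}

#' @export
coef.sirna_ridge <- function(object, ...) object$coefficients

#' @export
residuals.sirna_ridge <- function(object, ...) object$residuals

#' @export
fitted.sirna_ridge <- function(object, ...) object$fitted.values

#' @export
print.sirna_ridge <- function(x, ...) {
  cat(sprintf("Ridge regression fit: n=%d, d=%d, lambda=%g%s\n",
              nrow(x$x), ncol(x$x), x$lambda,
              if (x$center) ", label-centred" else ""))
  cat(sprintf("Training RMSE: %.4f\n", rmse(x$y, x$fitted.values)))
  invisible(x)
}

#' @export
summary.sirna_ridge <- function(object, ...) {
  out <- list(
    n = nrow(object$x), d = ncol(object$x), lambda = object$lambda,
    center = object$center,
    train_rmse = rmse(object$y, object$fitted.values),
    coefficients = object$coefficients
  )
  class(out) <- "summary.sirna_ridge"
  out
}

#' @export
print.summary.sirna_ridge <- function(x, ...) {
  cat(sprintf("Ridge regression: n=%d, d=%d, lambda=%g\n", x$n, x$d, x$lambda))
  cat(sprintf("Training RMSE: %.4f\n", x$train_rmse))
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' The five-region regularisation grid
#'
#' Candidate lambda values from the five standard search regions —
#' \[0.001, 0.1\] step 0.001, \[0.01, 0.1\] step 0.01, \[0.1, 1\] step 0.1,
#' \[1, 10\] step 1 and \[10, 100\] step 10 — with duplicates across regions
#' removed.
#'
#' @return sorted numeric vector of unique candidate values.
#' @export
lambda_grid <- function() {
  g <- c(seq(0.001, 0.1, by = 0.001),
         seq(0.01, 0.1, by = 0.01),
         seq(0.1, 1, by = 0.1),
         seq(1, 10, by = 1),
         seq(10, 100, by = 10))
  sort(unique(round(g, 10)))
}

#' Select lambda by cross-validation over all tasks
#'
#' Runs k-fold cross-validation independently within every task and, for each
#' candidate lambda in [lambda_grid()], accumulates the prediction error over
#' all folds of all tasks; the lambda minimising the total error is returned.
#' Tasks with fewer samples than folds fall back to leave-one-out (noted via
#' a message); fold assignment is a seeded uniform shuffle into folds of
#' near-equal size.
#'
#' @param tc a [task_collection()] (a single task is promoted).
#' @param folds number of folds, default 5.
#' @param seed optional integer seed for the fold shuffle.
#' @param error `"sse"` (default) accumulates squared error, `"rmse"`
#'   accumulates per-fold RMSE.
#' @param center centre labels per task during the fits.
#' @param grid candidate values, defaulting to [lambda_grid()].
#' @return the selected lambda, with the full error curve attached as
#'   attribute `"cv"` (a data.frame of lambda and total error).
#' @export
cv_select_lambda <- function(tc, folds = 5L, seed = NULL,
                             error = c("sse", "rmse"), center = FALSE,
                             grid = lambda_grid()) {
  error <- match.arg(error)
  if (inherits(tc, "task_dataset")) {
    tc <- task_collection(list(tc), "experiment")
  }
  validate_tasks(tc)
  total <- numeric(length(grid))
  with_seed(seed, {
    for (task in tc$tasks) {
      n <- nrow(task$X)
      if (n < 2L) {
        message("task '", task$task_id, "' has n<2; skipped in CV")
        next
      }
      k <- folds
      if (n < folds) {
        message("task '", task$task_id, "' too small for ", folds,
                "-fold CV; using leave-one-out")
        k <- n
      }
      assign_fold <- sample(rep_len(seq_len(k), n))
      for (f in seq_len(k)) {
        te <- assign_fold == f
        Xtr <- task$X[!te, , drop = FALSE]
        ytr <- task$y[!te]
        mu <- if (center) mean(ytr) else 0
        G <- crossprod(Xtr)
        b <- crossprod(Xtr, ytr - mu)
        for (j in seq_along(grid)) {
          w <- .spd_solve(G + diag(grid[j], ncol(Xtr)), b)
          pred <- drop(task$X[te, , drop = FALSE] %*% w) + mu
          e2 <- (task$y[te] - pred)^2
          total[j] <- total[j] +
            if (error == "sse") sum(e2) else sqrt(mean(e2))
        }
      }
    }
  })
  best <- grid[which.min(total)]
  attr(best, "cv") <- data.frame(lambda = grid, error = total)
  best
}
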