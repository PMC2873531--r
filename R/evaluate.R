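#' Root mean squared error
#'
#' `sqrt(mean((y - yhat)^2))` — the residual spread with the 1/n convention.
#' Smaller is better.
#'
#' @param y_true,y_pred numeric vectors of equal length (n >= 1).
#' @return non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  }
  if (length(y_true) < 1L) stop("empty vectors")
  sqrt(mean((y_true - y_pred)^2))
}

#' Min-max scale task labels to \[0, 1\]
#'
#' Maps every task's labels onto \[0, 1\] by its own range and records the
#' per-task transform so predictions can be mapped back exactly to the native
#' scale. By default the observed label range of each task is used (e.g. the
#' training portion's range, when applied to a training split); the stored
#' `label_min`/`label_max` bounds can be used instead.
#'
#' @param tc a [task_collection()].
#' @param use_bounds use the tasks' stored label bounds instead of the
#'   observed ranges.
#' @return list with `collection` (labels scaled, bounds set to \[0, 1\]) and
#'   `transforms` (data.frame of `task_id`, `lo`, `hi`).
#' @seealso [unscale_labels()]
#' @export
scale_task_labels <- function(tc, use_bounds = FALSE) {
  validate_tasks(tc)
  lo <- numeric(length(tc$tasks))
  hi <- numeric(length(tc$tasks))
  for (t in seq_along(tc$tasks)) {
    task <- tc$tasks[[t]]
    lo[t] <- if (use_bounds) task$label_min else min(task$y)
    hi[t] <- if (use_bounds) task$label_max else max(task$y)
    if (hi[t] <= lo[t]) {
      stop("task '", task$task_id, "' has a degenerate label range")
    }
    tc$tasks[[t]]$y <- (task$y - lo[t]) / (hi[t] - lo[t])
    tc$tasks[[t]]$label_min <- 0
    tc$tasks[[t]]$label_max <- 1
  }
  list(collection = tc,
       transforms = data.frame(
         task_id = names(tc$tasks), lo = lo, hi = hi,
         stringsAsFactors = FALSE))
}

#' Map \[0, 1\]-scaled labels (or predictions) back to a task's native scale
#'
#' @param y numeric vector on the \[0, 1\] scale.
#' @param transforms the `transforms` table from [scale_task_labels()].
#' @param task_id which task's transform to invert.
#' @return numeric vector on the native scale.
#' @export
unscale_labels <- function(y, transforms, task_id) {
  i <- match(task_id, transforms$task_id)
  if (is.na(i)) stop("no transform recorded for task '", task_id, "'")
  y * (transforms$hi[i] - transforms$lo[i]) + transforms$lo[i]
}

#' Paired t-test on per-task error vectors
#'
#' Compares two models by their aligned per-task RMSE vectors `a` and `b`:
#' with differences `d_i = a_i - b_i`, the statistic is
#' `t = dbar / (s_d / sqrt(k))` on `k - 1` degrees of freedom, with a
#' two-sided p-value from Student's t distribution. Also reports how many
#' tasks the second model wins (`b_i < a_i`).
#'
#' @param a,b numeric vectors of per-task errors, aligned task by task,
#'   length k >= 2.
#' @param labels optional character vector naming the two models.
#' @return an object of class `paired_rmse_test` with components `diffs`,
#'   `d_bar`, `s_d`, `t_stat`, `df`, `p_value`, `wins` and the inputs.
#' @export
paired_rmse_test <- function(a, b, labels = c("model A", "model B")) {
  if (length(a) != length(b)) stop("a and b must be aligned (equal length)")
  k <- length(a)
  if (k < 2L) stop("need at least 2 paired tasks")
  d <- a - b
  d_bar <- mean(d)
  s_d <- stats::sd(d)
  if (s_d == 0) {
    stop("all paired differences are identical: t statistic undefined")
  }
  t_stat <- d_bar / (s_d / sqrt(k))
  df <- k - 1L
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(
    list(rmse_a = a, rmse_b = b, labels = labels, diffs = d,
         d_bar = d_bar, s_d = s_d, t_stat = t_stat, df = df,
         p_value = p, wins = sum(b < a)),
    class = "paired_rmse_test"
  )
}

#' @export
print.paired_rmse_test <- function(x, digits = 4, ...) {
  cat(sprintf("Paired t-test on per-task RMSE: %s vs %s\n",
              x$labels[1], x$labels[2]))
  cat(sprintf("  mean difference %.4f (sd %.4f), t = %.4f, df = %d\n",
              x$d_bar, x$s_d, x$t_stat, x$df))
  cat(sprintf("  two-sided p-value = %.4f\n", x$p_value))
  cat(sprintf("  %s better in %d of %d tasks\n",
              x$labels[2], x$wins, length(x$diffs)))
  invisible(x)
}
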