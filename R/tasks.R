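#' A single regression task
#'
#' Bundles one task's covariate matrix and response vector: one RNAi
#' experiment (or one target mRNA) and the efficacies of its siRNAs. The
#' label bounds record the platform's native scale; they default to the
#' observed range.
#'
#' @param X numeric matrix, n x d, one row per siRNA.
#' @param y numeric response vector of length n (efficacy, native scale).
#' @param task_id character scalar identifying the task.
#' @param label_min,label_max native label-scale bounds; default to the
#'   observed range of `y`.
#' @return an object of class `task_dataset`.
#' @export
task_dataset <- function(X, y, task_id, label_min = NULL, label_max = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 1L) stop("task '", task_id, "' has no samples")
  if (nrow(X) != length(y)) {
    stop("task '", task_id, "': nrow(X) != length(y)")
  }
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y))) {
    stop("task '", task_id, "' contains missing or non-finite entries")
  }
  if (is.null(label_min)) label_min <- min(y)
  if (is.null(label_max)) label_max <- max(y)
  if (label_min > label_max) {
    stop("task '", task_id, "': label_min > label_max")
  }
  structure(
    list(X = X, y = y, task_id = as.character(task_id),
         label_min = label_min, label_max = label_max),
    class = "task_dataset"
  )
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("Task '%s': %d siRNAs, %d features, labels [%g, %g]\n",
              x$task_id, nrow(x$X), ncol(x$X), x$label_min, x$label_max))
  invisible(x)
}

#' @export
dim.task_dataset <- function(x) dim(x$X)

#' A collection of tasks sharing one feature space
#'
#' @param tasks list of [task_dataset()] objects sharing the same number of
#'   features; names are taken from the task ids.
#' @param granularity `"experiment"` (one task per RNAi experiment) or
#'   `"mrna"` (one task per target transcript).
#' @return an object of class `task_collection`.
#' @export
task_collection <- function(tasks, granularity = c("experiment", "mrna")) {
  granularity <- match.arg(granularity)
  tc <- structure(
    list(tasks = tasks, granularity = granularity),
    class = "task_collection"
  )
  names(tc$tasks) <- vapply(tasks, function(t) t$task_id, character(1))
  validate_tasks(tc)
}

#' Validate a task collection
#'
#' Checks that the collection is non-empty, that every element is a
#' `task_dataset`, that all tasks share the same feature dimension and that
#' task ids are unique. Returns the collection unchanged when all invariants
#' hold.
#'
#' @param tc a [task_collection()].
#' @return `tc`, invisibly usable.
#' @export
validate_tasks <- function(tc) {
  if (!inherits(tc, "task_collection")) stop("not a task_collection")
  if (length(tc$tasks) == 0L) stop("empty task collection")
  ok <- vapply(tc$tasks, inherits, logical(1), what = "task_dataset")
  if (!all(ok)) stop("collection elements must be task_dataset objects")
  ds <- vapply(tc$tasks, function(t) ncol(t$X), integer(1))
  if (length(unique(ds)) != 1L) {
    off <- names(ds)[ds != ds[1]][1]
    stop(sprintf(
      "feature dimension mismatch: task '%s' has d=%d, expected d=%d",
      off, ds[[off]], ds[[1]]))
  }
  ids <- vapply(tc$tasks, function(t) t$task_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated task ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tc
}

#' @export
print.task_collection <- function(x, ...) {
  ns <- vapply(x$tasks, function(t) nrow(t$X), integer(1))
  cat(sprintf("Task collection (%s level): %d tasks, d=%d, n per task %d-%d\n",
              x$granularity, length(x$tasks), ncol(x$tasks[[1]]$X),
              min(ns), max(ns)))
  invisible(x)
}

#' @export
length.task_collection <- function(x) length(x$tasks)

#' Number of features shared by a collection
#' @param tc a [task_collection()].
#' @return integer feature dimension.
#' @export
n_features <- function(tc) ncol(tc$tasks[[1]]$X)

#' Build experiment-level tasks from records and a feature matrix
#'
#' Groups the rows of a record table by experiment identifier; every group
#' becomes one [task_dataset()] whose rows are the matching rows of `X`.
#'
#' @param records validated siRNA record data.frame (see [sirna-records]).
#' @param X numeric feature matrix aligned row-by-row with `records`.
#' @return a [task_collection()] at experiment granularity.
#' @export
build_experiment_tasks <- function(records, X) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(records)) stop("X and records are not aligned")
  groups <- split(seq_len(nrow(records)), records$experiment)
  tasks <- lapply(names(groups), function(id) {
    i <- groups[[id]]
    task_dataset(X[i, , drop = FALSE], records$efficacy[i], id)
  })
  task_collection(tasks, "experiment")
}

#' Build mRNA-level tasks from records and a feature matrix
#'
#' Groups siRNAs by target mRNA accession and keeps only mRNAs with more than
#' `min_sirnas` bound siRNAs; transcripts with too few instances cannot be
#' treated as a task. Warns and errors if no group survives.
#'
#' @param records validated siRNA record data.frame.
#' @param X numeric feature matrix aligned with `records`.
#' @param min_sirnas groups must have strictly more siRNAs than this
#'   (default 5).
#' @return a [task_collection()] at mRNA granularity.
#' @export
build_mrna_tasks <- function(records, X, min_sirnas = 5L) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(records)) stop("X and records are not aligned")
  groups <- split(seq_len(nrow(records)), records$mrna)
  groups <- groups[vapply(groups, length, integer(1)) > min_sirnas]
  if (length(groups) == 0L) {
    warning("no mRNA has more than ", min_sirnas, " siRNAs")
    stop("empty task collection")
  }
  tasks <- lapply(names(groups), function(id) {
    i <- groups[[id]]
    task_dataset(X[i, , drop = FALSE], records$efficacy[i], id)
  })
  task_collection(tasks, "mrna")
}

## Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
## RNG stream is untouched. seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Split one task into a training and a test part
#'
#' Uniform random split without replacement. The training size is
#' `train_frac * n` rounded half-up, clamped to keep both parts non-empty.
#'
#' @param task a [task_dataset()].
#' @param train_frac fraction of samples used for training, in (0, 1).
#' @param seed optional integer; when given, the split is reproducible and
#'   the caller's RNG state is left untouched.
#' @return list with elements `train` and `test`, both [task_dataset()]s
#'   keeping the parent's label bounds.
#' @export
split_task <- function(task, train_frac, seed = NULL) {
  n <- nrow(task$X)
  if (n < 2L) stop("task '", task$task_id, "' has fewer than 2 samples")
  if (!(train_frac > 0 && train_frac < 1)) stop("train_frac must be in (0,1)")
  n_train <- floor(train_frac * n + 0.5)   # round half up
  n_train <- min(max(n_train, 1L), n - 1L) # both parts non-empty
  idx <- with_seed(seed, sample.int(n, n_train))
  part <- function(i) {
    task_dataset(task$X[i, , drop = FALSE], task$y[i], task$task_id,
                 task$label_min, task$label_max)
  }
  list(train = part(idx), test = part(setdiff(seq_len(n), idx)))
}

#' Standardise feature columns
#'
#' Centres each column to zero mean and scales to unit variance (constant
#' columns are left unscaled). The transform is recorded so it can be
#' inverted with [unstandardize_features()]; ridge and multi-task penalties
#' are scale-sensitive, so feature matrices are standardised before fitting.
#'
#' @param X numeric matrix; or a [task_collection()], in which case the
#'   columns are standardised jointly across all tasks.
#' @param center,scale statistics to reuse (e.g. from a training set);
#'   computed from `X` when `NULL`.
#' @return matrix (or collection) with attributes `center` and `scale`.
#' @export
standardize_features <- function(X, center = NULL, scale = NULL) {
  if (inherits(X, "task_collection")) {
    pooled <- do.call(rbind, lapply(X$tasks, function(t) t$X))
    if (is.null(center)) center <- colMeans(pooled)
    if (is.null(scale)) {
      scale <- apply(pooled, 2, stats::sd)
      scale[scale == 0 | !is.finite(scale)] <- 1
    }
    X$tasks <- lapply(X$tasks, function(t) {
      t$X <- sweep(sweep(t$X, 2, center), 2, scale, "/")
      t
    })
    attr(X, "center") <- center
    attr(X, "scale") <- scale
    return(X)
  }
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  out <- sweep(sweep(X, 2, center), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Invert a feature standardisation
#'
#' @param Z matrix returned by [standardize_features()] (or any matrix plus
#'   explicit `center`/`scale`).
#' @param center,scale the transform to invert; taken from `Z`'s attributes
#'   by default.
#' @return the matrix on the original scale.
#' @export
unstandardize_features <- function(Z, center = attr(Z, "center"),
                                   scale = attr(Z, "scale")) {
  sweep(sweep(as.matrix(Z), 2, scale, "*"), 2, center, "+")
}
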