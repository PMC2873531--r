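#' Configuration for the evaluation protocols
#'
#' Collects the knobs shared by all nine test protocols: the train fraction,
#' the number of seeded repeats (each repeat re-splits every task; both arms
#' of a comparison always share the same split, which is what makes the
#' paired t-test applicable), the fixed ridge `lambda`, the multi-task
#' `gamma`, and the base seed (repeat r uses `seed + r - 1`).
#'
#' @param train_frac training fraction for single-fraction tests.
#' @param fracs training fractions for the fraction-sweep test (Test 3).
#' @param repeats number of repeated random splits averaged over.
#' @param lambda ridge regularisation for all single-task fits.
#' @param gamma,eps,tol,max_iter multi-task fit parameters, see [mtl_fit()].
#' @param center centre labels by the training mean in every fit.
#' @param seed base seed.
#' @param report_tasks optional task ids to report (Test 5).
#' @param subtasks number of sub-tasks for the within-task test (Test 9).
#' @return a list of class `protocol_config`.
#' @export
protocol_config <- function(train_frac = 0.5,
                            fracs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            repeats = 10L, lambda = 10, gamma = 1,
                            eps = 1e-6, tol = 1e-5, max_iter = 1000L,
                            center = TRUE, seed = 1L,
                            report_tasks = NULL, subtasks = 5L) {
  structure(
    list(train_frac = train_frac, fracs = fracs, repeats = repeats,
         lambda = lambda, gamma = gamma, eps = eps, tol = tol,
         max_iter = max_iter, center = center, seed = seed,
         report_tasks = report_tasks, subtasks = subtasks),
    class = "protocol_config"
  )
}

## Split every task of a collection with one RNG stream; both arms of a
## comparison reuse the result, so comparisons are paired by split.
.split_collection <- function(tc, frac, seed) {
  with_seed(seed, {
    parts <- lapply(tc$tasks, split_task, train_frac = frac)
    list(
      train = task_collection(lapply(parts, `[[`, "train"), tc$granularity),
      test = task_collection(lapply(parts, `[[`, "test"), tc$granularity)
    )
  })
}

## Per-task single-task ridge; returns per-task test RMSE.
.eval_stl <- function(train, test, lambda, center) {
  vapply(seq_along(train$tasks), function(t) {
    fit <- ridge_fit(train$tasks[[t]], lambda = lambda, center = center)
    rmse(test$tasks[[t]]$y, predict(fit, test$tasks[[t]]$X))
  }, numeric(1))
}

## Pool all tasks after min-max scaling each task's training labels to [0,1]
## (training range only -- no test leakage), fit one ridge, then rescale the
## predictions back per task and score on the native scale.
.eval_pooled <- function(train, test, lambda, center) {
  sc <- scale_task_labels(train)
  Xp <- do.call(rbind, lapply(sc$collection$tasks, function(t) t$X))
  yp <- unlist(lapply(sc$collection$tasks, function(t) t$y),
               use.names = FALSE)
  fit <- ridge_fit(Xp, yp, lambda = lambda, center = center)
  vapply(seq_along(test$tasks), function(t) {
    pred01 <- predict(fit, test$tasks[[t]]$X)
    pred <- unscale_labels(pred01, sc$transforms, test$tasks[[t]]$task_id)
    rmse(test$tasks[[t]]$y, pred)
  }, numeric(1))
}

.eval_mtl <- function(train, test, cfg) {
  fit <- mtl_fit(train, gamma = cfg$gamma, eps = cfg$eps, tol = cfg$tol,
                 max_iter = cfg$max_iter, center = cfg$center)
  vapply(seq_along(test$tasks), function(t) {
    rmse(test$tasks[[t]]$y, predict(fit, test$tasks[[t]]$X, t))
  }, numeric(1))
}

## Average an evaluation over cfg$repeats paired splits.
.repeat_eval <- function(tc, frac, cfg, evals) {
  acc <- lapply(evals, function(.) 0)
  for (r in seq_len(cfg$repeats)) {
    sp <- .split_collection(tc, frac, cfg$seed + r - 1L)
    for (nm in names(evals)) {
      acc[[nm]] <- acc[[nm]] + evals[[nm]](sp$train, sp$test)
    }
  }
  lapply(acc, function(v) v / cfg$repeats)
}

#' Run one of the nine evaluation protocols
#'
#' Reproduces the standard split/pool/rescale protocols on any task
#' collection, averaging per-task test RMSE over seeded repeated splits:
#'
#' * **Test 1 / Test 6** — per-task single-task ridge (experiment- /
#'   mRNA-level).
#' * **Test 2 / Test 7** — one pooled model on \[0, 1\]-scaled labels, scored
#'   per task after rescaling back to the native scale.
#' * **Test 3** — single-task vs multi-task across training fractions
#'   10/30/50/70/90%.
#' * **Test 4** — single-task vs multi-task on a (small) collection of
#'   independent experiments alone.
#' * **Test 5** — multi-task over an enlarged collection, reporting
#'   `cfg$report_tasks` (default: all tasks).
#' * **Test 8** — multi-task at the 50% split (mRNA-level analogue of
#'   Test 3's middle column).
#' * **Test 9** — one task randomly partitioned into sub-tasks; per-sub-task
#'   ridge vs the pooled-and-scaled model, probing within-task homogeneity.
#'
#' Tests 1-5 expect an experiment-level collection, Tests 6-8 an mRNA-level
#' one, and Test 9 a single [task_dataset()] (or 1-task collection).
#'
#' @param test_id integer 1 to 9.
#' @param data a [task_collection()] (Test 9: a [task_dataset()]).
#' @param cfg a [protocol_config()].
#' @return a data.frame of per-task mean RMSEs; its shape depends on the
#'   test (see Details).
#' @export
run_test <- function(test_id, data, cfg = protocol_config()) {
  test_id <- as.integer(test_id)
  if (!test_id %in% 1:9) stop("unknown test id: ", test_id)
  if (test_id %in% 1:5) {
    validate_tasks(data)
    if (data$granularity != "experiment") {
      stop("Test ", test_id, " expects an experiment-level collection")
    }
  } else if (test_id %in% 6:8) {
    validate_tasks(data)
    if (data$granularity != "mrna") {
      stop("Test ", test_id, " expects an mRNA-level collection")
    }
  }
  ids <- if (test_id %in% 1:8) names(data$tasks)

  if (test_id %in% c(1L, 6L)) {
    out <- .repeat_eval(data, cfg$train_frac, cfg, list(
      rmse = function(tr, te) .eval_stl(tr, te, cfg$lambda, cfg$center)))
    return(data.frame(task = ids, rmse = out$rmse, row.names = NULL))
  }
  if (test_id %in% c(2L, 7L)) {
    out <- .repeat_eval(data, cfg$train_frac, cfg, list(
      rmse = function(tr, te) .eval_pooled(tr, te, cfg$lambda, cfg$center)))
    return(data.frame(task = ids, rmse = out$rmse, row.names = NULL))
  }
  if (test_id == 3L) {
    res <- lapply(cfg$fracs, function(f) {
      out <- .repeat_eval(data, f, cfg, list(
        stl = function(tr, te) .eval_stl(tr, te, cfg$lambda, cfg$center),
        mtl = function(tr, te) .eval_mtl(tr, te, cfg)))
      data.frame(task = ids, frac = f, stl = out$stl, mtl = out$mtl,
                 row.names = NULL)
    })
    return(do.call(rbind, res))
  }
  if (test_id == 4L) {
    out <- .repeat_eval(data, cfg$train_frac, cfg, list(
      stl = function(tr, te) .eval_stl(tr, te, cfg$lambda, cfg$center),
      mtl = function(tr, te) .eval_mtl(tr, te, cfg)))
    return(data.frame(task = ids, stl = out$stl, mtl = out$mtl,
                      row.names = NULL))
  }
  if (test_id == 5L) {
    out <- .repeat_eval(data, cfg$train_frac, cfg, list(
      mtl = function(tr, te) .eval_mtl(tr, te, cfg)))
    res <- data.frame(task = ids, rmse = out$mtl, row.names = NULL)
    if (!is.null(cfg$report_tasks)) {
      res <- res[res$task %in% cfg$report_tasks, , drop = FALSE]
      rownames(res) <- NULL
    }
    return(res)
  }
  if (test_id == 8L) {
    out <- .repeat_eval(data, cfg$train_frac, cfg, list(
      mtl = function(tr, te) .eval_mtl(tr, te, cfg)))
    return(data.frame(task = ids, rmse = out$mtl, row.names = NULL))
  }
  ## Test 9: split one task into sub-tasks, then STL vs pooled-scaled STL
  task <- if (inherits(data, "task_collection")) {
    if (length(data$tasks) != 1L) {
      stop("Test 9 expects a single task (or a 1-task collection)")
    }
    data$tasks[[1]]
  } else if (inherits(data, "task_dataset")) data
  else stop("Test 9 expects a task_dataset")
  n <- nrow(task$X)
  k <- cfg$subtasks
  if (n < 2L * k) stop("task too small to split into ", k, " sub-tasks")
  parts <- with_seed(cfg$seed, split(sample.int(n), rep_len(seq_len(k), n)))
  sub <- task_collection(lapply(seq_len(k), function(j) {
    i <- parts[[j]]
    task_dataset(task$X[i, , drop = FALSE], task$y[i],
                 paste0(task$task_id, ".", j))
  }), "mrna")
  out <- .repeat_eval(sub, cfg$train_frac, cfg, list(
    stl = function(tr, te) .eval_stl(tr, te, cfg$lambda, cfg$center),
    pooled = function(tr, te) .eval_pooled(tr, te, cfg$lambda, cfg$center)))
  data.frame(subtask = names(sub$tasks), stl = out$stl, pooled = out$pooled,
             row.names = NULL)
}
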