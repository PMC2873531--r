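#' Specification for the synthetic multi-task generator
#'
#' Describes a family of related regression tasks with the structure the
#' cross-platform siRNA analysis assumes: a sparse weight support shared by
#' all tasks, task-specific perturbations of the shared coefficients
#' (platforms genuinely alter feature effects, so conditional distributions
#' are not identical), task-specific affine label maps emulating the diverse
#' native efficacy scales of different platforms, heteroscedastic Gaussian
#' noise, and small per-task sample sizes.
#'
#' @param tasks number of tasks T.
#' @param d feature dimension (default 19, the classical feature count).
#' @param support_size number of features with non-zero shared weight.
#' @param n_range inclusive range per-task sample sizes are drawn from
#'   (default 5-180, the span of real experiment sizes).
#' @param n_per_task optional explicit vector of task sizes (recycled),
#'   overriding `n_range`.
#' @param beta optional explicit shared d-vector (zero off support); drawn
#'   when `NULL`.
#' @param coef_range magnitudes of the shared support coefficients are drawn
#'   uniformly from this range, with random sign.
#' @param perturb_sd SD of the task-specific Gaussian perturbation added to
#'   the shared coefficients, restricted to the support (default 0.5, about
#'   half a typical coefficient).
#' @param scale_range,offset_range per-task affine label maps
#'   `y = scale * signal + offset + noise`, drawn uniformly from these
#'   ranges; the defaults put labels on a 0-130 percent-style scale.
#' @param noise_sd_range per-task noise SDs, drawn uniformly (native scale).
#' @return a list of class `sim_spec`.
#' @export
sim_spec <- function(tasks = 14L, d = 19L, support_size = 4L,
                     n_range = c(5L, 180L), n_per_task = NULL, beta = NULL,
                     coef_range = c(0.5, 1.5), perturb_sd = 0.5,
                     scale_range = c(10, 25), offset_range = c(40, 70),
                     noise_sd_range = c(5, 20)) {
  if (support_size > d) stop("support_size must be <= d")
  if (tasks < 1L || d < 1L) stop("tasks and d must be >= 1")
  if (any(n_range < 1L)) stop("sample sizes must be >= 1")
  if (any(scale_range <= 0)) stop("label scales must be > 0")
  if (any(noise_sd_range < 0)) stop("noise SDs must be >= 0")
  if (!is.null(beta) && length(beta) != d) stop("beta must have length d")
  structure(
    list(tasks = as.integer(tasks), d = as.integer(d),
         support_size = as.integer(support_size),
         n_range = as.integer(n_range), n_per_task = n_per_task,
         beta = beta, coef_range = coef_range, perturb_sd = perturb_sd,
         scale_range = scale_range, offset_range = offset_range,
         noise_sd_range = noise_sd_range),
    class = "sim_spec"
  )
}

.draw_shared_beta <- function(spec) {
  support <- sort(sample.int(spec$d, spec$support_size))
  beta <- numeric(spec$d)
  if (!is.null(spec$beta)) {
    beta <- spec$beta
    support <- which(beta != 0)
  } else {
    beta[support] <- sample(c(-1, 1), spec$support_size, replace = TRUE) *
      stats::runif(spec$support_size, spec$coef_range[1], spec$coef_range[2])
  }
  list(beta = beta, support = support)
}

.draw_task_sizes <- function(spec) {
  if (!is.null(spec$n_per_task)) {
    return(rep_len(as.integer(spec$n_per_task), spec$tasks))
  }
  sample(seq(spec$n_range[1], spec$n_range[2]), spec$tasks, replace = TRUE)
}

.make_task <- function(id, n, d, w, sc, off, noise_sd) {
  X <- matrix(stats::rnorm(n * d), n, d)
  y <- sc * drop(X %*% w) + off + stats::rnorm(n, 0, noise_sd)
  task_dataset(X, y, id)
}

#' Generate a synthetic multi-task collection with planted structure
#'
#' Draws T tasks sharing a sparse coefficient support: task t has weights
#' `w_t = beta + perturbation` (perturbation restricted to the support),
#' standard-normal covariates, and labels
#' `y = scale_t * (X w_t) + offset_t + noise_t`. The ground truth (support,
#' per-task weights, affine maps, noise SDs) is returned alongside the data.
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed; the same seed reproduces the collection
#'   exactly, and the caller's RNG state is preserved.
#' @return list with `tasks` (a [task_collection()], experiment granularity)
#'   and `truth` (list: `support`, `beta`, `W` d x T, `scale`, `offset`,
#'   `noise_sd`).
#' @export
simulate_tasks <- function(spec = sim_spec(), seed = NULL) {
  with_seed(seed, {
    sh <- .draw_shared_beta(spec)
    ns <- .draw_task_sizes(spec)
    sc <- stats::runif(spec$tasks, spec$scale_range[1], spec$scale_range[2])
    off <- stats::runif(spec$tasks, spec$offset_range[1], spec$offset_range[2])
    nsd <- stats::runif(spec$tasks, spec$noise_sd_range[1],
                        spec$noise_sd_range[2])
    W <- matrix(0, spec$d, spec$tasks)
    tasks <- vector("list", spec$tasks)
    for (t in seq_len(spec$tasks)) {
      w <- sh$beta
      w[sh$support] <- w[sh$support] +
        stats::rnorm(spec$support_size, 0, spec$perturb_sd)
      W[, t] <- w
      tasks[[t]] <- .make_task(sprintf("S%d", t), ns[t], spec$d, w,
                               sc[t], off[t], nsd[t])
    }
    list(
      tasks = task_collection(tasks, "experiment"),
      truth = list(support = sh$support, beta = sh$beta, W = W,
                   scale = sc, offset = off, noise_sd = nsd)
    )
  })
}

#' Generate clustered tasks emulating mRNA-level homogeneity
#'
#' Tasks are grouped into clusters; within a cluster all tasks share the
#' identical weight vector, affine label map and noise level (siRNAs bound to
#' one mRNA behave homogeneously), while across clusters weights and maps
#' differ as in [simulate_tasks()]. With `clusters = 1` every task is an
#' exchangeable piece of one population (the within-task homogeneity
#' setting); with `clusters = tasks` the generator reduces to
#' [simulate_tasks()].
#'
#' @param spec a [sim_spec()].
#' @param clusters number of clusters (>= 1); tasks are assigned round-robin.
#' @param seed integer seed.
#' @return as [simulate_tasks()], with `truth$cluster` giving each task's
#'   cluster index; granularity is `"mrna"`.
#' @export
simulate_mrna_clusters <- function(spec = sim_spec(), clusters = 1L,
                                   seed = NULL) {
  clusters <- as.integer(clusters)
  if (clusters < 1L) stop("clusters must be >= 1")
  with_seed(seed, {
    sh <- .draw_shared_beta(spec)
    ns <- .draw_task_sizes(spec)
    cl <- rep_len(seq_len(clusters), spec$tasks)
    sc_c <- stats::runif(clusters, spec$scale_range[1], spec$scale_range[2])
    off_c <- stats::runif(clusters, spec$offset_range[1],
                          spec$offset_range[2])
    nsd_c <- stats::runif(clusters, spec$noise_sd_range[1],
                          spec$noise_sd_range[2])
    W_c <- matrix(0, spec$d, clusters)
    for (c in seq_len(clusters)) {
      w <- sh$beta
      w[sh$support] <- w[sh$support] +
        stats::rnorm(spec$support_size, 0, spec$perturb_sd)
      W_c[, c] <- w
    }
    tasks <- vector("list", spec$tasks)
    for (t in seq_len(spec$tasks)) {
      tasks[[t]] <- .make_task(sprintf("M%d", t), ns[t], spec$d,
                               W_c[, cl[t]], sc_c[cl[t]], off_c[cl[t]],
                               nsd_c[cl[t]])
    }
    list(
      tasks = task_collection(tasks, "mrna"),
      truth = list(support = sh$support, beta = sh$beta,
                   W = W_c[, cl, drop = FALSE], cluster = cl,
                   scale = sc_c[cl], offset = off_c[cl],
                   noise_sd = nsd_c[cl])
    )
  })
}

#' Support-recovery F1 score of a multi-task fit
#'
#' Compares the top-k features of a fit's shared feature weights against a
#' planted support of size k (so precision = recall = F1 here).
#'
#' @param fit a `sirna_mtl` fit (or any vector of feature weights).
#' @param support integer indices of the true support.
#' @return F1 score in \[0, 1\].
#' @export
support_f1 <- function(fit, support) {
  w <- if (inherits(fit, "sirna_mtl")) fit$D_diag else fit
  k <- length(support)
  top <- order(w, decreasing = TRUE)[seq_len(k)]
  tp <- length(intersect(top, support))
  2 * tp / (k + k)
}
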