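test_that("the feature-weight update is the normalised row-norm formula", {
  # single nonzero row takes all the weight
  W <- matrix(0, 4, 3)
  W[2, ] <- c(1, -2, 2)
  expect_equal(update_D(W), c(0, 1, 0, 0))

  # hand-computed row norms (5, 0, 1) -> (5/6, 0, 1/6)
  W <- rbind(c(3, 4), c(0, 0), c(1, 0))
  expect_equal(update_D(W), c(5 / 6, 0, 1 / 6))

  # zero weight exactly when a feature is unused by every task
  expect_true(update_D(W)[2] == 0)

  # permutation equivariance
  set.seed(3)
  W <- matrix(rnorm(15), 5, 3)
  perm <- sample(5)
  expect_equal(update_D(W[perm, ]), update_D(W)[perm])

  expect_equal(sum(update_D(W)), 1)
  expect_error(update_D(matrix(0, 3, 2)), "all-zero")
  expect_error(update_D(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("identical tasks receive identical weight vectors", {
  base <- random_task(12, 5, "a", seed = 8)
  tc <- task_collection(lapply(1:4, function(t) {
    task_dataset(base$X, base$y, paste0("t", t))
  }), "experiment")
  fit <- mtl_fit(tc, gamma = 1)
  for (t in 2:4) {
    expect_equal(fit$W[, t], fit$W[, 1], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the objective trace is non-increasing on every run", {
  for (s in 1:5) {
    sim <- simulate_tasks(sim_spec(tasks = 6, d = 10, support_size = 3,
                                   n_range = c(8, 25)), seed = 100 + s)
    fit <- mtl_fit(sim$tasks)
    expect_true(fit$converged)
    expect_true(all(diff(fit$objective) <=
                      1e-8 * pmax(abs(fit$objective[-length(fit$objective)]), 1)))
    expect_equal(sum(fit$D_diag), 1, tolerance = 1e-12)
    expect_true(all(fit$D_diag >= 0))
  }
})

test_that("a single-task fit degenerates to a reweighted ridge", {
  task <- random_task(30, 5, "only", seed = 4)
  tc <- task_collection(list(task), "experiment")
  fit <- mtl_fit(tc, gamma = 1, center = FALSE, scale = FALSE)
  expect_true(all(diff(fit$objective) <= 1e-8 * abs(fit$objective[-length(fit$objective)])))
  # the converged fixed point solves a ridge system under its own D
  lam_eff <- fit$gamma / (update_D(fit$W) + fit$eps)
  w_ridge <- solve(crossprod(task$X) + diag(as.numeric(lam_eff)),
                   crossprod(task$X, task$y))
  expect_equal(unname(fit$W[, 1]), as.numeric(w_ridge), tolerance = 1e-3)
})

test_that("gamma interpolates between independent fits and total shrinkage", {
  tc <- random_collection(T = 3, n = 40, d = 5, seed = 6)
  tiny <- mtl_fit(tc, gamma = 1e-8, center = FALSE, scale = FALSE)
  # as gamma -> 0, each column approaches the task's least-squares solution
  for (t in 1:3) {
    ols <- solve(crossprod(tc$tasks[[t]]$X),
                 crossprod(tc$tasks[[t]]$X, tc$tasks[[t]]$y))
    expect_equal(unname(tiny$W[, t]), as.numeric(ols), tolerance = 1e-3)
  }
  huge <- mtl_fit(tc, gamma = 1e8, center = FALSE, scale = FALSE)
  expect_lt(norm(huge$W, "F"), 1e-3 * norm(tiny$W, "F"))
})

test_that("alternating minimisation matches a direct joint optimisation", {
  # 2 tasks, 3 features, 5 samples; oracle: BFGS on the D-minimised objective
  set.seed(11)
  tc <- random_collection(T = 2, n = 5, d = 3, seed = 11)
  gamma <- 1
  eps <- 1e-6
  fit <- mtl_fit(tc, gamma = gamma, eps = eps, tol = 1e-10,
                 max_iter = 5000, center = FALSE, scale = FALSE)
  joint_obj <- function(wvec) {
    W <- matrix(wvec, 3, 2)
    loss <- sum(vapply(1:2, function(t) {
      sum((drop(tc$tasks[[t]]$X %*% W[, t]) - tc$tasks[[t]]$y)^2)
    }, numeric(1)))
    loss + gamma * sum(sqrt(rowSums(W^2) + eps))^2
  }
  direct <- stats::optim(rep(0, 6), joint_obj, method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-14))
  alt_obj <- utils::tail(fit$objective, 1)
  expect_equal(alt_obj, direct$value, tolerance = 1e-3)
  expect_lte(alt_obj, direct$value * (1 + 1e-3))
})

test_that("planted shared support dominates the learned feature weights", {
  fits <- lapply(1:10, function(s) {
    sim <- simulate_tasks(sim_spec(n_range = c(20, 60)), seed = 200 + s)
    sp <- lapply(sim$tasks$tasks, split_task, train_frac = 0.5, seed = s)
    train <- task_collection(lapply(sp, `[[`, "train"), "experiment")
    list(fit = mtl_fit(train), support = sim$truth$support)
  })
  ranking <- rank_features(lapply(fits, `[[`, "fit"))
  expect_equal(dim(ranking), c(19, 3))
  # averaged weights are still a distribution
  expect_equal(sum(ranking$weight), 1, tolerance = 1e-8)
  # each fit's top weights should recover its planted support
  per_fit_f1 <- vapply(fits, function(f) support_f1(f$fit, f$support),
                       numeric(1))
  expect_gte(mean(per_fit_f1), 0.75)
})

test_that("feature ranking is stable, named and validates its inputs", {
  sim <- simulate_tasks(sim_spec(tasks = 4, n_range = c(20, 30)), seed = 31)
  fit <- mtl_fit(sim$tasks)
  r1 <- rank_features(fit)
  expect_identical(sort(r1$feature), sort(feature_names()))
  expect_true(all(diff(r1$weight) <= 0))

  # all-equal weights: stable sort keeps input order
  tied <- fit
  tied$D_diag[] <- 1 / 19
  r2 <- rank_features(tied, names = paste0("f", 1:19))
  expect_identical(r2$feature, paste0("f", 1:19))

  other <- mtl_fit(simulate_tasks(sim_spec(tasks = 3, d = 6,
                                           support_size = 2,
                                           n_range = c(10, 20)),
                                  seed = 5)$tasks)
  expect_error(rank_features(list(fit, other)), "inconsistent")
})

test_that("multi-task model methods are coherent", {
  sim <- simulate_tasks(sim_spec(tasks = 3, d = 6, support_size = 2,
                                 n_range = c(12, 20)), seed = 77)
  fit <- mtl_fit(sim$tasks)
  expect_equal(dim(coef(fit)), c(6, 3))
  p_by_id <- predict(fit, sim$tasks$tasks[[2]]$X, names(sim$tasks$tasks)[2])
  p_by_ix <- predict(fit, sim$tasks$tasks[[2]]$X, 2)
  expect_identical(p_by_id, p_by_ix)
  expect_error(predict(fit, sim$tasks$tasks[[1]]$X, "nope"), "unknown task")

  res <- residuals(fit)
  fv <- fitted(fit)
  expect_equal(fv[[1]] + res[[1]], sim$tasks$tasks[[1]]$y)

  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_length(sims[[1]], 3)
  expect_length(sims[[1]][[2]], length(sim$tasks$tasks[[2]]$y))
  # same seed, same draws; RNG stream untouched
  expect_identical(simulate(fit, nsim = 1, seed = 9),
                   simulate(fit, nsim = 1, seed = 9))
})
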