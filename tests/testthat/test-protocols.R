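cfg_fast <- protocol_config(repeats = 2L, seed = 42L)

test_that("protocol outputs have the documented shapes", {
  sim <- simulate_tasks(sim_spec(tasks = 4, n_range = c(10, 20)), seed = 1)
  tc <- sim$tasks

  t1 <- run_test(1, tc, cfg_fast)
  expect_named(t1, c("task", "rmse"))
  expect_equal(nrow(t1), 4)
  expect_true(all(t1$rmse > 0))

  t2 <- run_test(2, tc, cfg_fast)
  expect_equal(nrow(t2), 4)

  cfg3 <- protocol_config(repeats = 2L, seed = 42L, fracs = c(0.3, 0.5))
  t3 <- run_test(3, tc, cfg3)
  expect_named(t3, c("task", "frac", "stl", "mtl"))
  expect_equal(nrow(t3), 4 * 2)

  t4 <- run_test(4, tc, cfg_fast)
  expect_named(t4, c("task", "stl", "mtl"))

  cfg5 <- protocol_config(repeats = 2L, seed = 42L,
                          report_tasks = c("S1", "S3"))
  t5 <- run_test(5, tc, cfg5)
  expect_equal(t5$task, c("S1", "S3"))

  expect_error(run_test(10, tc, cfg_fast), "unknown test id")
  expect_error(run_test(6, tc, cfg_fast), "mRNA-level")
  mr <- simulate_mrna_clusters(sim_spec(tasks = 3, n_range = c(12, 16)),
                               clusters = 3, seed = 2)
  expect_error(run_test(1, mr$tasks, cfg_fast), "experiment-level")
  t6 <- run_test(6, mr$tasks, cfg_fast)
  expect_equal(nrow(t6), 3)
  t8 <- run_test(8, mr$tasks, cfg_fast)
  expect_equal(nrow(t8), 3)
})

test_that("every protocol is reproducible from (config, seed)", {
  sim <- simulate_tasks(sim_spec(tasks = 3, n_range = c(10, 14)), seed = 5)
  for (id in c(1, 2)) {
    a <- run_test(id, sim$tasks, cfg_fast)
    b <- run_test(id, sim$tasks, cfg_fast)
    expect_identical(a, b)
  }
  c1 <- run_test(1, sim$tasks, protocol_config(repeats = 2L, seed = 1L))
  c2 <- run_test(1, sim$tasks, protocol_config(repeats = 2L, seed = 2L))
  expect_false(identical(c1$rmse, c2$rmse))
})

test_that("pooled-and-scaled evaluation fits its transform on training data only", {
  # scale_task_labels on a training split must reflect the training range,
  # not the full task range
  task <- task_dataset(matrix(rnorm(40), 20, 2), c(seq(0, 90, length = 19), 500),
                       "wide")
  sp <- split_task(task, 0.5, seed = 3)
  sc <- scale_task_labels(task_collection(list(sp$train), "experiment"))
  expect_equal(sc$transforms$lo, min(sp$train$y))
  expect_equal(sc$transforms$hi, max(sp$train$y))
  # the extreme test label plays no role unless it was sampled into training
  if (!500 %in% sp$train$y) expect_lt(sc$transforms$hi, 500)
})

test_that("the within-task protocol partitions one task into sub-tasks", {
  sim <- simulate_mrna_clusters(sim_spec(tasks = 1, n_per_task = 60),
                                clusters = 1, seed = 7)
  task <- sim$tasks$tasks[[1]]
  t9 <- run_test(9, task, protocol_config(repeats = 2L, seed = 9L,
                                          subtasks = 5L))
  expect_named(t9, c("subtask", "stl", "pooled"))
  expect_equal(nrow(t9), 5)
  expect_identical(t9, run_test(9, task, protocol_config(repeats = 2L,
                                                         seed = 9L,
                                                         subtasks = 5L)))
  expect_error(run_test(9, random_collection(T = 2), cfg_fast),
               "single task")
  expect_error(run_test(9, split_task(task, 0.1, seed = 1)$train,
                        protocol_config(subtasks = 5L)), "too small")
})

test_that("mRNA grouping keeps only transcripts with enough siRNAs", {
  set.seed(33)
  sizes <- c(M1 = 8, M2 = 3, M3 = 6, M4 = 5)
  recs <- data.frame(
    sequence = replicate(sum(sizes), paste(sample(c("A", "C", "G", "U"), 19,
                                                  TRUE), collapse = "")),
    efficacy = runif(sum(sizes), 0, 100),
    experiment = "E1",
    mrna = rep(names(sizes), sizes),
    stringsAsFactors = FALSE
  )
  X <- matrix(rnorm(sum(sizes) * 4), ncol = 4)
  tc <- build_mrna_tasks(recs, X, min_sirnas = 5L)
  # brute-force oracle: groups strictly larger than the cutoff
  expect_setequal(names(tc$tasks), names(sizes)[sizes > 5])
  expect_equal(vapply(tc$tasks, function(t) length(t$y), numeric(1)),
               c(M1 = 8, M3 = 6))

  expect_warning(
    expect_error(build_mrna_tasks(recs, X, min_sirnas = 10L), "empty"),
    "no mRNA")
})

test_that("adding related tasks helps the held-out independent tasks", {
  # two small 'independent' tasks benefit from joint fitting with a larger
  # related collection (sign test over seeded replicates)
  better <- 0L
  reps <- 6L
  for (r in seq_len(reps)) {
    spec <- sim_spec(tasks = 10, n_range = c(12, 25), perturb_sd = 0.3)
    sim <- simulate_tasks(spec, seed = 700 + r)
    ids <- names(sim$tasks$tasks)
    indep <- ids[9:10]
    small <- task_collection(sim$tasks$tasks[indep], "experiment")
    cfg4 <- protocol_config(repeats = 3L, seed = 50L + r)
    t4 <- run_test(4, small, cfg4)
    cfg5 <- protocol_config(repeats = 3L, seed = 50L + r,
                            report_tasks = indep)
    t5 <- run_test(5, sim$tasks, cfg5)
    if (mean(t5$rmse) < mean(t4$mtl)) better <- better + 1L
  }
  expect_gte(better, ceiling(reps / 2))
})
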