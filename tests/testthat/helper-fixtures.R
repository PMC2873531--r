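# Small in-code fixtures shared across test files.

random_task <- function(n, d, id = "t", seed = NULL, w = NULL, noise = 1) {
  with_seed <- function(s, expr) {
    if (!is.null(s)) set.seed(s)
    expr
  }
  with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    if (is.null(w)) w <- rnorm(d)
    task_dataset(X, drop(X %*% w) + rnorm(n, 0, noise), id)
  })
}

random_collection <- function(T = 3, n = 10, d = 5, seed = 1,
                              granularity = "experiment") {
  set.seed(seed)
  task_collection(
    lapply(seq_len(T), function(t) random_task(n, d, paste0("t", t))),
    granularity
  )
}

# A deterministic valid 19-nt sense sequence.
SEQ19 <- "GCAAUGCCUAAUGGCAUAA"

example_records <- function() {
  data.frame(
    sequence = c("GCAAUGCCUAAUGGCAUAA",
                 "AUGGCUACGUAGCUAGCUA",
                 "GGGAUAUAUAUAUAUAUAU",
                 "CCGUAGCUAGCAUCGAUCG"),
    efficacy = c(85.2, 40.1, 63.3, 12.8),
    experiment = c("E1", "E1", "E2", "E2"),
    mrna = c("M1", "M2", "M1", "M3"),
    stringsAsFactors = FALSE
  )
}
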