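thermo <- thermo_table()

test_that("nucleotide content is a direct positional count", {
  expect_equal(nucleotide_content(strrep("U", 19), "U"), 1)
  expect_equal(nucleotide_content("GGGAUAUAUAUAUAUAUAU", "G"), 3 / 19)
  expect_equal(nucleotide_content("GGGAUAUAUAUAUAUAUAU", "C"), 0)
  # DNA spelling accepted
  expect_equal(nucleotide_content("GGGATATATATATATATAT", "U"), 8 / 19)
  expect_error(nucleotide_content("GGGAXAUAUAUAUAUAUAU", "G"), "non-ACGU")
})

test_that("the stacking table covers all steps and obeys duplex symmetry", {
  steps <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                           paste0))
  expect_setequal(names(thermo), steps)
  expect_true(all(is.finite(thermo)))
  for (s in steps) {
    expect_equal(thermo[[s]], thermo[[reverse_complement_rna(s)]],
                 info = paste("step", s))
  }
})

test_that("duplex free energy equals the brute-force sum over the 18 steps", {
  set.seed(71)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "U"), 19, replace = TRUE),
                 collapse = "")
    # independent oracle: explicit loop over positions
    acc <- attr(thermo, "initiation")
    for (p in 1:18) acc <- acc + thermo[[substr(seq, p, p + 1)]]
    expect_equal(duplex_delta_g(seq, thermo), acc)
  }
  expect_error(duplex_delta_g("AUGC"), "19 nt")
})

test_that("terminal stacking difference is the step-1 minus step-18 lookup", {
  expect_equal(delta_g_diff_1_18(strrep("A", 19)), 0)   # identical end steps
  seq <- "GCAAUAUAUAUAUAUAUGC"                          # step1 GC, step18 GC
  expect_equal(delta_g_diff_1_18(seq), 0)
  seq2 <- "GGAUAUAUAUAUAUAUAAU"
  expect_equal(delta_g_diff_1_18(seq2),
               thermo[["GG"]] - thermo[["AU"]])
  expect_equal(stability_profile(seq2, 1), thermo[["GG"]])
  expect_equal(stability_profile(seq2, 18), thermo[["AU"]])
  expect_error(stability_profile(seq2, 19), "1..18")
})

test_that("consensus scores count preferred and avoided position matches", {
  cons <- data.frame(position = c(2L, 5L, 9L),
                     preferred = c("A", "G,C", ""),
                     avoided = c("", "U", "G"))
  hit_all <- "CAGGGAUACAUAUAUAUAU"   # pos2 A, pos5 G, pos9 C(no rule hit)
  sc <- position_consensus_scores(hit_all, cons)
  expect_equal(sc[["preferred"]], 2)
  expect_equal(sc[["avoided"]], 0)
  expect_equal(sc[["sum"]], 2)

  none <- "CCCCACAACAAAAAAAAAA"      # pos2 C, pos5 A, pos9 C: no rule matches
  expect_equal(unname(position_consensus_scores(none, cons)), c(0, 0, 0))

  # brute-force scan oracle against the shipped definition
  shipped <- consensus_table()
  set.seed(5)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "U"), 19, replace = TRUE),
                 collapse = "")
    nt <- strsplit(seq, "")[[1]]
    pref <- avoid <- 0
    for (r in seq_len(nrow(shipped))) {
      p <- strsplit(shipped$preferred[r], ",")[[1]]
      a <- strsplit(shipped$avoided[r], ",")[[1]]
      if (nt[shipped$position[r]] %in% p) pref <- pref + 1
      if (nt[shipped$position[r]] %in% a) avoid <- avoid + 1
    }
    got <- position_consensus_scores(seq, shipped)
    expect_equal(unname(got), c(pref - avoid, pref, avoid))
  }
})

test_that("feature vectors are complete, named, deterministic and finite", {
  set.seed(9)
  seqs <- replicate(20, paste(sample(c("A", "C", "G", "U"), 19, TRUE),
                              collapse = ""))
  for (seq in seqs) {
    fv <- sirna_features(seq, warn_sentinel = FALSE)
    expect_length(fv, 19)
    expect_identical(names(fv), feature_names())
    expect_true(all(is.finite(fv)))
  }
  f1 <- sirna_features(seqs[1], warn_sentinel = FALSE)
  expect_identical(f1, sirna_features(seqs[1], warn_sentinel = FALSE))
})

test_that("target-dependent features use the mRNA or the 0-sentinel policy", {
  mrna <- paste0("GGGAAA", SEQ19, "CCCUUU", SEQ19, "AA")
  fv <- sirna_features(SEQ19, mrna)
  expect_equal(fv[["target_site_count"]], 2)
  expect_lt(fv[["local_target_dg"]], 0)
  expect_equal(target_site_count(SEQ19, mrna), 2)

  expect_warning(fv0 <- sirna_features(SEQ19), "set to 0")
  expect_equal(fv0[["local_target_dg"]], 0)
  expect_equal(fv0[["target_site_count"]], 0)

  expect_error(local_target_dg(SEQ19, strrep("A", 50)), "not found")
})

test_that("feature matrices have one ordered 19-column row per record", {
  recs <- example_records()
  expect_warning(X <- feature_matrix(recs), "without an mRNA")
  expect_equal(dim(X), c(4, 19))
  expect_identical(colnames(X), feature_names())
  # order independence: permuting records permutes rows identically
  perm <- c(3, 1, 4, 2)
  expect_warning(Xp <- feature_matrix(recs[perm, ]), "without an mRNA")
  expect_equal(Xp, X[perm, ], ignore_attr = TRUE)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(X, path)
  expect_equal(read_feature_table(path), X, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("self-structure scores are zero-baselined and non-positive", {
  set.seed(13)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "U"), 19, TRUE), collapse = "")
    expect_lte(antisense_dimer_dg(seq, thermo), 0)
    expect_lte(antisense_hairpin_dg(seq, thermo), 0)
  }
  # a hairpin-free homopolymer scores the 0 baseline
  expect_equal(antisense_hairpin_dg(strrep("A", 19), thermo), 0)
})
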