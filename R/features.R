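#' The 19 classical siRNA design features
#'
#' Best-effort implementations of the 19 sequence and thermodynamic features
#' commonly used for siRNA efficacy regression: position-dependent nucleotide
#' consensus scores, duplex and positional stacking free energies, single- and
#' di-nucleotide content indices, antisense self-structure terms, and two
#' target-mRNA-dependent features (local target stability and the number of
#' potential target sites). The thermodynamic and consensus parameter sets are
#' shipped as editable plain-text files under `inst/extdata` and can be
#' overridden; downstream model fitting never depends on the exact parameter
#' values, only on a fixed, deterministic feature map.
#'
#' @name sirna-features
NULL

.feature_names <- c(
  "consensus_sum",                 # 1  preferred minus avoided position hits
  "dg_diff_pos1_pos18",            # 2  stacking dG step 1 minus step 18
  "duplex_dg",                     # 3  sense-antisense duplex dG
  "consensus_preferred",           # 4  preferred position hits
  "preferred_dinucleotide_index",  # 5  fraction of preferred dinucleotides
  "local_target_dg",               # 6  local target mRNA stability (needs mRNA)
  "consensus_avoided",             # 7  avoided position hits
  "content_U",                     # 8  U fraction
  "antisense_dimer_dg",            # 9  antisense-antisense dimer stability
  "stability_pos1",                # 10 duplex step dG at position 1
  "antisense_hairpin_dg",          # 11 antisense intramolecular structure dG
  "avoided_dinucleotide_index",    # 12 fraction of avoided dinucleotides
  "stability_pos13",               # 13 duplex step dG at position 13
  "stability_pos18",               # 14 duplex step dG at position 18
  "content_G",                     # 15 G fraction
  "stability_pos2",                # 16 duplex step dG at position 2
  "stability_pos6",                # 17 duplex step dG at position 6
  "stability_pos14",               # 18 duplex step dG at position 14
  "target_site_count"              # 19 potential target sites (needs mRNA)
)

#' Names of the 19 features, in canonical order
#' @return character vector of length 19.
#' @export
feature_names <- function() .feature_names

.check_seq <- function(seq) {
  seq <- normalize_rna(seq)
  if (length(seq) != 1L || is.na(seq)) stop("expected a single sequence")
  if (nchar(seq) != SIRNA_LEN) {
    stop("sequence must be 19 nt, got ", nchar(seq))
  }
  if (grepl("[^ACGU]", seq)) stop("sequence contains non-ACGU/T characters")
  seq
}

.extdata <- function(file) {
  system.file("extdata", file, package = "mtsirna", mustWork = TRUE)
}

#' Nearest-neighbor stacking free-energy table
#'
#' Loads an RNA/RNA dinucleotide stacking table (kcal/mol). The default is a
#' Freier-style Watson-Crick parameter set shipped with the package. The table
#' must contain all 16 dinucleotide steps; a step named `init` supplies the
#' duplex initiation term.
#'
#' @param path optional path to a two-column `step`/`dg` tab-delimited file.
#' @return named numeric vector over the 16 steps with attribute
#'   `"initiation"`.
#' @export
thermo_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("thermo_nn_rna.tsv")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  dg <- stats::setNames(tab$dg, tab$step)
  steps <- as.vector(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))
  missing <- setdiff(steps, names(dg))
  if (length(missing)) {
    stop("thermo table is missing steps: ", paste(missing, collapse = ", "))
  }
  out <- dg[steps]
  attr(out, "initiation") <- if ("init" %in% names(dg)) unname(dg[["init"]]) else 0
  out
}

#' Position-dependent consensus definition
#'
#' @param path optional path to a `position`/`preferred`/`avoided`
#'   tab-delimited file; fields hold comma-separated nucleotides.
#' @return data.frame with columns `position`, `preferred`, `avoided`.
#' @export
consensus_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("consensus_positions.tsv")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           fill = TRUE)
  for (col in c("preferred", "avoided")) {
    if (is.null(tab[[col]])) tab[[col]] <- ""
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  tab
}

.dinucleotide_sets <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("dinucleotide_sets.tsv")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  lapply(stats::setNames(tab$dinucleotides, tab$set),
         function(s) strsplit(s, ",", fixed = TRUE)[[1]])
}

.steps_of <- function(seq) {
  substring(seq, 1:(SIRNA_LEN - 1L), 2:SIRNA_LEN)
}

#' Fraction of a given nucleotide in a 19-nt sequence
#'
#' @param seq 19-nt sense sequence (T accepted, normalised to U).
#' @param base one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return count of `base` divided by 19.
#' @export
nucleotide_content <- function(seq, base = c("A", "C", "G", "U")) {
  seq <- .check_seq(seq)
  base <- match.arg(base)
  sum(strsplit(seq, "")[[1]] == base) / SIRNA_LEN
}

#' Free energy of the sense-antisense siRNA duplex
#'
#' Sum of nearest-neighbor stacking terms over the 18 dinucleotide steps of
#' the 19-nt duplex plus the initiation term.
#'
#' @param seq 19-nt sense sequence.
#' @param thermo stacking table from [thermo_table()].
#' @return duplex delta-G in kcal/mol (more negative = more stable).
#' @export
duplex_delta_g <- function(seq, thermo = thermo_table()) {
  seq <- .check_seq(seq)
  steps <- .steps_of(seq)
  sum(thermo[steps]) + attr(thermo, "initiation")
}

#' Stacking free-energy difference between duplex positions 1 and 18
#'
#' The difference between the stacking term of the first and the last of the
#' 18 duplex steps, a measure of the thermodynamic end asymmetry that governs
#' guide-strand selection.
#'
#' @inheritParams duplex_delta_g
#' @return `dG(step 1) - dG(step 18)` in kcal/mol.
#' @export
delta_g_diff_1_18 <- function(seq, thermo = thermo_table()) {
  seq <- .check_seq(seq)
  steps <- .steps_of(seq)
  unname(thermo[steps[1L]] - thermo[steps[18L]])
}

#' Stacking free energy of the duplex step at one position
#'
#' @inheritParams duplex_delta_g
#' @param pos step position, 1-based over the 18 duplex steps.
#' @return stacking delta-G of that step, kcal/mol.
#' @export
stability_profile <- function(seq, pos, thermo = thermo_table()) {
  seq <- .check_seq(seq)
  if (pos < 1L || pos > SIRNA_LEN - 1L) stop("pos must be in 1..18")
  unname(thermo[.steps_of(seq)[pos]])
}

#' Position-dependent nucleotide consensus scores
#'
#' Scans the sense strand against a per-position preferred/avoided nucleotide
#' definition. `preferred` counts positions whose nucleotide is in the
#' position's preferred set, `avoided` likewise for the avoided set, and
#' `sum = preferred - avoided`.
#'
#' @param seq 19-nt sense sequence.
#' @param consensus definition from [consensus_table()].
#' @return named numeric vector `c(sum, preferred, avoided)`.
#' @export
position_consensus_scores <- function(seq, consensus = consensus_table()) {
  seq <- .check_seq(seq)
  nt <- strsplit(seq, "")[[1]]
  hit <- function(col) {
    sum(vapply(seq_len(nrow(consensus)), function(i) {
      set <- strsplit(consensus[[col]][i], ",", fixed = TRUE)[[1]]
      length(set) > 0 && nt[consensus$position[i]] %in% set
    }, logical(1)))
  }
  pref <- hit("preferred")
  avoid <- hit("avoided")
  c(sum = pref - avoid, preferred = pref, avoided = avoid)
}

.rna_complement <- function(nt) {
  chartr("ACGU", "UGCA", nt)
}

#' Reverse complement in the RNA alphabet
#' @param seq sequence (T normalised to U).
#' @return reverse complement string.
#' @export
reverse_complement_rna <- function(seq) {
  seq <- normalize_rna(seq)
  paste(rev(strsplit(.rna_complement(seq), "")[[1]]), collapse = "")
}

## Fraction of the 18 dinucleotide steps that fall in `set`.
.dinucleotide_index <- function(seq, set) {
  steps <- .steps_of(seq)
  sum(steps %in% set) / length(steps)
}

## Best (most negative) ungapped antiparallel hybridisation of `a` with a
## second copy of itself: at every offset, runs of >= 2 consecutive
## Watson-Crick pairs contribute their stacking terms. 0 when nothing pairs.
.self_dimer_dg <- function(a, thermo) {
  n <- nchar(a)
  x <- strsplit(a, "")[[1]]
  rc <- rev(.rna_complement(x))         # pairing partner read 3'->5'
  best <- 0
  for (off in (-(n - 1L)):(n - 1L)) {
    i <- seq_len(n)
    j <- i + off
    keep <- j >= 1L & j <= n
    pair <- logical(n)
    pair[keep] <- x[keep] == rc[j[keep]]
    dg <- 0
    for (p in seq_len(n - 1L)) {
      if (pair[p] && pair[p + 1L]) dg <- dg + thermo[[paste0(x[p], x[p + 1L])]]
    }
    if (dg < best) best <- dg
  }
  best
}

## Most stable simple hairpin stem within one strand: complementary stretches
## (i..) vs (..j) with a loop of at least `min_loop` unpaired bases; stems of
## >= 2 pairs score the sum of their stacking terms. Hairpin-free sequences
## score 0 (the baseline).
.hairpin_dg <- function(a, thermo, min_loop = 3L) {
  n <- nchar(a)
  x <- strsplit(a, "")[[1]]
  comp <- .rna_complement(x)
  best <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + min_loop + 1L, length.out = max(0L, n - i - min_loop))) {
      ## grow a stem outward-in from pair (i, j)
      len <- 0L
      while (i + len < j - len - min_loop && x[i + len] == comp[j - len]) {
        len <- len + 1L
      }
      if (len >= 2L) {
        dg <- 0
        for (p in seq_len(len - 1L)) {
          dg <- dg + thermo[[paste0(x[i + p - 1L], x[i + p])]]
        }
        if (dg < best) best <- dg
      }
    }
  }
  best
}

#' Antisense-strand self-structure features
#'
#' `antisense_dimer_dg` scores the most stable ungapped antiparallel
#' hybridisation of the antisense (guide) strand with a second copy of
#' itself; `antisense_hairpin_dg` scores the most stable simple hairpin stem
#' within the strand (0 for a hairpin-free sequence). Both are deliberately
#' simple stand-ins for full secondary-structure prediction and can be
#' replaced by an external folding engine via `fold_fun`.
#'
#' @param seq 19-nt sense sequence; the antisense strand is its reverse
#'   complement.
#' @param thermo stacking table from [thermo_table()].
#' @param fold_fun optional function(antisense_sequence) returning a delta-G;
#'   when supplied it replaces the built-in scorer.
#' @return delta-G in kcal/mol (0 = no structure found).
#' @export
antisense_dimer_dg <- function(seq, thermo = thermo_table(), fold_fun = NULL) {
  seq <- .check_seq(seq)
  anti <- reverse_complement_rna(seq)
  if (!is.null(fold_fun)) return(fold_fun(anti))
  .self_dimer_dg(anti, thermo)
}

#' @rdname antisense_dimer_dg
#' @param min_loop minimum hairpin loop length in nucleotides.
#' @export
antisense_hairpin_dg <- function(seq, thermo = thermo_table(),
                                 min_loop = 3L, fold_fun = NULL) {
  seq <- .check_seq(seq)
  anti <- reverse_complement_rna(seq)
  if (!is.null(fold_fun)) return(fold_fun(anti))
  .hairpin_dg(anti, thermo, min_loop)
}

#' Local stability of the target mRNA around the siRNA site
#'
#' Finds the (first) exact target site of the siRNA on the mRNA — the site
#' read 5'-3' equals the sense-strand sequence — and sums nearest-neighbor
#' stacking terms over a window extending the site by `flank` nucleotides on
#' each side. A more negative value means a more structured, less accessible
#' local region.
#'
#' @param seq 19-nt sense sequence.
#' @param mrna_seq target mRNA sequence (character; T normalised to U).
#' @param thermo stacking table from [thermo_table()].
#' @param flank window extension on each side of the site, nt.
#' @return local delta-G in kcal/mol.
#' @export
local_target_dg <- function(seq, mrna_seq, thermo = thermo_table(),
                            flank = 10L) {
  seq <- .check_seq(seq)
  mrna_seq <- normalize_rna(mrna_seq)
  at <- regexpr(seq, mrna_seq, fixed = TRUE)
  if (at < 0) stop("target site not found in the supplied mRNA sequence")
  lo <- max(1L, at - flank)
  hi <- min(nchar(mrna_seq), at + SIRNA_LEN - 1L + flank)
  window <- substr(mrna_seq, lo, hi)
  steps <- substring(window, 1:(nchar(window) - 1L), 2:nchar(window))
  sum(thermo[steps])
}

#' Number of potential target sites on the supplied mRNA sequences
#'
#' Counts exact occurrences of the siRNA's target site across one or more
#' mRNA sequences.
#'
#' @param seq 19-nt sense sequence.
#' @param mrna_seqs character vector of mRNA sequences.
#' @return integer count of exact sites.
#' @export
target_site_count <- function(seq, mrna_seqs) {
  seq <- .check_seq(seq)
  mrna_seqs <- normalize_rna(mrna_seqs)
  sum(vapply(mrna_seqs, function(m) {
    hits <- gregexpr(seq, m, fixed = TRUE)[[1]]
    if (hits[1] < 0) 0L else length(hits)
  }, integer(1)))
}

#' Compute the 19-feature vector for one siRNA
#'
#' Evaluates all 19 features in canonical order (see [feature_names()]).
#' The two target-dependent features (`local_target_dg`,
#' `target_site_count`) need the target mRNA sequence; without one they are
#' set to 0 and a warning is raised (the documented sentinel policy).
#'
#' @param seq 19-nt sense sequence.
#' @param mrna_seq optional target mRNA sequence.
#' @param thermo stacking table from [thermo_table()].
#' @param consensus consensus definition from [consensus_table()].
#' @param dinucs list with `preferred` and `avoided` dinucleotide sets.
#' @param warn_sentinel warn when mRNA-dependent features fall back to 0.
#' @return named numeric vector of length 19.
#' @export
sirna_features <- function(seq, mrna_seq = NULL,
                           thermo = thermo_table(),
                           consensus = consensus_table(),
                           dinucs = .dinucleotide_sets(),
                           warn_sentinel = TRUE) {
  seq <- .check_seq(seq)
  cons <- position_consensus_scores(seq, consensus)
  if (is.null(mrna_seq)) {
    if (warn_sentinel) {
      warning("no mRNA sequence: local_target_dg and target_site_count set to 0")
    }
    local_dg <- 0
    sites <- 0
  } else {
    local_dg <- local_target_dg(seq, mrna_seq, thermo)
    sites <- target_site_count(seq, mrna_seq)
  }
  out <- c(
    cons[["sum"]],
    delta_g_diff_1_18(seq, thermo),
    duplex_delta_g(seq, thermo),
    cons[["preferred"]],
    .dinucleotide_index(seq, dinucs$preferred),
    local_dg,
    cons[["avoided"]],
    nucleotide_content(seq, "U"),
    antisense_dimer_dg(seq, thermo),
    stability_profile(seq, 1L, thermo),
    antisense_hairpin_dg(seq, thermo),
    .dinucleotide_index(seq, dinucs$avoided),
    stability_profile(seq, 13L, thermo),
    stability_profile(seq, 18L, thermo),
    nucleotide_content(seq, "G"),
    stability_profile(seq, 2L, thermo),
    stability_profile(seq, 6L, thermo),
    stability_profile(seq, 14L, thermo)
  )
  out <- c(out, sites)
  stats::setNames(out, .feature_names)
}

#' Compute the feature matrix for a record table
#'
#' @param records validated siRNA record data.frame (see [sirna-records]).
#' @param mrna optional named character vector of mRNA sequences keyed by
#'   accession (as in the records' `mrna` column); records without a matching
#'   sequence use the 0-sentinel policy for target-dependent features.
#' @inheritParams sirna_features
#' @return numeric matrix, one row per record, 19 named columns.
#' @export
feature_matrix <- function(records, mrna = NULL,
                           thermo = thermo_table(),
                           consensus = consensus_table(),
                           dinucs = .dinucleotide_sets()) {
  n_missing <- 0L
  rows <- lapply(seq_len(nrow(records)), function(i) {
    acc <- records$mrna[i]
    mseq <- if (!is.null(mrna) && acc %in% names(mrna)) mrna[[acc]] else NULL
    if (is.null(mseq)) n_missing <<- n_missing + 1L
    sirna_features(records$sequence[i], mseq, thermo, consensus, dinucs,
                   warn_sentinel = FALSE)
  })
  if (n_missing > 0L) {
    warning(n_missing, " record(s) without an mRNA sequence: ",
            "target-dependent features set to 0")
  }
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  X
}

#' Write / read a 19-column feature table
#'
#' @param X feature matrix with the 19 canonical columns.
#' @param path tab-delimited output/input path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the matrix.
#' @export
write_feature_table <- function(X, path) {
  stopifnot(ncol(X) == length(.feature_names))
  colnames(X) <- .feature_names
  utils::write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  missing <- setdiff(.feature_names, names(tab))
  if (length(missing)) {
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(tab[, .feature_names])
}
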