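#' siRNA record tables
#'
#' An siRNA record table is a plain `data.frame` with one row per siRNA and
#' columns `sequence` (19-nt sense strand), `efficacy` (percent inhibition on
#' the experiment's native scale), `experiment` (platform/experiment token),
#' `mrna` (target mRNA accession) and optionally `concentration` (nM).
#' Sequences are held in the RNA alphabet: any `T` in the input is normalised
#' to `U`, since published tables mix DNA and RNA spellings.
#'
#' @name sirna-records
NULL

SIRNA_LEN <- 19L
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalise a sequence to the RNA alphabet
#'
#' Uppercases and replaces `T` with `U`.
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector in the RNA alphabet.
#' @export
normalize_rna <- function(seq) {
  gsub("T", "U", toupper(seq), fixed = TRUE)
}

## Returns a character vector of row-level problems ("" = ok).
.record_problems <- function(sequence, efficacy) {
  msg <- character(length(sequence))
  bad_len <- nchar(sequence) != SIRNA_LEN
  msg[bad_len] <- sprintf("sequence length %d != 19", nchar(sequence)[bad_len])
  bad_alpha <- !bad_len & grepl("[^ACGU]", sequence)
  msg[bad_alpha] <- "sequence contains characters outside {A,C,G,U/T}"
  bad_eff <- !is.finite(efficacy)
  msg[bad_eff & !nzchar(msg)] <- "efficacy is not a finite number"
  msg
}

#' Validate an siRNA record table
#'
#' Checks sequence length (19 nt), the RNA alphabet after T-to-U
#' normalisation, and that every efficacy value is finite. Errors list the
#' offending rows.
#'
#' @param records data.frame with columns `sequence`, `efficacy`,
#'   `experiment`, `mrna` and optionally `concentration`.
#' @return the validated records, with sequences normalised to RNA.
#' @export
validate_sirna_records <- function(records) {
  required <- c("sequence", "efficacy", "experiment", "mrna")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  records$sequence <- normalize_rna(records$sequence)
  records$efficacy <- as.numeric(records$efficacy)
  msg <- .record_problems(records$sequence, records$efficacy)
  bad <- which(nzchar(msg))
  if (length(bad)) {
    stop(
      "invalid siRNA records:\n",
      paste(sprintf("  row %d: %s", bad, msg[bad]), collapse = "\n")
    )
  }
  records
}

#' Read an siRNA dataset from delimited text
#'
#' Reads a tab- or comma-delimited table with a header containing at least
#' `sequence`, `efficacy`, `experiment` and `mrna` columns, normalises the
#' sequences to the RNA alphabet and validates every row.
#'
#' @param path file path; `.csv` is read comma-delimited, anything else
#'   tab-delimited unless `sep` is given.
#' @param sep field separator, inferred from the extension by default.
#' @return a validated record `data.frame` (see [sirna-records]).
#' @export
read_sirna_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  records <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "", check.names = TRUE)
  validate_sirna_records(records)
}

#' Write an siRNA dataset as delimited text
#'
#' @param records validated record data.frame.
#' @param path output path; `.csv` writes comma-delimited, else tab.
#' @param sep field separator, inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_sirna_table <- function(records, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read mRNA sequences from a FASTA file
#'
#' Thin wrapper around Biostrings; returns plain uppercase RNA-alphabet
#' character strings named by the FASTA identifiers, which is the form the
#' feature functions expect.
#'
#' @param path FASTA file of target mRNA sequences (DNA or RNA alphabet).
#' @return named character vector of sequences.
#' @export
read_mrna_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_rna(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}
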