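# File formats: DNA targets come in as FASTA or one-sequence-per-line text;
# training pairs travel as 2-column TSV (dna, protein).  Output TSVs carry a
# single provenance comment line so a run can be traced to its config.

#' Read 9 bp DNA targets from FASTA or plain text
#'
#' FASTA description lines are preserved as query IDs; for plain text the
#' IDs are `query_1`, `query_2`, ...  Every sequence is validated as a 9-mer
#' over \{A,C,G,T\}.
#'
#' @param path file path.
#' @param format `"auto"` (default; FASTA detected by a leading `>`),
#'   `"fasta"`, or `"text"`.
#' @return named character vector of validated targets.
#' @export
read_targets <- function(path, format = c("auto", "fasta", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_validation(sprintf("target file not found: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) > 0L && startsWith(trimws(first), ">")) "fasta" else "text"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    ids <- names(set)
  } else {
    seqs <- trimws(readLines(path, warn = FALSE))
    seqs <- seqs[nzchar(seqs)]
    ids <- paste0("query_", seq_along(seqs))
  }
  if (length(seqs) == 0L) abort_validation(sprintf("no sequences in %s", path))
  out <- vapply(seqs, function(s) unclass(dna_target(s)), character(1L),
                USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Read training pairs from TSV
#'
#' Expects columns `dna` (9-mer) and `protein` (21-mer); comment lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with validated character columns `dna`, `protein`.
#' @export
read_training_pairs <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("pairs file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("dna", "protein") %in% names(df))) {
    abort_validation("training pairs TSV must have columns 'dna' and 'protein'")
  }
  df$dna <- vapply(df$dna, function(s) unclass(dna_target(s)), character(1L),
                   USE.NAMES = FALSE)
  df$protein <- vapply(df$protein, function(s) unclass(zfp_design(s)), character(1L),
                       USE.NAMES = FALSE)
  df[, c("dna", "protein")]
}

#' Write training pairs to TSV
#'
#' @param pairs data.frame with columns `dna`, `protein`.
#' @param path output path.
#' @param comment optional provenance string written as a leading `#` line.
#' @export
write_training_pairs <- function(pairs, path, comment = NULL) {
  write_tsv(pairs[, c("dna", "protein")], path, comment = comment)
}

# Shared TSV writer: optional '# ...' provenance line, then header + rows.
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write representative targets as FASTA
#'
#' @param seqs character vector of sequences; names become FASTA IDs
#'   (defaults `rep_1`, `rep_2`, ...).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("rep_", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", unname(seqs)), path)
  invisible(path)
}
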