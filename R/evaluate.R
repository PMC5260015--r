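# Hamming-identity evaluation of ZFP predictions.
#
# Accuracy is measured by position-wise sequence identity between a
# predicted 21-residue design and the experimentally identified one:
# matches/21, i.e. 1 - HammingDistance/21.  Two display conventions are
# used downstream and both are provided: per-row table cells truncate to
# two decimals (16/21 = 0.7619 -> 0.76), while prose-style percentages
# round to the nearest percent (0.8095 -> 81%).

#' Position-wise sequence identity between two ZFP designs
#'
#' @param a,b 21-residue designs (strings or [zfp_design()]).
#' @return exact fraction matches/21 in \[0, 1\].
#' @examples
#' sequence_identity("QSGNLTRRSGHLTRRSGELTR", "DSGHLTRDSGHLTRDSGHLTR")  # 16/21
#' @export
sequence_identity <- function(a, b) {
  a <- unclass(zfp_design(a))
  b <- unclass(zfp_design(b))
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(ca == cb) / 21
}

#' Truncate an identity for table display
#'
#' Table cells show identities truncated (not rounded) to `digits`
#' decimals: 17/21 = 0.8095 displays as 0.80.
#'
#' @param x identity fraction(s).
#' @param digits decimals kept (default 2).
#' @return truncated numeric.
#' @export
identity_display <- function(x, digits = 2L) {
  floor(x * 10^digits + 1e-9) / 10^digits
}

#' Round an identity to a whole percentage
#'
#' Prose-style display: 0.8095 -> 81.
#'
#' @param x identity fraction(s).
#' @return integer percentage.
#' @export
percent_display <- function(x) {
  as.integer(round(100 * x))
}

#' Build a prediction-vs-experiment comparison report
#'
#' @param rows data.frame with columns `target` (9-mer), `experimental`
#'   (21-mer) and `predicted` (21-mer or `NA` where the tool made no
#'   prediction).
#' @return object of class `comparison_report`: list with `rows` (input
#'   plus an `identity` column, `NA` where no prediction), `average_identity`
#'   (mean of unrounded identities over predicted rows) and `coverage`
#'   (fraction of rows with a prediction).
#' @export
build_report <- function(rows) {
  if (!is.data.frame(rows) ||
      !all(c("target", "experimental", "predicted") %in% names(rows)) ||
      nrow(rows) == 0L) {
    abort_validation("rows must be a nonempty data.frame with target, experimental, predicted")
  }
  rows$target <- vapply(rows$target, function(s) unclass(dna_target(s)), character(1L),
                        USE.NAMES = FALSE)
  rows$experimental <- vapply(rows$experimental, function(s) unclass(zfp_design(s)),
                              character(1L), USE.NAMES = FALSE)
  has_pred <- !is.na(rows$predicted) & nzchar(rows$predicted) & rows$predicted != "-"
  rows$identity <- NA_real_
  rows$identity[has_pred] <- vapply(which(has_pred), function(i) {
    sequence_identity(rows$experimental[i], rows$predicted[i])
  }, numeric(1L))
  structure(list(rows = rows,
                 average_identity = mean(rows$identity[has_pred]),
                 coverage = mean(has_pred)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report: %d targets, coverage %d%%, average identity %s\n",
              nrow(x$rows), percent_display(x$coverage),
              ifelse(is.nan(x$average_identity), "-",
                     sprintf("%d%%", percent_display(x$average_identity)))))
  invisible(x)
}

#' Match a DNA target against a consensus pattern
#'
#' Patterns are 9 positional tokens over \{A,C,G,T,N\} plus two-letter
#' alternations written `X/Y` (e.g. `GNGNA/TNGAN`): `N` matches any base,
#' `X/Y` matches either listed base.
#'
#' @param target a [dna_target()] or valid 9-mer.
#' @param pattern consensus pattern string.
#' @return logical.
#' @examples
#' matches_consensus("GCTGCTGCT", "GCNGNNGCN")  # TRUE
#' @export
matches_consensus <- function(target, pattern) {
  target <- unclass(dna_target(target))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (i + 2L <= length(chars) && chars[i + 1L] == "/") {
      tokens <- c(tokens, paste0(chars[i], "/", chars[i + 2L]))
      i <- i + 3L
    } else {
      tokens <- c(tokens, chars[i])
      i <- i + 1L
    }
  }
  if (length(tokens) != 9L) {
    abort_validation(sprintf("consensus pattern must have 9 positions, got %d (\"%s\")",
                             length(tokens), pattern))
  }
  tchars <- strsplit(target, "", fixed = TRUE)[[1L]]
  ok <- vapply(seq_len(9L), function(p) {
    tok <- tokens[p]
    if (tok == "N") return(TRUE)
    alts <- strsplit(tok, "/", fixed = TRUE)[[1L]]
    if (!all(alts %in% c("A", "C", "G", "T"))) {
      abort_validation(sprintf("invalid consensus token '%s' at position %d", tok, p))
    }
    tchars[p] %in% alts
  }, logical(1L))
  all(ok)
}

#' Published tool-comparison fixture
#'
#' The packaged benchmark of 16 experimentally characterised 9 bp targets
#' with their literature-reported optimal ZFPs and the designs returned by
#' three prediction tools (`zifnn`, `zifit`, `zftools`); `-` marks targets
#' for which a tool made no prediction.  Identity columns hold the values
#' as printed in the original comparison (truncated to two decimals).
#'
#' @return data.frame, one row per benchmark target.
#' @export
table3_comparisons <- function() {
  path <- system.file("extdata", "tool_comparison_benchmark.tsv", package = "zifnn")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "-")
  df
}
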