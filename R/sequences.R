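#' Sequence types and one-hot encodings
#'
#' A three-finger Cys2-His2 ZFP reads a 9 bp DNA target as three 3 bp
#' subsites, one per finger.  Each finger contacts its subsite through the
#' seven recognition-helix residues at alpha-helical positions
#' -1, +1, +2, +3, +4, +5, +6; the residues at -1, +3 and +6 (together with
#' the fixed +2) form the "recognition code".  This file defines the
#' validated domain types and the exact one-hot encodings consumed by the
#' neural networks.
#'
#' @name sequences
NULL

# Base order of the 4-entry one-hot code used by the networks.
DNA_CODE <- c("A", "T", "G", "C")

# Lexicographic DNA alphabet (used for enumeration / ordering, not encoding).
DNA_ALPHABET <- c("A", "C", "G", "T")

# Amino-acid order of the 20-entry one-hot blocks: alphabetical one-letter
# codes.  Fixed once here and used everywhere.
AA_CODE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Offsets (1-based) of helix positions -1, +3, +6 within the 7-residue helix
# (-1, +1, +2, +3, +4, +5, +6); +2 sits at offset 3 and is never mutated.
HELIX_KEY_OFFSETS <- c(`-1` = 1L, `+3` = 4L, `+6` = 7L)
HELIX_PLUS2_OFFSET <- 3L

#' Validate a 9 bp DNA target
#'
#' A DNA target is a 9-character string over \{A,C,G,T\}, read 5'->3'.
#' Ambiguity codes (including N) are rejected rather than expanded.
#'
#' @param x character scalar.
#' @return The validated string, with class `dna_target`.
#' @examples
#' dna_target("GCTGCTGCT")
#' @export
dna_target <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort_validation("DNA target must be a single character string")
  }
  x <- toupper(x)
  if (nchar(x) != 9L) {
    abort_validation(sprintf("DNA target must have length 9, got %d (\"%s\")",
                             nchar(x), x))
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% DNA_ALPHABET)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "invalid base '%s' at position %d of DNA target \"%s\" (alphabet is A,C,G,T)",
      chars[bad[1L]], bad[1L], x))
  }
  structure(x, class = c("dna_target", "character"))
}

#' Extract a 3 bp subsite of a DNA target
#'
#' Subsites are numbered 1..3 in genomic (5'->3') order; concatenating them
#' in order recovers the full target.
#'
#' @param target a [dna_target()] (or valid 9-mer string).
#' @param i subsite index in 1..3.
#' @return 3-character string.
#' @export
subsite <- function(target, i) {
  target <- dna_target(target)
  if (!i %in% 1:3) abort_validation("subsite index must be 1, 2 or 3")
  substr(unclass(target), 3L * (i - 1L) + 1L, 3L * i)
}

#' Validate a 7-residue recognition helix
#'
#' @param x character scalar of 7 one-letter amino-acid codes
#'   (positions -1, +1, +2, +3, +4, +5, +6).
#' @return validated string with class `recognition_helix`.
#' @export
recognition_helix <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort_validation("recognition helix must be a single character string")
  }
  x <- toupper(x)
  if (nchar(x) != 7L) {
    abort_validation(sprintf("recognition helix must have length 7, got %d (\"%s\")",
                             nchar(x), x))
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_CODE)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "invalid residue '%s' at helix position %d of \"%s\"",
      chars[bad[1L]], bad[1L], x))
  }
  structure(x, class = c("recognition_helix", "character"))
}

#' Construct a three-finger ZFP design
#'
#' A design is the ordered triple of recognition helices (F1, F2, F3),
#' stored flattened as the 21-residue string F1+F2+F3.  The triple and the
#' flattened form round-trip losslessly.
#'
#' @param f1 either a full 21-residue string, or finger 1's 7-residue helix.
#' @param f2,f3 helices for fingers 2 and 3 when `f1` is a single helix.
#' @return validated 21-residue string with class `zfp_design`.
#' @examples
#' zfp_design("RSDELTR", "RSDHLTT", "RSDERKR")
#' zfp_design("RSDELTRRSDHLTTRSDERKR")
#' @export
zfp_design <- function(f1, f2 = NULL, f3 = NULL) {
  if (is.null(f2) && is.null(f3)) {
    if (!is.character(f1) || length(f1) != 1L || is.na(f1)) {
      abort_validation("ZFP design must be a single character string")
    }
    f1 <- toupper(f1)
    if (nchar(f1) != 21L) {
      abort_validation(sprintf("flattened ZFP design must have length 21, got %d",
                               nchar(f1)))
    }
    helices <- substring(f1, c(1L, 8L, 15L), c(7L, 14L, 21L))
  } else {
    helices <- c(f1, f2, f3)
  }
  helices <- vapply(helices, function(h) unclass(recognition_helix(h)), character(1L))
  structure(paste0(helices[1L], helices[2L], helices[3L]),
            class = c("zfp_design", "character"))
}

#' Split a ZFP design into its three recognition helices
#'
#' @param design a [zfp_design()] (or valid 21-residue string).
#' @return named character vector `c(F1 = , F2 = , F3 = )`.
#' @export
zfp_helices <- function(design) {
  design <- zfp_design(design)
  h <- substring(unclass(design), c(1L, 8L, 15L), c(7L, 14L, 21L))
  names(h) <- c("F1", "F2", "F3")
  h
}

#' One-hot encode a DNA target
#'
#' Produces the length-36 vector consumed by the networks: nine consecutive
#' 4-entry blocks, one per base, with code order A=(1,0,0,0), T=(0,1,0,0),
#' G=(0,0,1,0), C=(0,0,0,1).
#'
#' @param target a [dna_target()] or valid 9-mer string.
#' @return numeric vector of length 36 with exactly one 1 per block.
#' @export
encode_dna <- function(target) {
  target <- dna_target(target)
  chars <- strsplit(unclass(target), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_CODE)
  v <- numeric(36L)
  v[4L * (seq_len(9L) - 1L) + idx] <- 1
  v
}

#' Decode a length-36 vector to a DNA target
#'
#' Each 4-entry block is decoded by argmax through the A,T,G,C code; ties
#' resolve to the lowest index.  Total on any real-valued input of the right
#' length, so raw network outputs decode directly.
#'
#' @param v numeric vector of length 36.
#' @return a [dna_target()].
#' @export
decode_dna <- function(v) {
  if (!is.numeric(v) || length(v) != 36L) {
    abort_validation(sprintf("decode_dna() expects a numeric vector of length 36, got length %d",
                             length(v)))
  }
  m <- matrix(v, nrow = 4L)
  dna_target(paste0(DNA_CODE[apply(m, 2L, which.max)], collapse = ""))
}

#' One-hot encode a ZFP design
#'
#' Produces the length-420 vector: 21 consecutive 20-entry blocks, one per
#' residue, indexed by the alphabetical one-letter amino-acid order
#' `A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y`.
#'
#' @param design a [zfp_design()] or valid 21-residue string.
#' @return numeric vector of length 420 with exactly one 1 per block.
#' @export
encode_protein <- function(design) {
  design <- zfp_design(design)
  chars <- strsplit(unclass(design), "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA_CODE)
  v <- numeric(420L)
  v[20L * (seq_len(21L) - 1L) + idx] <- 1
  v
}

#' Decode a length-420 vector to a ZFP design
#'
#' Per-20-block argmax through the alphabetical amino-acid order, lowest
#' index on ties.  Raw sigmoid outputs of a network decode directly.
#'
#' @param v numeric vector of length 420.
#' @return a [zfp_design()].
#' @export
decode_protein <- function(v) {
  if (!is.numeric(v) || length(v) != 420L) {
    abort_validation(sprintf("decode_protein() expects a numeric vector of length 420, got length %d",
                             length(v)))
  }
  m <- matrix(v, nrow = 20L)
  zfp_design(paste0(AA_CODE[apply(m, 2L, which.max)], collapse = ""))
}
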