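# Recognition-helix library enumeration.
#
# Candidate helices are generated by mutating the key alpha-helical
# positions -1, +3 and +6 of the Zif-268 template fingers.  Position +2 is
# kept fixed to eliminate cross-strand interactions, and the non-key
# positions always retain the template residue.  Restricting each key
# position to the residues most frequently observed in sequence-specific
# DNA binding keeps the library small: with allowed-set sizes 7, 8 and 8
# the library has 7*8*8 = 448 members.

#' Zif-268 template recognition helices
#'
#' The seven-residue helices (positions -1..+6) of the three fingers of the
#' Zif-268 prototype, from the 1AAY crystal structure sequence.
#'
#' @return named character vector `c(F1=, F2=, F3=)`.
#' @export
zif268_template <- function() {
  c(F1 = "RSDELTR", F2 = "RSDHLTT", F3 = "RSDERKR")
}

#' Default allowed-mutation table (synthetic stand-in)
#'
#' Allowed residues per key position with set sizes 7, 8, 8 (order -1, +3,
#' +6), assembled from residues commonly reported in the Cys2-His2
#' recognition code.  The original study's per-position residue lists were
#' published only as supplementary material, so this default is a clearly
#' labelled stand-in: every count and test in the package depends only on
#' the set sizes, and the table is fully user-overridable (see
#' [mutation_table()] and [read_mutation_table()]).
#'
#' @return a `mutation_table` object.
#' @export
default_mutation_table <- function() {
  mutation_table(list(
    `-1` = c("D", "E", "K", "N", "Q", "R", "T"),
    `+3` = c("A", "D", "E", "H", "N", "S", "T", "V"),
    `+6` = c("A", "E", "K", "N", "Q", "R", "T", "V")
  ))
}

#' Construct an allowed-mutation table
#'
#' @param allowed named list with entries exactly `-1`, `+3`, `+6`, each a
#'   nonempty character vector of one-letter amino-acid codes.  A `+2` key
#'   is rejected: that position is never mutated.
#' @return validated `mutation_table` (sets stored sorted alphabetically).
#' @export
mutation_table <- function(allowed) {
  if (!is.list(allowed)) abort_validation("mutation table must be a named list")
  if ("+2" %in% names(allowed)) {
    abort_validation("position +2 must not be mutated (it is kept fixed)")
  }
  keys <- c("-1", "+3", "+6")
  if (!setequal(names(allowed), keys)) {
    abort_validation("mutation table keys must be exactly -1, +3, +6")
  }
  allowed <- allowed[keys]
  for (k in keys) {
    set <- toupper(allowed[[k]])
    if (length(set) == 0L) abort_validation(sprintf("allowed set for %s is empty", k))
    if (anyDuplicated(set)) abort_validation(sprintf("duplicate residues in set for %s", k))
    bad <- setdiff(set, AA_CODE)
    if (length(bad) > 0L) {
      abort_validation(sprintf("invalid residue '%s' in allowed set for %s", bad[1L], k))
    }
    allowed[[k]] <- sort(set)
  }
  structure(allowed, class = "mutation_table")
}

#' Read a mutation table from a YAML config file
#'
#' The file maps each key position to a residue list, e.g.
#' \preformatted{
#' "-1": [D, E, K, N, Q, R, T]
#' "+3": [A, D, E, H, N, S, T, V]
#' "+6": [A, E, K, N, Q, R, T, V]
#' }
#'
#' @param path YAML file path.
#' @return a `mutation_table`.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("mutation table file not found: %s", path))
  mutation_table(yaml::read_yaml(path))
}

#' Enumerate a recognition-helix library from a template
#'
#' Forms the full Cartesian product of the allowed residues at positions
#' -1, +3 and +6, retaining the template residue at every other position.
#' Order is deterministic: -1 varies slowest, +6 fastest, each set sorted
#' alphabetically.
#'
#' @param template 7-residue template helix (see [zif268_template()]).
#' @param table a [mutation_table()]; default [default_mutation_table()].
#' @return object of class `helix_library`: list with `template`, `members`
#'   (character vector of distinct helices) and `sizes` (allowed-set sizes).
#' @examples
#' lib <- enumerate_helices(zif268_template()[["F1"]])
#' length(lib$members)  # 7*8*8 = 448
#' @export
enumerate_helices <- function(template, table = default_mutation_table()) {
  template <- recognition_helix(template)
  if (!inherits(table, "mutation_table")) table <- mutation_table(table)
  g <- expand.grid(p6 = table[["+6"]], p3 = table[["+3"]], p1 = table[["-1"]],
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tpl <- strsplit(unclass(template), "", fixed = TRUE)[[1L]]
  n <- nrow(g)
  chars <- matrix(tpl, nrow = n, ncol = 7L, byrow = TRUE)
  chars[, HELIX_KEY_OFFSETS[["-1"]]] <- g$p1
  chars[, HELIX_KEY_OFFSETS[["+3"]]] <- g$p3
  chars[, HELIX_KEY_OFFSETS[["+6"]]] <- g$p6
  members <- apply(chars, 1L, paste0, collapse = "")
  structure(list(template = unclass(template), members = members,
                 sizes = lengths(unclass(table))),
            class = "helix_library")
}

#' Lazy iterator over the three-finger design space
#'
#' Streams the Cartesian product of three helix libraries (one per finger)
#' without materialising it; a full 448^3 space (~9e7 designs) is iterated
#' in constant memory.  F1 varies slowest, F3 fastest.
#'
#' @param lib1,lib2,lib3 `helix_library` objects for fingers F1, F2, F3.
#' @return object of class `design_space`: list with `n` (total count) and
#'   `next_design()`, a closure returning the next 21-residue design string
#'   or `NULL` when exhausted.
#' @export
design_space <- function(lib1, lib2, lib3) {
  libs <- list(lib1, lib2, lib3)
  for (l in libs) {
    if (!inherits(l, "helix_library")) abort_validation("design_space() expects helix_library objects")
  }
  sizes <- vapply(libs, function(l) length(l$members), integer(1L))
  total <- prod(as.numeric(sizes))
  i <- 0
  next_design <- function() {
    if (i >= total) return(NULL)
    r <- i
    i3 <- r %% sizes[3L]; r <- r %/% sizes[3L]
    i2 <- r %% sizes[2L]; r <- r %/% sizes[2L]
    i1 <- r
    i <<- i + 1
    paste0(libs[[1L]]$members[i1 + 1L],
           libs[[2L]]$members[i2 + 1L],
           libs[[3L]]$members[i3 + 1L])
  }
  structure(list(n = total, next_design = next_design), class = "design_space")
}
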