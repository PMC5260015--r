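# Hydrogen-bond free-energy scoring of protein-DNA complexes.
#
# Amino acid-base hydrogen bonds are the most frequent specific contact in
# protein-DNA interfaces, so candidate complexes are ranked by the summed
# free energy of their hydrogen bonds.  Each bond contributes an 8-6
# Lennard-Jones-style radial term scaled by a cos^4 angular term:
#
#   dG(hb) = eps_ij * [ 3 (d'_ij / d_ij)^8 - 4 (d'_ij / d_ij)^6 ] * cos^4(theta)
#
# where eps_ij is the optimum bond energy and d'_ij the optimum bond length
# for the donor/acceptor element pair (N or O), d_ij the observed
# donor-acceptor distance and theta the deviation from linearity (theta = 0
# is an ideal, linear bond).  At d_ij = d'_ij and theta = 0 the energy is
# exactly -eps_ij; it vanishes at theta = 90 degrees and diverges to +Inf
# as d_ij -> 0 (repulsive core).
#
# Geometry records are consumed as plain TSV (donor_element,
# acceptor_element, distance, angle) standing in for the output of a
# structure-based H-bond extraction step; no distance or angle cutoff is
# applied before summation.

#' Default hydrogen-bond pair-class parameters
#'
#' Optimum energies (kcal/mol) and lengths (Angstrom) per unordered
#' donor/acceptor element pair: N-N (2.0, 3.2), N-O (2.8, 3.0),
#' O-O (4.0, 2.8).
#'
#' @return an `hbond_params` object (data.frame with columns `pair_class`,
#'   `epsilon`, `d_opt`).
#' @export
default_hbond_params <- function() {
  hbond_params(data.frame(
    pair_class = c("N-N", "N-O", "O-O"),
    epsilon = c(2.0, 2.8, 4.0),
    d_opt = c(3.2, 3.0, 2.8),
    stringsAsFactors = FALSE
  ))
}

#' Construct/validate hydrogen-bond parameters
#'
#' @param table data.frame with columns `pair_class` (among "N-N", "N-O",
#'   "O-O"), `epsilon` (> 0, kcal/mol) and `d_opt` (> 0, Angstrom).
#' @return validated `hbond_params`.
#' @export
hbond_params <- function(table) {
  if (!is.data.frame(table) || !all(c("pair_class", "epsilon", "d_opt") %in% names(table))) {
    abort_validation("hbond params must be a data.frame with pair_class, epsilon, d_opt")
  }
  bad <- setdiff(table$pair_class, c("N-N", "N-O", "O-O"))
  if (length(bad) > 0L) abort_validation(sprintf("unknown pair class '%s'", bad[1L]))
  if (anyDuplicated(table$pair_class)) abort_validation("duplicate pair classes")
  if (any(table$epsilon <= 0) || any(table$d_opt <= 0)) {
    abort_validation("epsilon and d_opt must be positive")
  }
  structure(table[, c("pair_class", "epsilon", "d_opt")],
            class = c("hbond_params", "data.frame"))
}

# Unordered element pair -> class label ("N-O" for either orientation).
pair_class <- function(donor, acceptor) {
  for (e in c(donor, acceptor)) {
    if (!e %in% c("N", "O")) abort_validation(sprintf("unknown element '%s' (expected N or O)", e))
  }
  p <- sort(c(donor, acceptor))
  paste(p, collapse = "-")
}

#' Free energy of a single hydrogen bond
#'
#' Evaluates the 8-6 radial / cos^4 angular hydrogen-bond energy for one
#' donor-acceptor pair.  The angle is the deviation from linearity in
#' degrees (0 = ideal bond) and is converted to radians internally.
#'
#' @param donor,acceptor element symbols, `"N"` or `"O"`.
#' @param distance donor-acceptor distance in Angstrom (> 0).
#' @param angle deviation from linearity in degrees, in \[0, 180\].
#' @param params an [hbond_params()]; default [default_hbond_params()].
#' @return energy in kcal/mol (negative = attractive).
#' @examples
#' hbond_energy("N", "O", distance = 3.0, angle = 0)  # -2.8 at the optimum
#' @export
hbond_energy <- function(donor, acceptor, distance, angle,
                         params = default_hbond_params()) {
  params <- hbond_params(params)
  if (!is.numeric(distance) || length(distance) != 1L || is.na(distance) || distance <= 0) {
    abort_validation("distance must be a positive number (Angstrom)")
  }
  if (!is.numeric(angle) || length(angle) != 1L || is.na(angle) || angle < 0 || angle > 180) {
    abort_validation("angle must be in [0, 180] degrees")
  }
  cls <- pair_class(donor, acceptor)
  row <- match(cls, params$pair_class)
  if (is.na(row)) abort_validation(sprintf("no parameters for pair class %s", cls))
  eps <- params$epsilon[row]
  d_opt <- params$d_opt[row]
  r <- d_opt / distance
  eps * (3 * r^8 - 4 * r^6) * cos(angle * pi / 180)^4
}

#' Parse hydrogen-bond geometry records from TSV
#'
#' Expects a header `donor_element`, `acceptor_element`, `distance`,
#' `angle`; comment lines starting with `#` are skipped.  Malformed rows
#' are rejected with their line number.  An empty file is a valid complex
#' with zero bonds.
#'
#' @param path TSV file path.
#' @return data.frame of validated records with a `line` column for
#'   traceability.
#' @export
parse_hbond_records <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("bond file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  empty <- data.frame(donor_element = character(0), acceptor_element = character(0),
                      distance = numeric(0), angle = numeric(0), line = integer(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("donor_element", "acceptor_element", "distance", "angle")
  if (!all(need %in% header)) {
    abort_validation(sprintf("bond TSV header must contain: %s", paste(need, collapse = ", ")))
  }
  if (length(lines) == 1L) return(empty)
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      abort_validation(sprintf("line %d: expected %d fields, got %d",
                               lineno[i], length(header), length(f)))
    }
    rec <- as.list(f)
    names(rec) <- header
    for (e in c(rec$donor_element, rec$acceptor_element)) {
      if (!e %in% c("N", "O")) {
        abort_validation(sprintf("line %d: unknown element '%s'", lineno[i], e))
      }
    }
    d <- suppressWarnings(as.numeric(rec$distance))
    a <- suppressWarnings(as.numeric(rec$angle))
    if (is.na(d) || d <= 0) {
      abort_validation(sprintf("line %d: distance must be a positive number, got '%s'",
                               lineno[i], rec$distance))
    }
    if (is.na(a) || a < 0 || a > 180) {
      abort_validation(sprintf("line %d: angle must be in [0, 180], got '%s'",
                               lineno[i], rec$angle))
    }
    data.frame(donor_element = rec$donor_element, acceptor_element = rec$acceptor_element,
               distance = d, angle = a, line = lineno[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Total hydrogen-bond energy of a complex
#'
#' The interface energy of a candidate complex is the sum of its individual
#' bond energies; an empty bond list gives 0.
#'
#' @param bonds data.frame of geometry records (see [parse_hbond_records()]).
#' @param params an [hbond_params()].
#' @param design_id identifier carried through to ranking.
#' @return object of class `complex_energy`: list with `design_id`,
#'   `bond_energies` and `total_energy` (kcal/mol).
#' @export
complex_energy <- function(bonds, params = default_hbond_params(), design_id = NA_character_) {
  if (nrow(bonds) == 0L) {
    energies <- numeric(0)
  } else {
    energies <- vapply(seq_len(nrow(bonds)), function(i) {
      hbond_energy(bonds$donor_element[i], bonds$acceptor_element[i],
                   bonds$distance[i], bonds$angle[i], params)
    }, numeric(1L))
  }
  structure(list(design_id = design_id, bond_energies = energies,
                 total_energy = sum(energies)),
            class = "complex_energy")
}

#' Rank candidate complexes by total hydrogen-bond energy
#'
#' Ascending total energy: more negative means stronger predicted binding,
#' so the best candidate comes first.  The sort is stable, preserving input
#' order among equal energies.
#'
#' @param energies list of `complex_energy` objects.
#' @return data.frame with columns `design_id`, `total_energy`, `rank`.
#' @export
rank_designs <- function(energies) {
  if (length(energies) == 0L) abort_validation("rank_designs() needs at least one complex")
  ids <- vapply(energies, function(e) as.character(e$design_id), character(1L))
  tot <- vapply(energies, function(e) e$total_energy, numeric(1L))
  ord <- order(tot)  # radix sort: stable
  data.frame(design_id = ids[ord], total_energy = tot[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
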