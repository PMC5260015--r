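# Synthetic training data with the structure the method assumes.
#
# The real training labels come from docking-derived energetics: for each
# representative DNA target, the lowest-energy recognition helices from the
# enumerated library.  The generator stands in for that step with a
# deterministic recognition code.  Its modular component mirrors the
# canonical Cys2-His2 code, which is approximately base-wise: helix
# position -1 reads the 3' base of the finger's subsite, +3 the middle
# base and +6 the 5' base.  For each finger the generator draws a seeded
# per-base residue code at each key position (from the allowed-mutation
# sets, so every emitted helix is a library member) and composes the
# helix for a 3-mer from the three base codes.
#
# A coupling parameter in [0, 1] adds the qualitative signature of
# synergistic binding: with probability `coupling` a 3-mer's helix is
# context-dependent, keyed additionally on the first base of the
# neighbouring subsite, so identical subsites can receive different
# helices in different contexts.  The synergy surrogate provides label
# structure only; it makes no claim to emulate docking energetics.
#
# Finger-to-subsite orientation follows the canonical Zif-268 antiparallel
# convention by default: finger F1 binds the 3'-most 3 bp subsite.  The
# parallel reading is available via `orientation = "5prime"`.

ALL_TRIMERS <- function() {
  g <- expand.grid(b3 = DNA_ALPHABET, b2 = DNA_ALPHABET, b1 = DNA_ALPHABET,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# Subsite index (1..3, genomic order) bound by finger f under an orientation.
finger_subsite <- function(f, orientation = c("3prime", "5prime")) {
  orientation <- match.arg(orientation)
  if (orientation == "3prime") 4L - f else f
}

# Compose the helix a per-base code assigns to a 3-mer: template residues
# everywhere except the key positions, which read one subsite base each
# (-1 <- 3' base, +3 <- middle, +6 <- 5' base).
compose_helix <- function(template_chars, code, trimer) {
  b <- strsplit(trimer, "", fixed = TRUE)[[1L]]
  chars <- template_chars
  chars[HELIX_KEY_OFFSETS[["-1"]]] <- code[["-1"]][[b[3L]]]
  chars[HELIX_KEY_OFFSETS[["+3"]]] <- code[["+3"]][[b[2L]]]
  chars[HELIX_KEY_OFFSETS[["+6"]]] <- code[["+6"]][[b[1L]]]
  paste0(chars, collapse = "")
}

#' Build a deterministic recognition map
#'
#' Constructs the DNA-to-helix code the generator labels with.  For each
#' finger, a seeded base-wise code is drawn at the key helix positions
#' (-1, +3, +6) from the allowed-mutation sets; the helix assigned to a
#' 3 bp subsite composes those per-base residues onto the finger's
#' template, so every assigned helix belongs to the enumerated library.
#' With probability `coupling`, a (finger, 3-mer) entry is instead
#' context-dependent: it carries one independently drawn helix per first
#' base of the neighbouring subsite (finger f's neighbour is finger f+1;
#' finger 3's is finger 2).  `coupling = 0` gives a purely modular code in
#' which a finger's helix depends only on its own subsite.
#'
#' @param seed integer seed; same seed and coupling give an identical map.
#' @param coupling real in \[0, 1\].
#' @param table a [mutation_table()] of allowed residues per key position
#'   (default [default_mutation_table()]).
#' @param templates named character vector of the three template helices
#'   (default [zif268_template()]).
#' @param orientation finger-to-subsite convention; stored on the map.
#' @return object of class `recognition_map`.
#' @export
make_recognition_map <- function(seed = 1L, coupling = 0,
                                 table = default_mutation_table(),
                                 templates = zif268_template(),
                                 orientation = c("3prime", "5prime")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(coupling) || length(coupling) != 1L || is.na(coupling) ||
      coupling < 0 || coupling > 1) {
    abort_validation("coupling must be in [0, 1]")
  }
  if (!inherits(table, "mutation_table")) table <- mutation_table(table)
  if (length(templates) != 3L) abort_validation("need three template helices")
  trimers <- ALL_TRIMERS()
  keys <- c("-1", "+3", "+6")
  fingers <- with_seed(seed, {
    lapply(1:3, function(f) {
      template_chars <- strsplit(unclass(recognition_helix(templates[[f]])), "",
                                 fixed = TRUE)[[1L]]
      code <- lapply(keys, function(k) {
        res <- sample(table[[k]], 4L, replace = TRUE)
        names(res) <- DNA_ALPHABET
        as.list(res)
      })
      names(code) <- keys
      coupled <- runif(length(trimers)) < coupling
      names(coupled) <- trimers
      variants <- lapply(trimers, function(tri) {
        if (!coupled[[tri]]) return(NULL)
        # one independently drawn library helix per neighbouring first base
        v <- vapply(DNA_ALPHABET, function(nb) {
          chars <- template_chars
          for (k in keys) {
            chars[HELIX_KEY_OFFSETS[[k]]] <- sample(table[[k]], 1L)
          }
          paste0(chars, collapse = "")
        }, character(1L))
        v
      })
      names(variants) <- trimers
      list(template_chars = template_chars, code = code,
           coupled = coupled, variants = variants)
    })
  })
  structure(list(fingers = fingers, coupling = coupling, seed = as.integer(seed),
                 table = table, templates = templates, orientation = orientation),
            class = "recognition_map")
}

#' Label a DNA target under a recognition map
#'
#' @param map a [make_recognition_map()] result.
#' @param target a [dna_target()] or valid 9-mer.
#' @return the 21-residue [zfp_design()] the map assigns to the target.
#' @export
map_label <- function(map, target) {
  target <- dna_target(target)
  helices <- vapply(1:3, function(f) {
    fm <- map$fingers[[f]]
    sub <- subsite(target, finger_subsite(f, map$orientation))
    if (fm$coupled[[sub]]) {
      neighbour_f <- if (f < 3L) f + 1L else 2L
      nb <- substr(subsite(target, finger_subsite(neighbour_f, map$orientation)), 1L, 1L)
      unname(fm$variants[[sub]][[nb]])
    } else {
      compose_helix(fm$template_chars, fm$code, sub)
    }
  }, character(1L))
  zfp_design(helices[1L], helices[2L], helices[3L])
}

# Index (1..4^9) -> 9-mer over the lexicographic alphabet A<C<G<T.
index_to_9mer <- function(idx) {
  vapply(idx, function(i) {
    i <- i - 1
    digits <- integer(9L)
    for (p in 9:1) {
      digits[p] <- i %% 4
      i <- i %/% 4
    }
    paste0(DNA_ALPHABET[digits + 1L], collapse = "")
  }, character(1L))
}

#' Generate a synthetic training/testing dataset
#'
#' Draws `n` distinct DNA targets, labels each through the recognition map,
#' then independently corrupts each key-position residue (-1, +3, +6 of
#' every helix) with probability `noise_rate`, replacing it by a different
#' residue drawn uniformly from the allowed set at that position (a
#' singleton allowed set leaves nothing to corrupt to, so the residue is
#' unchanged).  Non-key positions are template-fixed and never corrupted.
#' The first 80% of pairs form the training split and the rest the test
#' split, mirroring the published 40/10 design at n = 50.
#'
#' @param map a [make_recognition_map()].
#' @param n number of pairs (default 50; must not exceed 4^9).
#' @param noise_rate per-key-residue corruption probability in \[0, 1\].
#' @param seed integer seed.
#' @param targets optional character vector of `n` distinct targets (e.g. a
#'   [kmeans_representatives()] set); default: uniform draw without
#'   replacement from the full 4^9 space.
#' @return object of class `synthetic_dataset`: list with `pairs`
#'   (data.frame `dna`, `protein`), `train_idx`, `test_idx`, `noise_rate`.
#' @export
generate_dataset <- function(map, n = 50L, noise_rate = 0, seed = 1L,
                             targets = NULL) {
  if (!inherits(map, "recognition_map")) abort_validation("map must be a recognition_map")
  if (n < 1L || n > 4^9) abort_validation("n must be in 1..4^9")
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate > 1) {
    abort_validation("noise_rate must be in [0, 1]")
  }
  n <- as.integer(n)
  key_sets <- lapply(names(HELIX_KEY_OFFSETS), function(k) map$table[[k]])
  with_seed(seed, {
    if (is.null(targets)) {
      targets <- index_to_9mer(sample.int(4^9, n))
    } else {
      if (length(targets) != n || anyDuplicated(targets)) {
        abort_validation("targets must be n distinct sequences")
      }
      targets <- vapply(targets, function(s) unclass(dna_target(s)), character(1L),
                        USE.NAMES = FALSE)
    }
    labels <- vapply(targets, function(t) unclass(map_label(map, t)), character(1L),
                     USE.NAMES = FALSE)
    if (noise_rate > 0) {
      labels <- vapply(seq_along(labels), function(i) {
        chars <- strsplit(labels[i], "", fixed = TRUE)[[1L]]
        for (f in 1:3) {
          for (ko in seq_along(HELIX_KEY_OFFSETS)) {
            pos <- (f - 1L) * 7L + HELIX_KEY_OFFSETS[[ko]]
            if (runif(1L) < noise_rate) {
              alternatives <- setdiff(key_sets[[ko]], chars[pos])
              if (length(alternatives) > 0L) {
                chars[pos] <- sample(alternatives, 1L)
              }
            }
          }
        }
        paste0(chars, collapse = "")
      }, character(1L))
    }
  })
  n_test <- max(1L, round(n / 5))
  n_train <- n - n_test
  structure(list(pairs = data.frame(dna = targets, protein = labels,
                                    stringsAsFactors = FALSE),
                 train_idx = seq_len(n_train),
                 test_idx = seq.int(n_train + 1L, n),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' Training split of a synthetic dataset
#' @param dataset a `synthetic_dataset`.
#' @return data.frame of training pairs.
#' @export
train_pairs <- function(dataset) dataset$pairs[dataset$train_idx, , drop = FALSE]

#' Test split of a synthetic dataset
#' @param dataset a `synthetic_dataset`.
#' @return data.frame of held-out pairs.
#' @export
test_pairs <- function(dataset) dataset$pairs[dataset$test_idx, , drop = FALSE]
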