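# Shared helpers for building small in-code fixtures.

random_9mer <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), 9L, replace = TRUE), collapse = "")
  }, character(1L))
}

random_design <- function(n = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  vapply(seq_len(n), function(i) {
    paste0(sample(aa, 21L, replace = TRUE), collapse = "")
  }, character(1L))
}

# A micro_net with externally chosen weights (for tally oracles).
frozen_net <- function(w1, w2) {
  structure(list(w1 = w1, w2 = w2, hidden_size = nrow(w1), seed = NA_integer_),
            class = "micro_net")
}

# An ensemble wrapper around a list of nets.
frozen_ensemble <- function(nets) {
  structure(list(nets = nets,
                 config = ensemble_config(n_nets = length(nets))),
            class = "zifnn_ensemble")
}

# A tiny noise-free synthetic training set shared by ensemble tests.
toy_dataset <- function(seed = 5L, n = 12L) {
  map <- make_recognition_map(seed = seed, coupling = 0)
  generate_dataset(map, n = n, noise_rate = 0, seed = seed)
}

# Positions (1..21) of the key residues -1/+3/+6 across the three helices.
key_positions <- function() as.vector(outer(c(1L, 4L, 7L), (0:2) * 7L, "+"))
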