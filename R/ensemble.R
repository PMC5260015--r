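# Ensemble of micro neural networks.
#
# A micro neural network (muNN) is a single-hidden-layer feed-forward net
# whose hidden size (28..52) is an order of magnitude smaller than its
# 420-dimensional output.  Input is the one-hot 9 bp target (36 values plus
# a constant-1 bias entry); both layers apply LayerOperation(X) =
# Sigmoid(W.X).  Training minimises the squared (L2) output error by
# per-sample stochastic gradient descent, with the training order
# reshuffled every epoch.
#
# One hundred such nets with different hidden architectures are trained on
# the same data; each decodes its output to a 21-residue design, and the
# per-position tallies over nets form a 21 x 20 vote matrix.  The consensus
# design takes the plurality residue at every position.  The confidence of
# any candidate design with total vote count s is scored exp(-0.01 * s):
# smaller score = more votes = higher confidence.

#' Ensemble configuration
#'
#' @param n_nets number of micro networks (default 100).
#' @param hidden_range inclusive integer range for hidden-layer sizes,
#'   default `c(28, 52)`; must lie within \[1, 419\].
#' @param epochs passes over the training set per net (default 150).
#' @param learning_rate SGD step size (default 0.5, suited to the
#'   sigmoid + squared-error scale of the one-hot targets).
#' @param seed master seed; net i trains under `seed + i` so results are
#'   independent of training order.
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(n_nets = 100L, hidden_range = c(28L, 52L),
                            epochs = 150L, learning_rate = 0.5, seed = 1L) {
  if (n_nets < 1L) abort_validation("n_nets must be >= 1")
  if (length(hidden_range) != 2L || hidden_range[1L] > hidden_range[2L] ||
      hidden_range[1L] < 1L || hidden_range[2L] >= 420L) {
    abort_validation("hidden_range must be [lo, hi] with 1 <= lo <= hi < 420")
  }
  if (epochs < 1L) abort_validation("epochs must be >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    abort_validation("learning_rate must be positive")
  }
  structure(list(n_nets = as.integer(n_nets),
                 hidden_range = as.integer(hidden_range),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Encode training pairs into network input/target matrices
#'
#' @param pairs data.frame with columns `dna` (9-mers) and `protein`
#'   (21-mers), as from [read_training_pairs()] or [generate_dataset()].
#' @return list with `X` (n x 36) and `Y` (n x 420) one-hot matrices.
#' @export
encode_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("dna", "protein") %in% names(pairs)) ||
      nrow(pairs) == 0L) {
    abort_validation("pairs must be a nonempty data.frame with columns dna, protein")
  }
  X <- t(vapply(pairs$dna, encode_dna, numeric(36L)))
  Y <- t(vapply(pairs$protein, encode_protein, numeric(420L)))
  dimnames(X) <- NULL
  dimnames(Y) <- NULL
  list(X = X, Y = Y)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass through one net; returns hidden activations and output so the
# gradient can reuse them.  Bias is a constant-1 column appended to each
# layer's input, preserving the plain Sigmoid(W.X) layer form.
net_forward_full <- function(w1, w2, x) {
  h <- sigmoid(drop(w1 %*% c(x, 1)))
  y <- sigmoid(drop(w2 %*% c(h, 1)))
  list(hidden = h, output = y)
}

#' Forward pass of a micro network
#'
#' @param net a `micro_net`.
#' @param x numeric input of length 36 (one-hot DNA).
#' @return numeric output of length 420, all entries in (0, 1).
#' @export
net_forward <- function(net, x) {
  if (length(x) != ncol(net$w1) - 1L) {
    abort_validation(sprintf("input length %d does not match net input size %d",
                             length(x), ncol(net$w1) - 1L))
  }
  net_forward_full(net$w1, net$w2, x)$output
}

# Squared-error loss of one sample (used by the finite-difference oracle).
net_loss <- function(w1, w2, x, target) {
  y <- net_forward_full(w1, w2, x)$output
  sum((y - target)^2)
}

# Exact backpropagation gradients of net_loss w.r.t. w1 and w2.
net_gradient <- function(w1, w2, x, target) {
  fw <- net_forward_full(w1, w2, x)
  h <- fw$hidden
  y <- fw$output
  nh <- length(h)
  d2 <- 2 * (y - target) * y * (1 - y)
  g2 <- tcrossprod(d2, c(h, 1))
  d1 <- drop(crossprod(w2[, seq_len(nh), drop = FALSE], d2)) * h * (1 - h)
  g1 <- tcrossprod(d1, c(x, 1))
  list(g1 = g1, g2 = g2)
}

#' Train a single micro network
#'
#' Runs `epochs` passes of per-sample stochastic gradient descent on the
#' squared output error, reshuffling the sample order each epoch under the
#' seeded generator.  Weights initialise uniformly in \[-0.5, 0.5\].
#'
#' @param data list with matrices `X` (n x 36) and `Y` (n x 420); see
#'   [encode_pairs()].
#' @param hidden_size hidden-layer width.
#' @param epochs,learning_rate,seed training hyperparameters.
#' @return object of class `micro_net`: list with `w1`
#'   (hidden_size x 37), `w2` (420 x hidden_size+1), `hidden_size`, `seed`.
#' @export
train_micro_net <- function(data, hidden_size, epochs = 150L,
                            learning_rate = 0.5, seed = 1L) {
  X <- data$X
  Y <- data$Y
  if (is.null(X) || is.null(Y) || !is.matrix(X) || !is.matrix(Y) ||
      nrow(X) == 0L || nrow(X) != nrow(Y)) {
    abort_validation("training data must contain matched nonempty matrices X and Y")
  }
  n <- nrow(X)
  n_in <- ncol(X)
  n_out <- ncol(Y)
  hidden_size <- as.integer(hidden_size)
  if (hidden_size < 1L) abort_validation("hidden_size must be >= 1")
  with_seed(seed, {
    w1 <- matrix(runif(hidden_size * (n_in + 1L), -0.5, 0.5), hidden_size, n_in + 1L)
    w2 <- matrix(runif(n_out * (hidden_size + 1L), -0.5, 0.5), n_out, hidden_size + 1L)
    hseq <- seq_len(hidden_size)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        x <- c(X[i, ], 1)
        h <- sigmoid(drop(w1 %*% x))
        hb <- c(h, 1)
        y <- sigmoid(drop(w2 %*% hb))
        d2 <- 2 * (y - Y[i, ]) * y * (1 - y)
        d1 <- drop(crossprod(w2[, hseq, drop = FALSE], d2)) * h * (1 - h)
        w2 <- w2 - learning_rate * tcrossprod(d2, hb)
        w1 <- w1 - learning_rate * tcrossprod(d1, x)
      }
    }
  })
  structure(list(w1 = w1, w2 = w2, hidden_size = hidden_size, seed = as.integer(seed)),
            class = "micro_net")
}

#' Train the full ensemble
#'
#' Draws `n_nets` hidden sizes uniformly from `hidden_range` under the
#' master seed, then trains net i under seed `config$seed + i`.  Because
#' each net owns a derived RNG stream, training is embarrassingly parallel
#' and the result is independent of training order.
#'
#' @param data list with `X`, `Y` (see [encode_pairs()]), or a pairs
#'   data.frame with columns `dna`, `protein`.
#' @param config an [ensemble_config()].
#' @return object of class `zifnn_ensemble`: list with `nets` and `config`.
#' @export
train_ensemble <- function(data, config = ensemble_config()) {
  if (is.data.frame(data)) data <- encode_pairs(data)
  sizes <- with_seed(config$seed, {
    vals <- config$hidden_range[1L]:config$hidden_range[2L]
    vals[sample.int(length(vals), config$n_nets, replace = TRUE)]
  })
  nets <- lapply(seq_len(config$n_nets), function(i) {
    train_micro_net(data, hidden_size = sizes[i], epochs = config$epochs,
                    learning_rate = config$learning_rate,
                    seed = config$seed + i)
  })
  structure(list(nets = nets, config = config), class = "zifnn_ensemble")
}

#' Position-wise vote matrix for a DNA target
#'
#' Runs every net of the ensemble on the encoded target, decodes each
#' 420-dimensional output by per-20-block argmax, and tallies the votes:
#' `counts[p, a]` is the number of nets predicting residue `a` at position
#' `p`.  Every row sums to the number of nets.
#'
#' @param model a `zifnn_ensemble`.
#' @param target a [dna_target()] or valid 9-mer string.
#' @return 21 x 20 integer matrix with residue column names.
#' @export
vote_matrix <- function(model, target) {
  x <- encode_dna(target)
  counts <- matrix(0L, nrow = 21L, ncol = 20L,
                   dimnames = list(NULL, AA_CODE))
  for (net in model$nets) {
    y <- net_forward(net, x)
    picks <- apply(matrix(y, nrow = 20L), 2L, which.max)
    counts[cbind(seq_len(21L), picks)] <- counts[cbind(seq_len(21L), picks)] + 1L
  }
  counts
}

score_from_votes <- function(s) exp(-0.01 * s)

#' Consensus prediction from a vote matrix
#'
#' Takes the plurality residue at every position (lowest alphabetical index
#' on ties).  The vote total s of the consensus design is the per-position
#' maximum summed over positions, hence maximal over all candidate designs;
#' its confidence score is exp(-0.01 * s).
#'
#' @param votes vote matrix from [vote_matrix()] (positions x residues).
#' @return object of class `zifnn_prediction`: list with `design`
#'   (21-residue string), `s` (integer vote total) and `score`.
#' @export
consensus_prediction <- function(votes) {
  picks <- apply(votes, 1L, which.max)
  s <- sum(votes[cbind(seq_len(nrow(votes)), picks)])
  design <- paste0(colnames(votes)[picks], collapse = "")
  structure(list(design = design, s = as.integer(s), score = score_from_votes(s)),
            class = "zifnn_prediction")
}

#' @export
print.zifnn_prediction <- function(x, ...) {
  cat(sprintf("ZFP prediction: %s  (votes s = %d, score = %.3g)\n",
              x$design, x$s, x$score))
  invisible(x)
}

#' Exact top-k predictions by best-first vote decoding
#'
#' Positions are scored independently, so the k candidates with the largest
#' vote totals can be enumerated exactly: starting from the per-position
#' argmax, a best-first search expands one position at a time to the
#' next-most-voted residue.  Results come in ascending score (descending
#' vote total s); exact ties in s order lexicographically by design string.
#' If k exceeds the number of distinct candidates, all candidates are
#' returned with attribute `truncated = TRUE` and a warning.
#'
#' @param votes vote matrix (positions x residues, residue column names);
#'   21 x 20 for a full design, but any shape works (used by tests with toy
#'   matrices).
#' @param k number of predictions (the published tool reports 10).
#' @return list of `zifnn_prediction` objects.
#' @export
top_k_predictions <- function(votes, k = 10L) {
  if (k < 1L) abort_validation("k must be >= 1")
  P <- nrow(votes)
  A <- ncol(votes)
  letters_ <- colnames(votes)
  if (is.null(letters_)) abort_validation("vote matrix must have residue column names")
  # Per position: residue order by descending votes, alphabetical on ties.
  ord <- lapply(seq_len(P), function(p) order(-votes[p, ], letters_))
  sorted_votes <- lapply(seq_len(P), function(p) votes[p, ord[[p]]])
  design_of <- function(choice) {
    paste0(vapply(seq_len(P), function(p) letters_[ord[[p]][choice[p]]],
                  character(1L)), collapse = "")
  }
  s_of <- function(choice) {
    sum(vapply(seq_len(P), function(p) sorted_votes[[p]][choice[p]], numeric(1L)))
  }
  n_candidates <- A^P  # may overflow to Inf for real sizes; comparison still works
  truncated <- FALSE
  if (is.finite(n_candidates) && k > n_candidates) {
    warning(sprintf("k = %d exceeds the %d distinct candidates; returning all", k, n_candidates))
    k <- as.integer(n_candidates)
    truncated <- TRUE
  }
  root <- rep(1L, P)
  frontier <- list(list(choice = root, s = s_of(root), design = design_of(root)))
  visited <- new.env(parent = emptyenv())
  assign(design_of(root), TRUE, envir = visited)
  results <- vector("list", k)
  for (r in seq_len(k)) {
    ss <- vapply(frontier, function(e) e$s, numeric(1L))
    ds <- vapply(frontier, function(e) e$design, character(1L))
    best <- order(-ss, ds)[1L]
    node <- frontier[[best]]
    frontier <- frontier[-best]
    results[[r]] <- structure(
      list(design = node$design, s = as.integer(node$s),
           score = score_from_votes(node$s)),
      class = "zifnn_prediction")
    for (p in seq_len(P)) {
      if (node$choice[p] < A) {
        child <- node$choice
        child[p] <- child[p] + 1L
        d <- design_of(child)
        if (!exists(d, envir = visited, inherits = FALSE)) {
          assign(d, TRUE, envir = visited)
          frontier <- c(frontier, list(list(choice = child, s = s_of(child), design = d)))
        }
      }
    }
    if (length(frontier) == 0L && r < k) {
      results <- results[seq_len(r)]
      truncated <- TRUE
      warning("candidate space exhausted before k predictions")
      break
    }
  }
  attr(results, "truncated") <- truncated
  results
}

#' Predict optimal ZFP designs for DNA targets
#'
#' Runs the ensemble on each query target and reports the top `k` designs
#' by exact vote decoding.
#'
#' @param object a trained `zifnn_ensemble`.
#' @param targets character vector of 9-mers (named = query IDs).
#' @param k predictions per query (default 10).
#' @param ... unused.
#' @return data.frame with columns `query_id`, `target`, `rank`,
#'   `helix_F1`, `helix_F2`, `helix_F3`, `s`, `score`.
#' @export
predict.zifnn_ensemble <- function(object, targets, k = 10L, ...) {
  ids <- names(targets)
  if (is.null(ids)) ids <- paste0("query_", seq_along(targets))
  rows <- lapply(seq_along(targets), function(i) {
    votes <- vote_matrix(object, targets[[i]])
    preds <- top_k_predictions(votes, k)
    do.call(rbind, lapply(seq_along(preds), function(r) {
      h <- zfp_helices(preds[[r]]$design)
      data.frame(query_id = ids[i], target = unclass(dna_target(targets[[i]])),
                 rank = r, helix_F1 = h[["F1"]], helix_F2 = h[["F2"]],
                 helix_F3 = h[["F3"]], s = preds[[r]]$s, score = preds[[r]]$score,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Persist a trained ensemble to a directory
#'
#' Writes one JSON metadata file (config, seeds, hidden sizes) plus per-net
#' weight matrices as plain TSV, so a reloaded model reproduces identical
#' vote matrices on any platform.
#'
#' @param model a `zifnn_ensemble`.
#' @param dir output directory (created if needed).
#' @export
write_ensemble <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config = unclass(model$config),
               n_nets = length(model$nets),
               hidden_sizes = vapply(model$nets, function(n) n$hidden_size, integer(1L)),
               net_seeds = vapply(model$nets, function(n) n$seed, integer(1L)))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(model$nets)) {
    utils::write.table(model$nets[[i]]$w1, file.path(dir, sprintf("net_%03d_w1.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(model$nets[[i]]$w2, file.path(dir, sprintf("net_%03d_w2.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Load an ensemble written by [write_ensemble()]
#'
#' @param dir model directory.
#' @return a `zifnn_ensemble`.
#' @export
read_ensemble <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) abort_validation(sprintf("no model.json in %s", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- do.call(ensemble_config, meta$config)
  nets <- lapply(seq_len(meta$n_nets), function(i) {
    w1 <- as.matrix(utils::read.delim(file.path(dir, sprintf("net_%03d_w1.tsv", i)),
                                      header = FALSE))
    w2 <- as.matrix(utils::read.delim(file.path(dir, sprintf("net_%03d_w2.tsv", i)),
                                      header = FALSE))
    dimnames(w1) <- NULL
    dimnames(w2) <- NULL
    structure(list(w1 = w1, w2 = w2, hidden_size = meta$hidden_sizes[i],
                   seed = meta$net_seeds[i]),
              class = "micro_net")
  })
  structure(list(nets = nets, config = cfg), class = "zifnn_ensemble")
}
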