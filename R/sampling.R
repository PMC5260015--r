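# Representative sampling of the DNA target space.
#
# The space of all 9 bp targets (4^9 = 262,144 sequences) is far too large
# to model structurally one by one, so a small representative subset is
# chosen by K-means clustering of the one-hot encoded sequences (Euclidean
# distance on one-hot vectors is a monotone function of Hamming distance).
# The published design used K = 50.  Each cluster is reported through its
# medoid - the actual population sequence nearest the centroid - so the
# representatives are always real sequences.

#' Enumerate all DNA k-mers of a given length
#'
#' @param length k-mer length, 1..9 (the cap guards against memory blowup;
#'   4^9 = 262,144 is the largest population used).
#' @return character vector of all `4^length` k-mers in lexicographic order
#'   over A < C < G < T.
#' @examples
#' enumerate_population(1)
#' @export
enumerate_population <- function(length) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1L || length > 9L || length != as.integer(length)) {
    abort_validation("`length` must be an integer in 1..9")
  }
  length <- as.integer(length)
  g <- do.call(expand.grid,
               c(rep(list(DNA_ALPHABET), length),
                 list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  # expand.grid varies the first column fastest; for lexicographic order the
  # *last* character must vary fastest, so columns are pasted in reverse.
  do.call(paste0, g[, rev(seq_len(length)), drop = FALSE])
}

# One-hot encode a character vector of equal-length DNA sequences into an
# N x 4L matrix (blocks ordered A,T,G,C to match encode_dna()).
one_hot_matrix <- function(seqs) {
  L <- nchar(seqs[1L])
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  X <- matrix(0, nrow = n, ncol = 4L * L)
  for (p in seq_len(L)) {
    idx <- match(chars[, p], DNA_CODE)
    if (anyNA(idx)) abort_validation("sequences must be over A,C,G,T")
    X[cbind(seq_len(n), 4L * (p - 1L) + idx)] <- 1
  }
  X
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance from the nearest chosen one.
# Consumes the current RNG stream.
kmeans_pp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    xsq <- rowSums(X^2)
    d2 <- xsq + sum(X[centers[1L], ]^2) - 2 * drop(X %*% X[centers[1L], ])
    d2 <- pmax(d2, 0)
    for (j in 2L:k) {
      if (all(d2 == 0)) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2)
      }
      dj <- xsq + sum(X[centers[j], ]^2) - 2 * drop(X %*% X[centers[j], ])
      d2 <- pmin(d2, pmax(dj, 0))
    }
  }
  X[centers, , drop = FALSE]
}

# One seeded Lloyd run.  Assignment step via argmin ||x-c||^2 computed as
# ||c||^2 - 2 x.c (||x||^2 is constant per point and drops out); ties to the
# lowest cluster index.  An emptied cluster is re-seeded from the point
# farthest from its assigned centroid.  Returns assignments, centroids and
# the within-cluster sum of squares.
lloyd_run <- function(X, k, max_iter) {
  n <- nrow(X)
  C <- kmeans_pp_init(X, k)
  xsq <- rowSums(X^2)
  assign_prev <- integer(0)
  for (iter in seq_len(max_iter)) {
    G <- X %*% t(C)                       # n x k inner products
    obj <- sweep(-2 * G, 2L, rowSums(C^2), "+")
    a <- max.col(-obj, ties.method = "first")
    d2 <- xsq + obj[cbind(seq_len(n), a)]
    empty <- setdiff(seq_len(k), unique(a))
    if (length(empty) > 0L) {
      for (j in empty) {
        far <- which.max(d2)
        C[j, ] <- X[far, ]
        a[far] <- j
        d2[far] <- 0
      }
    }
    if (identical(a, assign_prev)) break
    assign_prev <- a
    sz <- tabulate(a, nbins = k)
    C <- rowsum(X, a, reorder = TRUE) / sz
  }
  G <- X %*% t(C)
  obj <- sweep(-2 * G, 2L, rowSums(C^2), "+")
  a <- max.col(-obj, ties.method = "first")
  d2 <- pmax(xsq + obj[cbind(seq_len(n), a)], 0)
  list(assignments = a, centers = C, inertia = sum(d2), point_d2 = d2)
}

#' Select representative DNA sequences by K-means clustering
#'
#' Clusters the one-hot encodings of `population` with seeded k-means++
#' initialisation and Lloyd iteration, then snaps each centroid to its
#' cluster medoid (nearest actual sequence; ties broken lexicographically),
#' so every representative is a member of the population.  With `n_init > 1`
#' the run with the lowest within-cluster sum of squares wins.
#'
#' @param population character vector of equal-length DNA sequences.
#' @param k number of clusters (the published design used 50).
#' @param seed integer seed; the same seed gives byte-identical output.
#' @param max_iter maximum Lloyd iterations per start (default 300).
#' @param n_init number of independent seeded starts (default 10).
#' @return object of class `representative_set`: list with `sequences`
#'   (k distinct population members), `cluster_sizes` (summing to the
#'   population size), `inertia`, and `k`.
#' @export
kmeans_representatives <- function(population, k, seed = 1L,
                                   max_iter = 300L, n_init = 10L) {
  if (length(population) == 0L) abort_validation("population must be nonempty")
  if (anyDuplicated(population)) abort_validation("population must not contain duplicates")
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k != as.integer(k)) {
    abort_validation("`k` must be a positive integer")
  }
  k <- as.integer(k)
  if (k > length(population)) {
    abort_validation(sprintf("k = %d exceeds population size %d", k, length(population)))
  }
  X <- one_hot_matrix(population)
  best <- NULL
  with_seed(seed, {
    for (run in seq_len(n_init)) {
      res <- lloyd_run(X, k, max_iter)
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
  })
  # Medoid snap: nearest member per cluster, lexicographically smallest on ties.
  reps <- character(k)
  sizes <- integer(k)
  for (j in seq_len(k)) {
    members <- which(best$assignments == j)
    sizes[j] <- length(members)
    d2 <- best$point_d2[members]
    cand <- members[d2 == min(d2)]
    reps[j] <- min(population[cand])
  }
  structure(list(sequences = reps, cluster_sizes = sizes,
                 inertia = best$inertia, k = k),
            class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("Representative set: %d sequences from a population of %d\n",
              x$k, sum(x$cluster_sizes)))
  cat(sprintf("  within-cluster sum of squares: %.3f\n", x$inertia))
  cat("  first representatives:", paste(head(x$sequences, 5L), collapse = ", "), "\n")
  invisible(x)
}
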