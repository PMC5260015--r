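test_that("a micro network memorises a single training pair", {
  pairs <- data.frame(dna = "GCTGGGAAA", protein = "QSGNLTRRSGHLTRRSGELTR",
                      stringsAsFactors = FALSE)
  data <- encode_pairs(pairs)
  net <- train_micro_net(data, hidden_size = 10L, epochs = 500L,
                         learning_rate = 0.5, seed = 2L)
  out <- decode_protein(net_forward(net, data$X[1L, ]))
  expect_identical(unclass(out), pairs$protein)
})

test_that("training is deterministic under a seed", {
  ds <- toy_dataset(seed = 5L, n = 6L)
  data <- encode_pairs(ds$pairs)
  a <- train_micro_net(data, 8L, epochs = 10L, seed = 33L)
  b <- train_micro_net(data, 8L, epochs = 10L, seed = 33L)
  expect_identical(a, b)
  c <- train_micro_net(data, 8L, epochs = 10L, seed = 34L)
  expect_false(identical(a$w1, c$w1))
})

test_that("a four-pair toy mapping is learned exactly after convergence", {
  pairs <- data.frame(
    dna = c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG", "TTTTTTTTT"),
    protein = c("QSGNLTRRSGHLTRRSGELTR", "DSGHLTRDSGHLTRDSGHLTR",
                "TSGELTETSGELTETSGELTE", "RSGDLTTRSGDLTTRSGDLTT"),
    stringsAsFactors = FALSE)
  data <- encode_pairs(pairs)
  net <- train_micro_net(data, hidden_size = 12L, epochs = 800L,
                         learning_rate = 0.5, seed = 4L)
  for (i in 1:4) {
    expect_identical(unclass(decode_protein(net_forward(net, data$X[i, ]))),
                     pairs$protein[i])
  }
})

test_that("backpropagation gradients match central finite differences", {
  set.seed(99)
  h <- 6L
  w1 <- matrix(runif(h * 37L, -0.5, 0.5), h, 37L)
  w2 <- matrix(runif(420L * (h + 1L), -0.5, 0.5), 420L, h + 1L)
  x <- encode_dna(random_9mer())
  target <- encode_protein(random_design())
  g <- zifnn:::net_gradient(w1, w2, x, target)
  eps <- 1e-5
  rel_err <- function(analytic, numeric_) {
    abs(analytic - numeric_) / pmax(abs(analytic) + abs(numeric_), 1e-8)
  }
  # check every w1 entry and a random sample of w2 entries
  errs <- c()
  for (idx in seq_along(w1)) {
    wp <- w1; wp[idx] <- wp[idx] + eps
    wm <- w1; wm[idx] <- wm[idx] - eps
    fd <- (zifnn:::net_loss(wp, w2, x, target) -
           zifnn:::net_loss(wm, w2, x, target)) / (2 * eps)
    if (abs(fd) + abs(g$g1[idx]) > 1e-7) errs <- c(errs, rel_err(g$g1[idx], fd))
  }
  for (idx in sample(length(w2), 400L)) {
    wp <- w2; wp[idx] <- wp[idx] + eps
    wm <- w2; wm[idx] <- wm[idx] - eps
    fd <- (zifnn:::net_loss(w1, wp, x, target) -
           zifnn:::net_loss(w1, wm, x, target)) / (2 * eps)
    if (abs(fd) + abs(g$g2[idx]) > 1e-7) errs <- c(errs, rel_err(g$g2[idx], fd))
  }
  expect_gt(length(errs), 100L)
  expect_lt(max(errs), 1e-4)
})

test_that("ensemble hidden sizes respect the configured range and reduce to one net", {
  ds <- toy_dataset(seed = 5L, n = 6L)
  cfg <- ensemble_config(n_nets = 12L, epochs = 3L, seed = 21L)
  model <- train_ensemble(ds$pairs, cfg)
  sizes <- vapply(model$nets, function(n) n$hidden_size, integer(1L))
  expect_true(all(sizes >= 28L & sizes <= 52L))

  cfg1 <- ensemble_config(n_nets = 1L, hidden_range = c(9L, 9L), epochs = 5L, seed = 21L)
  single <- train_ensemble(ds$pairs, cfg1)
  direct <- train_micro_net(encode_pairs(ds$pairs), 9L, epochs = 5L,
                            learning_rate = cfg1$learning_rate, seed = 22L)  # seed + index
  expect_identical(single$nets[[1L]]$w1, direct$w1)
  expect_identical(single$nets[[1L]]$w2, direct$w2)
})

test_that("same config seed gives identical vote matrices across runs", {
  ds <- toy_dataset(seed = 6L, n = 6L)
  cfg <- ensemble_config(n_nets = 5L, epochs = 3L, seed = 77L)
  m1 <- train_ensemble(ds$pairs, cfg)
  m2 <- train_ensemble(ds$pairs, cfg)
  q <- random_9mer()
  expect_identical(vote_matrix(m1, q), vote_matrix(m2, q))
})

test_that("vote matrices conserve votes and match a brute-force tally", {
  ds <- toy_dataset(seed = 6L, n = 6L)
  cfg <- ensemble_config(n_nets = 7L, epochs = 3L, seed = 15L)
  model <- train_ensemble(ds$pairs, cfg)
  v <- vote_matrix(model, ds$pairs$dna[1L])
  expect_identical(dim(v), c(21L, 20L))
  expect_true(all(rowSums(v) == 7L))

  single <- train_ensemble(ds$pairs, ensemble_config(n_nets = 1L, epochs = 3L, seed = 3L))
  v1 <- vote_matrix(single, ds$pairs$dna[1L])
  expect_true(all(v1 %in% c(0L, 1L)))
  expect_true(all(rowSums(v1) == 1L))

  # frozen 3-net ensemble: tally each net's decoded design by hand
  set.seed(31)
  nets <- lapply(1:3, function(i) {
    frozen_net(matrix(runif(5 * 37, -1, 1), 5, 37),
               matrix(runif(420 * 6, -1, 1), 420, 6))
  })
  ens <- frozen_ensemble(nets)
  q <- "GATTACAGA"
  v <- vote_matrix(ens, q)
  oracle <- matrix(0L, 21L, 20L, dimnames = list(NULL, zifnn:::AA_CODE))
  for (net in nets) {
    d <- strsplit(unclass(decode_protein(net_forward(net, encode_dna(q)))), "")[[1L]]
    for (p in 1:21) oracle[p, d[p]] <- oracle[p, d[p]] + 1L
  }
  expect_identical(v, oracle)
})

test_that("consensus takes the per-position plurality and scores exp(-0.01 s)", {
  # unanimous 100-net matrix: s = 21 * 100, score = e^-21
  v <- matrix(0L, 21L, 20L, dimnames = list(NULL, zifnn:::AA_CODE))
  v[, "R"] <- 100L
  cons <- consensus_prediction(v)
  expect_identical(cons$design, strrep("R", 21L))
  expect_identical(cons$s, 2100L)
  expect_equal(cons$score, exp(-21))
  expect_equal(exp(-0.01 * 0), 1)  # score formula upper bound at s = 0

  # consensus s is maximal over a brute-force candidate sweep
  set.seed(12)
  v <- matrix(rbinom(21L * 20L, 10L, 0.3), 21L, 20L,
              dimnames = list(NULL, zifnn:::AA_CODE))
  cons <- consensus_prediction(v)
  for (rep in 1:200) {
    cand <- sample(20L, 21L, replace = TRUE)
    s <- sum(v[cbind(1:21, cand)])
    expect_lte(s, cons$s)
  }
})

test_that("top-k decoding equals brute-force enumeration on toy vote matrices", {
  # 3 positions x 2 residues, k = 4: all 8 candidates by hand
  v <- matrix(c(5L, 1L,
                3L, 3L,
                0L, 6L), nrow = 3L, byrow = TRUE,
              dimnames = list(NULL, c("A", "C")))
  got <- top_k_predictions(v, k = 4L)
  combos <- expand.grid(p1 = 1:2, p2 = 1:2, p3 = 1:2)
  brute <- data.frame(
    design = apply(combos, 1L, function(ch) paste0(c("A", "C")[ch], collapse = "")),
    s = apply(combos, 1L, function(ch) v[1, ch[1]] + v[2, ch[2]] + v[3, ch[3]]))
  brute <- brute[order(-brute$s, brute$design), ]
  expect_identical(vapply(got, `[[`, character(1L), "design"), brute$design[1:4])
  expect_identical(vapply(got, `[[`, integer(1L), "s"), as.integer(brute$s[1:4]))
  expect_equal(vapply(got, `[[`, numeric(1L), "score"), exp(-0.01 * brute$s[1:4]))

  # k = 1 equals the consensus
  expect_identical(top_k_predictions(v, 1L)[[1L]]$design, consensus_prediction(v)$design)

  # random 4x4 instance (256 candidates) against exhaustive enumeration
  set.seed(7)
  v4 <- matrix(sample(0:20, 16L, replace = TRUE), 4L, 4L,
               dimnames = list(NULL, c("A", "C", "D", "E")))
  got <- top_k_predictions(v4, k = 10L)
  combos <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  brute <- data.frame(
    design = apply(combos, 1L, function(ch) paste0(c("A", "C", "D", "E")[ch], collapse = "")),
    s = apply(combos, 1L, function(ch) sum(v4[cbind(1:4, ch)])))
  brute <- brute[order(-brute$s, brute$design), ]
  expect_identical(vapply(got, `[[`, character(1L), "design"), brute$design[1:10])
  expect_identical(vapply(got, `[[`, integer(1L), "s"), as.integer(brute$s[1:10]))

  # k beyond the candidate count returns everything, flagged
  expect_warning(all8 <- top_k_predictions(v, k = 50L), "distinct candidates")
  expect_length(all8, 8L)
  expect_true(attr(all8, "truncated"))
})

test_that("top-10 prediction output is well-formed with non-increasing vote totals", {
  ds <- toy_dataset(seed = 9L, n = 6L)
  model <- train_ensemble(ds$pairs, ensemble_config(n_nets = 4L, epochs = 3L, seed = 2L))
  preds <- predict(model, c(q1 = "GCTGCTGCT"), k = 10L)
  expect_identical(nrow(preds), 10L)
  expect_identical(preds$rank, 1:10)
  expect_true(all(diff(preds$s) <= 0))
  expect_true(all(diff(preds$score) >= 0))
  expect_true(all(nchar(paste0(preds$helix_F1, preds$helix_F2, preds$helix_F3)) == 21L))
})

test_that("a persisted ensemble reloads to identical vote matrices", {
  ds <- toy_dataset(seed = 3L, n = 5L)
  model <- train_ensemble(ds$pairs, ensemble_config(n_nets = 3L, epochs = 2L, seed = 8L))
  dir <- withr::local_tempdir()
  write_ensemble(model, dir)
  reloaded <- read_ensemble(dir)
  q <- random_9mer()
  expect_identical(vote_matrix(model, q), vote_matrix(reloaded, q))
})
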