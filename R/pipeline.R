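# Pipeline orchestration and command-line entry point.
#
# The design pipeline is: sample representative targets -> obtain training
# labels (here: simulate through the synthetic recognition code, or ingest
# a pairs TSV) -> train the ensemble -> predict top-k designs for query
# targets -> evaluate against known optima.  Every stochastic step draws
# from an explicit seed, and each run serialises its configuration next to
# its outputs, so reruns with the same config are byte-identical.
#
# The installed script `inst/cli/zifnn` is a thin Rscript wrapper around
# zifnn_cli(); exit codes: 0 success, 2 invalid input, 1 runtime error.

#' Run the full design pipeline
#'
#' @param config named list with entries:
#'   \describe{
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{master seed (default 1).}
#'     \item{n}{synthetic pairs to generate when no `pairs` file is given
#'       (default 50).}
#'     \item{noise_rate, coupling}{generator settings (defaults 0).}
#'     \item{pairs}{optional path to a training-pairs TSV; overrides the
#'       generator.}
#'     \item{queries}{optional FASTA/text of query targets; default: the
#'       dataset's held-out test targets.}
#'     \item{ensemble}{an [ensemble_config()]; default
#'       `ensemble_config(seed = seed)`.}
#'     \item{top_k}{predictions per query (default 10).}
#'   }
#' @return invisibly, a list with the trained model, the predictions
#'   data.frame, and (when truth is available) the comparison report.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) abort_validation("config$out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  top_k <- if (is.null(config$top_k)) 10L else as.integer(config$top_k)
  ens_cfg <- if (is.null(config$ensemble)) ensemble_config(seed = seed) else config$ensemble
  if (!is.null(config$pairs) && !file.exists(config$pairs)) {
    abort_validation(sprintf("pairs file not found: %s", config$pairs))
  }
  if (!is.null(config$queries) && !file.exists(config$queries)) {
    abort_validation(sprintf("query file not found: %s", config$queries))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  written <- character(0)
  on.exit(if (!ok) unlink(written), add = TRUE)

  truth <- NULL
  if (!is.null(config$pairs)) {
    train_df <- read_training_pairs(config$pairs)
  } else {
    noise <- if (is.null(config$noise_rate)) 0 else config$noise_rate
    coupling <- if (is.null(config$coupling)) 0 else config$coupling
    n <- if (is.null(config$n)) 50L else as.integer(config$n)
    map <- make_recognition_map(seed = seed, coupling = coupling)
    ds <- generate_dataset(map, n = n, noise_rate = noise, seed = seed)
    train_df <- train_pairs(ds)
    truth <- test_pairs(ds)
    p <- file.path(config$out_dir, "pairs.tsv")
    write_training_pairs(ds$pairs, p,
                         comment = sprintf("zifnn synthetic pairs; seed=%d noise=%g coupling=%g",
                                           seed, noise, coupling))
    written <- c(written, p)
  }

  model <- train_ensemble(train_df, ens_cfg)
  model_dir <- file.path(config$out_dir, "model")
  write_ensemble(model, model_dir)
  written <- c(written, model_dir)

  if (!is.null(config$queries)) {
    queries <- read_targets(config$queries)
  } else if (!is.null(truth)) {
    queries <- truth$dna
    names(queries) <- paste0("test_", seq_along(queries))
  } else {
    queries <- train_df$dna
    names(queries) <- paste0("train_", seq_along(queries))
  }
  preds <- predict(model, queries, k = top_k)
  pred_path <- file.path(config$out_dir, "predictions.tsv")
  write_tsv(preds, pred_path,
            comment = sprintf("zifnn predictions; seed=%d top_k=%d", seed, top_k))
  written <- c(written, pred_path)

  report <- NULL
  if (!is.null(truth)) {
    best <- preds[preds$rank == 1L, , drop = FALSE]
    rows <- data.frame(target = truth$dna, experimental = truth$protein,
                       predicted = paste0(best$helix_F1, best$helix_F2, best$helix_F3)
                       [match(truth$dna, best$target)],
                       stringsAsFactors = FALSE)
    report <- build_report(rows)
    rep_path <- file.path(config$out_dir, "report.tsv")
    write_tsv(report$rows, rep_path,
              comment = sprintf("zifnn evaluation; average_identity=%.4f coverage=%.4f",
                                report$average_identity, report$coverage))
    written <- c(written, rep_path)
  }

  cfg_out <- list(seed = seed, top_k = top_k, ensemble = unclass(ens_cfg),
                  n = config$n, noise_rate = config$noise_rate,
                  coupling = config$coupling,
                  version = as.character(utils::packageVersion("zifnn")))
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(list(model = model, predictions = preds, report = report))
}

# --- minimal flag parser: --key value pairs after the subcommand ----------
parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort_validation(sprintf("unexpected argument '%s'", a))
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flag_int <- function(flags, key, default) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.integer(flags[[key]]))
  if (is.na(v)) abort_validation(sprintf("--%s must be an integer", key))
  v
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(v)) abort_validation(sprintf("--%s must be a number", key))
  v
}

cli_usage <- function() {
  cat("usage: zifnn <subcommand> [--flag value ...]\n",
      "subcommands:\n",
      "  sample    --k 50 --seed 1 --out reps.fasta [--length 9] [--n-init 10] [--sizes sizes.tsv]\n",
      "  helices   [--table table.yml] [--finger F1|F2|F3] [--count] [--out helices.txt]\n",
      "  energy    --bonds bonds.tsv [--out energies.tsv]\n",
      "  rank      --energies totals.tsv --out ranked.tsv\n",
      "  simulate  --n 50 --noise 0 --coupling 0 --seed 1 --out pairs.tsv\n",
      "  train     --data pairs.tsv --out model_dir [--nets 100] [--epochs 150] [--seed 1]\n",
      "  predict   --model model_dir --query targets.fasta [--top 10] --out predictions.tsv\n",
      "  evaluate  --pred predictions.tsv --truth truth.tsv --out report.tsv\n",
      "  pipeline  --out dir [--seed 1] [--n 50] [--noise 0] [--coupling 0] [--pairs pairs.tsv]\n",
      sep = "")
}

#' Command-line entry point
#'
#' Dispatches the subcommands listed by `zifnn` with no arguments.  Used by
#' the installed `inst/cli/zifnn` script; callable directly for testing.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 success, 2 validation error, 1 runtime
#'   error.
#' @export
zifnn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    cli_usage()
    return(0L)
  }
  sub <- args[1L]
  flags <- tryCatch(parse_flags(args[-1L]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    return(2L)
  }
  run <- function() {
    switch(sub,
      sample = {
        k <- flag_int(flags, "k", 50L)
        seed <- flag_int(flags, "seed", 1L)
        len <- flag_int(flags, "length", 9L)
        n_init <- flag_int(flags, "n-init", 10L)
        if (is.null(flags$out)) abort_validation("sample: --out is required")
        pop <- enumerate_population(len)
        reps <- kmeans_representatives(pop, k = k, seed = seed, n_init = n_init)
        write_fasta(reps$sequences, flags$out)
        if (!is.null(flags$sizes)) {
          write_tsv(data.frame(representative = reps$sequences,
                               cluster_size = reps$cluster_sizes),
                    flags$sizes, comment = sprintf("k=%d seed=%d", k, seed))
        }
        message(sprintf("wrote %d representatives to %s", k, flags$out))
      },
      helices = {
        tab <- if (is.null(flags$table)) default_mutation_table() else read_mutation_table(flags$table)
        finger <- if (is.null(flags$finger)) "F1" else flags$finger
        tpl <- zif268_template()
        if (!finger %in% names(tpl)) abort_validation("--finger must be F1, F2 or F3")
        lib <- enumerate_helices(tpl[[finger]], tab)
        if (isTRUE(flags$count)) {
          cat(length(lib$members), "\n")
        } else if (!is.null(flags$out)) {
          writeLines(lib$members, flags$out)
        } else {
          writeLines(lib$members)
        }
      },
      energy = {
        if (is.null(flags$bonds)) abort_validation("energy: --bonds is required")
        bonds <- parse_hbond_records(flags$bonds)
        ce <- complex_energy(bonds, design_id = basename(flags$bonds))
        df <- if (nrow(bonds) > 0L) {
          cbind(bonds, energy = round(ce$bond_energies, 4L))
        } else {
          cbind(bonds, energy = numeric(0))
        }
        out <- if (is.null(flags$out)) stdout() else flags$out
        if (is.character(out)) {
          write_tsv(df, out, comment = sprintf("total_energy=%.4f kcal/mol", ce$total_energy))
        } else {
          utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
        }
        message(sprintf("total energy: %.4f kcal/mol", ce$total_energy))
      },
      rank = {
        if (is.null(flags$energies) || is.null(flags$out)) {
          abort_validation("rank: --energies and --out are required")
        }
        df <- utils::read.delim(flags$energies, comment.char = "#", stringsAsFactors = FALSE)
        if (!all(c("design_id", "total_energy") %in% names(df))) {
          abort_validation("rank: input needs columns design_id, total_energy")
        }
        energies <- lapply(seq_len(nrow(df)), function(i) {
          structure(list(design_id = df$design_id[i], bond_energies = numeric(0),
                         total_energy = df$total_energy[i]), class = "complex_energy")
        })
        write_tsv(rank_designs(energies), flags$out)
      },
      simulate = {
        if (is.null(flags$out)) abort_validation("simulate: --out is required")
        seed <- flag_int(flags, "seed", 1L)
        n <- flag_int(flags, "n", 50L)
        noise <- flag_num(flags, "noise", 0)
        coupling <- flag_num(flags, "coupling", 0)
        map <- make_recognition_map(seed = seed, coupling = coupling)
        ds <- generate_dataset(map, n = n, noise_rate = noise, seed = seed)
        write_training_pairs(ds$pairs, flags$out,
                             comment = sprintf("zifnn synthetic pairs; seed=%d noise=%g coupling=%g",
                                               seed, noise, coupling))
      },
      train = {
        if (is.null(flags$data) || is.null(flags$out)) {
          abort_validation("train: --data and --out are required")
        }
        cfg <- ensemble_config(n_nets = flag_int(flags, "nets", 100L),
                               epochs = flag_int(flags, "epochs", 150L),
                               seed = flag_int(flags, "seed", 1L))
        model <- train_ensemble(read_training_pairs(flags$data), cfg)
        write_ensemble(model, flags$out)
        message(sprintf("trained %d nets -> %s", cfg$n_nets, flags$out))
      },
      predict = {
        if (is.null(flags$model) || is.null(flags$query) || is.null(flags$out)) {
          abort_validation("predict: --model, --query and --out are required")
        }
        model <- read_ensemble(flags$model)
        queries <- read_targets(flags$query)
        preds <- predict(model, queries, k = flag_int(flags, "top", 10L))
        write_tsv(preds, flags$out)
      },
      evaluate = {
        if (is.null(flags$pred) || is.null(flags$truth) || is.null(flags$out)) {
          abort_validation("evaluate: --pred, --truth and --out are required")
        }
        preds <- utils::read.delim(flags$pred, comment.char = "#", stringsAsFactors = FALSE)
        truth <- read_training_pairs(flags$truth)
        best <- preds[preds$rank == 1L, , drop = FALSE]
        rows <- data.frame(target = truth$dna, experimental = truth$protein,
                           predicted = paste0(best$helix_F1, best$helix_F2, best$helix_F3)
                           [match(truth$dna, best$target)],
                           stringsAsFactors = FALSE)
        report <- build_report(rows)
        write_tsv(report$rows, flags$out,
                  comment = sprintf("average_identity=%.4f coverage=%.4f",
                                    report$average_identity, report$coverage))
        message(sprintf("average identity %d%%, coverage %d%%",
                        percent_display(report$average_identity),
                        percent_display(report$coverage)))
      },
      pipeline = {
        if (is.null(flags$out)) abort_validation("pipeline: --out is required")
        run_pipeline(list(out_dir = flags$out,
                          seed = flag_int(flags, "seed", 1L),
                          n = flag_int(flags, "n", 50L),
                          noise_rate = flag_num(flags, "noise", 0),
                          coupling = flag_num(flags, "coupling", 0),
                          pairs = flags$pairs, queries = flags$query,
                          top_k = flag_int(flags, "top", 10L)))
      },
      abort_validation(sprintf("unknown subcommand '%s'", sub))
    )
    0L
  }
  tryCatch(run(),
           zifnn_validation_error = function(e) { message(conditionMessage(e)); 2L },
           error = function(e) { message(conditionMessage(e)); 1L })
}
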