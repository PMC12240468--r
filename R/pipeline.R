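# Pipeline orchestration: a single YAML run config, per-stage derived
# seeds, and subcommand dispatch for the command-line wrapper
# (inst/cli/chromswarm.R).

.known_config_sections <- c("seed", "paths", "synthetic", "model", "training",
                            "swarm", "labeling", "log_level")

#' Load and validate a run configuration
#'
#' YAML with optional sections `synthetic`, `model`, `training`, `swarm`,
#' `labeling`, `paths`, plus a global `seed`. Unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with defaults filled in.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_config_sections)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Derive a reproducible per-stage seed from the global seed
#'
#' Each pipeline stage draws randomness from its own seed, a deterministic
#' hash of the global seed and the stage name, so stages are independently
#' reproducible.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 10007 + h) %% 2147483587)
}

.cfg_synthetic <- function(cfg) {
  args <- if (is.null(cfg$synthetic)) list() else cfg$synthetic
  args$seed <- stage_seed(cfg$seed, "simulate")
  do.call(synthetic_config, args)
}

.cfg_spec <- function(cfg, n_targets, n_bins) {
  m <- if (is.null(cfg$model)) list() else cfg$model
  arch <- if (is.null(m$architecture)) 1L else m$architecture
  hp <- m
  hp$architecture <- NULL
  model_spec(arch, n_targets, n_bins, hyperparams = hp)
}

.write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "resolved-config.yaml"))
}

#' Pipeline stages
#'
#' Programmatic equivalents of the command-line subcommands; each is
#' idempotent given identical inputs and seed and writes its artifacts under
#' `out_dir`.
#'
#' @param cfg A `run_config` from [load_run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of written paths.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(.cfg_synthetic(cfg))
  container <- file.path(out_dir, "occupancy.tensor")
  save_container(ds$tensor, container, labels = ds$labels,
                 windows = ds$windows, target_names = ds$target_names)
  labels_bed <- file.path(out_dir, "labels.bed")
  write_bed(ds$windows, labels_bed)
  .write_resolved_config(cfg, out_dir)
  invisible(list(container = container, labels = labels_bed))
}

#' @rdname pipeline
#' @export
pipeline_train <- function(cfg, out_dir) {
  container <- file.path(out_dir, "occupancy.tensor")
  if (!file.exists(container)) {
    stop("missing ", container, "; run the simulate (or featurize) ",
         "subcommand first", call. = FALSE)
  }
  dat <- load_container(container)
  d <- dim(dat$values)
  spec <- .cfg_spec(cfg, d[2], d[3])
  tc_args <- if (is.null(cfg$training)) list() else cfg$training
  tc_args$seed <- stage_seed(cfg$seed, "train")
  tc <- do.call(training_config, tc_args)
  model <- build_model(spec, seed = stage_seed(cfg$seed, "init"))
  fit <- train(model, dat$values, dat$labels, tc)
  ckpt <- file.path(out_dir, "model.json")
  save_model(fit$model, ckpt)
  loss_csv <- file.path(out_dir, "loss-curve.csv")
  utils::write.csv(data.frame(epoch = seq_along(fit$loss_curve),
                              mean_loss = fit$loss_curve),
                   loss_csv, row.names = FALSE)
  invisible(list(model = ckpt, loss_curve = loss_csv))
}

#' @rdname pipeline
#' @export
pipeline_evaluate <- function(cfg, out_dir) {
  container <- file.path(out_dir, "occupancy.tensor")
  ckpt <- file.path(out_dir, "model.json")
  if (!file.exists(ckpt)) {
    stop("missing ", ckpt, "; run the train subcommand first", call. = FALSE)
  }
  dat <- load_container(container)
  model <- load_model(ckpt)
  rep_ <- evaluate(model, dat$values, dat$labels, "full synthetic dataset")
  out <- file.path(out_dir, "metrics.json")
  writeLines(jsonlite::toJSON(unclass(rep_), auto_unbox = TRUE, digits = NA),
             out)
  invisible(list(metrics = out))
}

#' @rdname pipeline
#' @export
pipeline_score_genome <- function(cfg, out_dir) {
  dat <- load_container(file.path(out_dir, "occupancy.tensor"))
  ckpt <- file.path(out_dir, "model.json")
  if (!file.exists(ckpt)) {
    stop("missing ", ckpt, "; run the train subcommand first", call. = FALSE)
  }
  model <- load_model(ckpt)
  sc <- genome_scores(model, dat$values, dat$windows)
  out <- file.path(out_dir, "scores.bedgraph")
  write_bedgraph(sc, out)
  invisible(list(scores = out))
}

#' @rdname pipeline
#' @export
pipeline_attack <- function(cfg, out_dir, mode = "positive") {
  ckpt <- file.path(out_dir, "model.json")
  if (!file.exists(ckpt)) {
    stop("missing ", ckpt, "; run the train subcommand first", call. = FALSE)
  }
  model <- load_model(ckpt)
  sw <- if (is.null(cfg$swarm)) list() else cfg$swarm
  n_runs <- if (is.null(sw$runs)) 8L else as.integer(sw$runs)
  sw$runs <- NULL
  sw$seed <- stage_seed(cfg$seed, paste0("attack-", mode))
  hp <- do.call(swarm_hyperparams, sw)
  res <- attack(model, hp, n_runs = n_runs, mode = mode)
  prof_csv <- file.path(out_dir, paste0("attack-profile-", mode, ".csv"))
  utils::write.csv(res$profile, prof_csv, row.names = FALSE)
  summ <- file.path(out_dir, paste0("attack-summary-", mode, ".json"))
  writeLines(jsonlite::toJSON(list(mode = mode,
                                   run_scores = res$run_scores,
                                   feature_means = as.list(res$feature_means)),
                              auto_unbox = TRUE, digits = NA), summ)
  invisible(list(profile = prof_csv, summary = summ))
}

#' @rdname pipeline
#' @export
pipeline_explain <- function(cfg, out_dir) {
  dat <- load_container(file.path(out_dir, "occupancy.tensor"))
  ckpt <- file.path(out_dir, "model.json")
  if (!file.exists(ckpt)) {
    stop("missing ", ckpt, "; run the train subcommand first", call. = FALSE)
  }
  model <- load_model(ckpt)
  pos <- which(dat$labels == 1)[seq_len(min(32L, sum(dat$labels == 1)))]
  ig <- integrated_gradients(model, dat$values[pos, , , drop = FALSE])
  per_target <- colMeans(apply(ig$values, c(1, 2), mean))
  out <- file.path(out_dir, "ig-per-target.csv")
  utils::write.csv(data.frame(target = dat$target_names,
                              mean_ig = per_target),
                   out, row.names = FALSE)
  invisible(list(ig = out))
}

#' @rdname pipeline
#' @param starr,atac,out BED paths for enhancer calling.
#' @export
pipeline_make_calls <- function(starr, atac, out, width = 1000L) {
  calls <- intersect_enhancer_calls(merge_intervals(read_bed(starr)),
                                    merge_intervals(read_bed(atac)))
  calls <- resize_midpoint(calls, width = width,
                           chrom_sizes = NULL)
  write_bed(calls, out)
  invisible(list(calls = out))
}

#' Command-line entry point
#'
#' Dispatches `chromswarm <subcommand> --config <yaml> --out <dir>`; see
#' `inst/cli/chromswarm.R` for the installed wrapper script. Exit-code
#' discipline is handled by the wrapper; this function raises classed
#' errors.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Invisibly, the dispatched stage's result.
#' @export
cli_main <- function(argv) {
  if (length(argv) < 1) {
    stop("usage: chromswarm <simulate|train|evaluate|score-genome|attack|",
         "explain|make-calls> [--config file] [--out dir] ...", call. = FALSE)
  }
  cmd <- argv[1]
  opts <- list()
  i <- 2
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    opts[[key]] <- if (i + 1 <= length(argv)) argv[i + 1] else ""
    i <- i + 2
  }
  if (cmd == "make-calls") {
    return(invisible(pipeline_make_calls(opts$starr, opts$atac, opts$out)))
  }
  if (is.null(opts$config) || is.null(opts$out)) {
    stop("--config and --out are required", call. = FALSE)
  }
  cfg <- load_run_config(opts$config)
  res <- switch(cmd,
    simulate = pipeline_simulate(cfg, opts$out),
    train = pipeline_train(cfg, opts$out),
    evaluate = pipeline_evaluate(cfg, opts$out),
    `score-genome` = pipeline_score_genome(cfg, opts$out),
    attack = pipeline_attack(cfg, opts$out,
                             mode = if (is.null(opts$mode)) "positive" else opts$mode),
    explain = pipeline_explain(cfg, opts$out),
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(res)
}
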