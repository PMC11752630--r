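#!/usr/bin/env Rscript
# Thin command-line wrapper over the apamirnet package.
#
#   Rscript scripts/apamirnet.R simulate --out DIR [--seed N]
#   Rscript scripts/apamirnet.R run --config run.yaml [--out DIR] [--seed N]
#
# `simulate` writes a synthetic input bundle (expression + APA matrices,
# clusters, binding sites, interactions, embedding, ground truth).
# `run` executes the full pipeline; the YAML config takes any
# pipeline_config() key, with synthetic-generator overrides under
# `simulate:`.

suppressPackageStartupMessages(library(apamirnet))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: apamirnet.R <simulate|run> [--config F] [--out DIR] [--seed N]")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

config_path <- opt("--config")
out_dir <- opt("--out")
seed <- opt("--seed")

if (cmd == "simulate") {
  if (is.null(out_dir)) stop("simulate needs --out DIR")
  overrides <- if (is.null(config_path)) list() else yaml::read_yaml(config_path)
  if (is.null(overrides)) overrides <- list()
  if (!is.null(seed)) overrides$seed <- as.integer(seed)
  cfg <- do.call(synthetic_config, overrides)
  ds <- simulate_dataset(cfg)
  write_dataset(ds, out_dir)
  message("wrote synthetic bundle to ", out_dir)
} else if (cmd == "run") {
  cfg <- validate_config(config_path)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  run_pipeline(cfg)
} else {
  stop("unknown subcommand: ", cmd)
}
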