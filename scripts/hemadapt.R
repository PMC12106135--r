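#!/usr/bin/env Rscript
# Command-line driver for the hemadapt pipeline.
#
#   Rscript scripts/hemadapt.R <subcommand> [--config cfg.yaml] [--seed N]
#                              [--output DIR] [--preset tiny|vit_b]
#
# Subcommands: simulate, preprocess, split, train, evaluate, compare,
# agreement, all. Each maps to the corresponding pipeline stage; `all` runs
# the full chain. Stages read upstream artifacts from the output directory,
# so a pipeline can be resumed stage by stage.

suppressMessages({
  library(optparse)
  library(hemadapt)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || args[1] %in% c("-h", "--help")) {
  cat("usage: hemadapt.R <simulate|preprocess|split|train|evaluate|compare|agreement|all> [options]\n")
  quit(status = if (length(args) < 1) 1 else 0)
}
subcmd <- args[1]
stages_all <- c("simulate", "preprocess", "split", "train", "evaluate",
                "compare", "agreement")
if (!subcmd %in% c(stages_all, "all")) {
  stop("unknown subcommand: ", subcmd)
}

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration"),
  make_option("--seed", type = "integer", default = NULL,
              help = "global seed (overrides the config)"),
  make_option("--output", type = "character", default = NULL,
              help = "artifact directory (overrides the config)"),
  make_option("--preset", type = "character", default = NULL,
              help = "model preset: tiny or vit_b"),
  make_option("--stage", type = "character", default = NULL,
              help = "comma-separated stage list (overrides the subcommand)")
)), args = args[-1])

cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else default_run_config()
if (!is.null(opts$seed)) cfg$seed <- opts$seed
if (!is.null(opts$output)) cfg$output <- opts$output
if (!is.null(opts$preset)) cfg$model$preset <- opts$preset

stages <- if (!is.null(opts$stage)) {
  strsplit(opts$stage, ",")[[1]]
} else if (subcmd == "all") stages_all else subcmd

run_pipeline(cfg, stages = stages)
cat("done:", cfg$output, "\n")
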