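#!/usr/bin/env Rscript
# Thin command-line wrapper over headconform::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --config <config.yaml> --out <dir>
#   Rscript scripts/run_pipeline.R --simulate --seed 7 --out <dir>
#
# --simulate runs the default synthetic study (52 + 36 participants, 60-s
# laps at 90 Hz) without a config file.

suppressMessages(library(headconform))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

out_dir <- get_arg("--out", "pipeline_output")
config_path <- get_arg("--config")

if ("--simulate" %in% args || is.null(config_path)) {
  config <- list(
    io = list(lap_duration = 60, rate = 90),
    synthetic = list(seed = as.integer(get_arg("--seed", "1"))),
    report = list(figures = TRUE)
  )
} else {
  config <- config_path
}

run_pipeline(config, out_dir)
message(sprintf("Pipeline outputs written to %s", out_dir))
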