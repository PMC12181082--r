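#!/usr/bin/env Rscript

# Thin command-line wrapper over contoureval::run_study().
#
# Usage: Rscript scripts/run_study.R <config.yaml|config.json> <out_dir>
#        Rscript scripts/run_study.R --default <out_dir> [seed]

suppressPackageStartupMessages(library(contoureval))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2L)
  stop("usage: run_study.R <config|--default> <out_dir> [seed]")

config <- if (args[1] == "--default") {
  seed <- if (length(args) >= 3L) as.integer(args[3]) else 1L
  default_study_config(seed = seed)
} else args[1]

report <- run_study(config, out_dir = args[2], verbose = TRUE)
print(report)
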