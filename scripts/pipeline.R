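#!/usr/bin/env Rscript
# Thin command-line wrapper over whalebreach::run_pipeline().
#
# Usage:
#   Rscript scripts/pipeline.R [--config run.yaml] [--out DIR] [--seed N]
#           [--input tag.csv]
#
# Without --config, a default synthetic three-breach run is executed.

suppressPackageStartupMessages(library(whalebreach))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(config = NULL, out = NULL, seed = NULL, input = NULL)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- args[i + 1]
  i <- i + 2L
}

cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
if (!is.null(opt$out)) cfg$out_dir <- opt$out
if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
if (!is.null(opt$input)) cfg$input <- opt$input

res <- run_pipeline(cfg)
cat("breaches detected:", nrow(res$metrics), "\n")
cat("outputs:\n")
for (p in res$paths) cat(" ", p, "\n")
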