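#!/usr/bin/env Rscript

# Thin command-line wrapper around cutrunr::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] --out <dir>
#
# The YAML config supports the keys documented in ?run_pipeline:
# `seed`, `stages`, and `simulate` (sim_config overrides). Without
# --config the pipeline runs all stages with default settings.

suppressPackageStartupMessages(library(cutrunr))

args <- commandArgs(trailingOnly = TRUE)
config <- list()
out <- NULL
i <- 1
while (i <= length(args)) {
  if (args[i] == "--config") { config <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--out") { out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}
if (is.null(out)) stop("--out <dir> is required")

res <- run_pipeline(config, out)
cat("wrote", length(res$manifest$outputs), "files to", out, "\n")
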