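#!/usr/bin/env Rscript

# End-to-end simulation from a config file (or the package defaults):
# canonical HRTFs -> stimulus matrix -> virtual experiment -> regression
# summary, all written as CSV plus a manifest.
#
# Usage: Rscript scripts/run_pipeline.R [--config FILE] [--seed INT] --out DIR

suppressPackageStartupMessages(library(specloc))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(config = NULL, seed = NULL, out = "pipeline_out")
i <- 1
while (i <= length(args)) {
  if (args[i] == "--config") { opt$config <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}

cfg <- if (is.null(opt$config)) pipeline_config() else read_pipeline_config(opt$config)
if (!is.null(opt$seed)) cfg$seed <- opt$seed
res <- run_pipeline(cfg, opt$out)
message("artifacts in ", opt$out)
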