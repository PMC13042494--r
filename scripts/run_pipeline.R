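#!/usr/bin/env Rscript
# Thin command-line wrapper over cscore::run_pipeline().
# Usage: Rscript scripts/run_pipeline.R <config.yaml> [output_dir]

suppressPackageStartupMessages(library(cscore))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript scripts/run_pipeline.R <config.yaml> [output_dir]",
       call. = FALSE)
}
summary <- run_pipeline(args[1],
                        output_dir = if (length(args) > 1) args[2] else NULL)
print(summary)
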