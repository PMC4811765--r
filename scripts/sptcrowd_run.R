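#!/usr/bin/env Rscript
# Thin shell entry point over sptcrowd::run_pipeline().
# Usage: Rscript scripts/sptcrowd_run.R <config.yaml> [--seed <int>] [--out <dir>]
# CLI flags override the corresponding config fields.

suppressPackageStartupMessages(library(sptcrowd))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || args[1] %in% c("-h", "--help")) {
  cat("usage: Rscript scripts/sptcrowd_run.R <config.yaml> [--seed <int>] [--out <dir>]\n")
  quit(status = if (length(args) < 1L) 1L else 0L)
}
config <- yaml::read_yaml(args[1])
get_arg <- function(flag) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
}
if (!is.null(get_arg("--seed"))) config$seed <- as.integer(get_arg("--seed"))
if (!is.null(get_arg("--out"))) config$output_dir <- get_arg("--out")

manifest <- tryCatch(run_pipeline(config), error = function(e) {
  message("pipeline failed: ", conditionMessage(e))
  quit(status = 1L)
})
print(manifest$comparison)
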