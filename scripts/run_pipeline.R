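#!/usr/bin/env Rscript
# Thin command-line wrapper over microconn::run_pipeline().
#   Rscript scripts/run_pipeline.R --out <dir> [--config <json>] [--seed <int>]
# The JSON config mirrors run_config(); omitted keys take their defaults.

suppressPackageStartupMessages({
  library(optparse)
  library(microconn)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "JSON file with run_config() fields"),
  make_option("--out", type = "character", default = "mc_output",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config seed"),
  make_option("--verbose", action = "store_true", default = FALSE,
              help = "print per-stage progress")
)))

cfg_args <- list()
if (!is.null(opts$config)) {
  cfg_args <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  if (!is.null(cfg_args$generator)) {
    cfg_args$generator <- do.call(ms_config, as.list(cfg_args$generator))
  }
}
if (!is.null(opts$seed)) cfg_args$seed <- opts$seed
config <- do.call(run_config, cfg_args)

report <- run_pipeline(config, out_dir = opts$out, verbose = opts$verbose)
print(report)
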