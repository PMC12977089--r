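#!/usr/bin/env Rscript

# Thin command-line wrapper around prsbrainmap::runPipeline():
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed 1]
#     [--out results] [--n-perm 1000] [--relative | --absolute]
#     [--atlas-crosswalk weights.csv] [--exclude-regions regions.bed]

suppressPackageStartupMessages({
  library(optparse)
  library(prsbrainmap)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON pipeline configuration"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed (overrides config)"),
  make_option("--out", type = "character", default = NULL,
              help = "output directory (overrides config)"),
  make_option("--n-perm", type = "integer", default = NULL,
              dest = "nPerm", help = "permutations for the correlation null"),
  make_option("--relative", action = "store_true", default = FALSE,
              help = "use global-size-adjusted measures"),
  make_option("--absolute", action = "store_true", default = FALSE,
              help = "use unadjusted measures (default)"),
  make_option("--atlas-crosswalk", type = "character", default = NULL,
              dest = "crosswalk", help = "crosswalk weights CSV"),
  make_option("--exclude-regions", type = "character", default = NULL,
              dest = "excludeRegions", help = "BED-like exclusion file")))
opt <- parse_args(parser)

cfg <- if (!is.null(opt$config)) {
  readPipelineConfig(opt$config)
} else {
  pipelineConfig()
}
if (!is.null(opt$seed)) cfg$seed <- opt$seed
if (!is.null(opt$out)) cfg$outDir <- opt$out
if (!is.null(opt$nPerm)) cfg$nPerm <- opt$nPerm
if (opt$relative && opt$absolute)
  stop("--relative and --absolute are mutually exclusive")
if (opt$relative) cfg$relative <- TRUE
if (opt$absolute) cfg$relative <- FALSE
if (!is.null(opt$crosswalk)) cfg$crosswalkPath <- opt$crosswalk
if (!is.null(opt$excludeRegions)) cfg$excludeRegionsPath <- opt$excludeRegions

message(sprintf("running pipeline (seed %d) -> %s", cfg$seed, cfg$outDir))
res <- runPipeline(cfg)
message(sprintf("association rows: %d; map comparisons: %d; MR rows: %d; quadrant rows: %d",
                nrow(res$association), nrow(res$concordance),
                nrow(res$mr), nrow(res$quadrant)))
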