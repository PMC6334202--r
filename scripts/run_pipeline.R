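#!/usr/bin/env Rscript
# Thin command-line wrapper over afdfmap::run_pipeline().
#
#   Rscript scripts/run_pipeline.R --scenario scenario.yaml --out results/
#   Rscript scripts/run_pipeline.R --atrial a.tsv --atrial-sidecar a.yaml \
#       --torso t.tsv --torso-sidecar t.yaml --out results/
#
# A scenario YAML holds synthetic_scenario() arguments by name.

suppressPackageStartupMessages({
  library(optparse)
  library(afdfmap)
})

opt_list <- list(
  make_option("--scenario", type = "character", default = NULL,
              help = "YAML file of synthetic_scenario() arguments"),
  make_option("--atrial", type = "character", default = NULL),
  make_option("--atrial-sidecar", type = "character", default = NULL,
              dest = "atrial_sidecar"),
  make_option("--torso", type = "character", default = NULL),
  make_option("--torso-sidecar", type = "character", default = NULL,
              dest = "torso_sidecar"),
  make_option("--oi-threshold", type = "double", default = 0.5,
              dest = "oi_threshold",
              help = "comparison OI threshold [default %default]"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "afdfmap-results")
)
opts <- parse_args(OptionParser(option_list = opt_list))

scenario <- NULL
if (!is.null(opts$scenario)) {
  args <- yaml::read_yaml(opts$scenario)
  scenario <- do.call(synthetic_scenario, args)
}
cfg <- pipeline_config(
  scenario = scenario,
  atrial_path = opts$atrial, torso_path = opts$torso,
  atrial_sidecar = opts$atrial_sidecar, torso_sidecar = opts$torso_sidecar,
  compare_threshold = opts$oi_threshold,
  out_dir = opts$out, seed = opts$seed)

t0 <- Sys.time()
res <- run_pipeline(cfg)
print(res)
cat(sprintf("artifacts written to %s (%.1f s)\n", opts$out,
            as.numeric(difftime(Sys.time(), t0, units = "secs"))))
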