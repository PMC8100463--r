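#!/usr/bin/env Rscript
# Generate one synthetic membrane-peptide system and write it to disk.
#
# Usage: Rscript scripts/simulate.R --config gen.yaml --seed N --out DIR
#
# The YAML file holds syntheticConfig() arguments; --seed overrides the
# config seed.

suppressPackageStartupMessages(library(pepMembrane))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
outDir <- getArg("--out", "synthetic_system")
seed <- getArg("--seed")
cfgPath <- getArg("--config")

gen <- if (is.null(cfgPath)) list() else yaml::read_yaml(cfgPath)
for (nm in c("composition", "diffusion", "box"))
  if (!is.null(gen[[nm]])) gen[[nm]] <- unlist(gen[[nm]])
if (!is.null(seed)) gen$seed <- as.integer(seed)
cfg <- do.call(syntheticConfig, gen)
sim <- generateSystem(cfg)
writeSystem(sim, outDir)
message("wrote GRO topology, trajectory and ground truth to ", outDir)
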