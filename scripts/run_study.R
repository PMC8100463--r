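#!/usr/bin/env Rscript
# Thin command-line wrapper over pepMembrane::runStudy().
#
# Usage: Rscript scripts/run_study.R --config study.yaml --out DIR --seed N
#
# The YAML config lists conditions; each condition is either synthetic
# (generator arguments under `config:`) or ingested (`topology:` +
# `trajectories:`). Analysis parameter overrides go under `params:`.

suppressPackageStartupMessages(library(pepMembrane))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
cfgPath <- getArg("--config")
if (is.null(cfgPath)) stop("--config FILE is required")
outDir <- getArg("--out", "report")
seed <- as.integer(getArg("--seed", "1"))

y <- yaml::read_yaml(cfgPath)
conds <- lapply(y$conditions, function(cc) {
  if (!is.null(cc$config)) {
    gen <- cc$config
    for (nm in c("composition", "diffusion")) {
      if (!is.null(gen[[nm]])) gen[[nm]] <- unlist(gen[[nm]])
    }
    if (!is.null(gen$box)) gen$box <- unlist(gen$box)
    list(config = do.call(syntheticConfig, gen),
         nRepeats = if (is.null(cc$nRepeats)) 4L else cc$nRepeats)
  } else {
    list(topology = cc$topology, trajectories = unlist(cc$trajectories))
  }
})
names(conds) <- vapply(y$conditions, `[[`, character(1), "label")

params <- if (is.null(y$params)) list() else y$params
runStudy(studyConfig(conds, comparePairs = y$comparePairs, outDir = outDir,
                     seed = seed, params = params))
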