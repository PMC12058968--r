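#!/usr/bin/env Rscript

# Full-scale state census: the complete (R, T0) sweep with all four
# initialization families at the reference system size (N = 1000,
# 1000 tau_R equilibration + 1000 tau_R collection). This is a
# long-running batch job (days of CPU time); run it on a cluster, ideally
# one (R, T0, init, seed) combination per job. For a desktop-scale census
# see the reduced sweep in scripts/acceptance.R.
#
#   Rscript scripts/census.R --seed 1 --out results/census.json \
#       [--radii 1.05,1.5,2,2.5,3] [--torques 1,2.5,5,10,25,50,75,100] \
#       [--nseeds 4]

suppressPackageStartupMessages({
  library(cohesim)
  library(optparse)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/census.json"),
  make_option("--radii", type = "character", default = "1.05,1.5,2,2.5,3"),
  make_option("--torques", type = "character",
              default = "1,2.5,5,10,25,50,75,100"),
  make_option("--nseeds", type = "integer", default = 4L)
)))

base <- sim_params(N = 1000, Phi = 0.025, dt = 5e-5,
                   t_equil = 1000, t_collect = 1000,
                   sample_interval = 0.1, seed = opt$seed)

sdg <- sweep_state_diagram(
  base,
  R_values = as.numeric(strsplit(opt$radii, ",")[[1]]),
  T0_values = as.numeric(strsplit(opt$torques, ",")[[1]]),
  inits = c("lattice_random", "hex_cluster_inward",
            "hex_cluster_random", "worm"),
  seeds = opt$seed + seq_len(opt$nseeds) - 1L,
  verbose = TRUE)

print(sdg)
dir.create(dirname(opt$out), showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(sdg$runs, opt$out, dataframe = "rows",
                     auto_unbox = TRUE, digits = NA, na = "null")
message("wrote ", opt$out)
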