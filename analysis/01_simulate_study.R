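#!/usr/bin/env Rscript
# Generate the synthetic study: GWAS summary statistics for a birth-weight
# style exposure, one mediator and one outcome from the mediation diagram
# exposure -> mediator -> outcome, with truth at the published scale
# (total effect -1.1, mediated proportion 4/11), plus a block LD matrix.
# Outputs: results/synthetic/{exposure,mediator,outcome}.tsv, truth.json.

library(twostepmr)

out_dir <- "results/synthetic"
cfg <- sim_config(n_snps = 100, seed = 20240917)
sim <- simulate_mediation_gwas(cfg)
paths <- write_sim_study(sim, out_dir)

message("Simulated ", cfg$n_snps, " instruments for three GWAS (N = 1e5 each)")
message("  truth: total = ", sim$truth$total_true,
        ", direct = ", sim$truth$direct_true,
        ", mediated proportion = ", round(sim$truth$proportion_true, 4))
message("  written to ", out_dir)
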