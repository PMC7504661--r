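#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- control/tumor expression, the
# TF-target network, signed pathways, the drug catalog and the synergy
# screen -- and write every pipeline input plus the planted truth.

suppressMessages(library(oncocascade))

outdir <- "results/run/inputs"
cfg <- simulation_config(seed = 20260)  # stock study conditions
sim <- simulate_study(cfg)
write_simulation(sim, outdir)

cat(sprintf("samples: %d control, %d tumor; genes: %d\n",
            ncol(sim$control), ncol(sim$tumor), nrow(sim$control)))
cat(sprintf("network: %d TFs, %d targets, %d interactions\n",
            length(sim$network$tfs), length(sim$network$targets),
            nrow(sim$network$edges)))
cat(sprintf("planted: %d subgroups, %d cascades, %d drugs (%d with network targets), %d synergistic pairs\n",
            cfg$n_subgroups, length(sim$truth$planted_cascades),
            cfg$n_drugs, length(sim$truth$network_drugs),
            nrow(sim$truth$synergy_pairs)))
cat("inputs written under", outdir, "\n")
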