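#!/usr/bin/env Rscript
# Stage 3: per-sample activated-TF inference by hypergeometric target-set
# enrichment among the sample's up-regulated genes (gate p <= 0.05).

suppressMessages(library(oncocascade))

indir <- "results/run/inputs"
outdir <- "results/run"
control <- read_expression_matrix(file.path(indir, "control.tsv"))
network <- read_regulatory_network(file.path(indir, "network.tsv"))
calls <- read.delim(file.path(outdir, "calls.tsv"))

act <- activation_matrix(calls, network, universe = rownames(control))
write_expression_matrix(act$active, file.path(outdir, "tf_active.tsv"))
write_expression_matrix(act$p_values, file.path(outdir, "tf_pvalues.tsv"))

per_sample <- rowSums(act$active)
cat(sprintf("tested %d TFs in %d samples\n", ncol(act$active), nrow(act$active)))
cat(sprintf("activated TFs per sample: median %d (range %d-%d)\n",
            as.integer(median(per_sample)), min(per_sample), max(per_sample)))
cat("most frequently activated TFs:",
    paste(names(sort(colSums(act$active), decreasing = TRUE))[1:5],
          collapse = ", "), "\n")
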