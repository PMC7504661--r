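#!/usr/bin/env Rscript
# Stage 2: fit the per-gene Bayesian null on the controls and call
# up-regulated genes per tumor sample (fold change >= 2 AND doubled-variable
# p-value <= 0.05). Also tabulates the per-gene up-regulation probabilities
# reused by the cascade and perturbation stages.

suppressMessages(library(oncocascade))

indir <- "results/run/inputs"
outdir <- "results/run"
control <- read_expression_matrix(file.path(indir, "control.tsv"))
tumor <- read_expression_matrix(file.path(indir, "tumor.tsv"))

settings <- mcmc_settings(seed = 20261)
calls <- call_upregulated(control, tumor, settings = settings)
models <- attr(calls, "models")
probs <- probability_matrix(models, tumor)

df <- calls; attr(df, "models") <- NULL
write.table(df, file.path(outdir, "calls.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_expression_matrix(probs, file.path(outdir, "probabilities.tsv"))

per_sample <- tapply(calls$up, calls$sample, sum)
cat(sprintf("fitted %d gene null models on %d controls\n",
            length(models), ncol(control)))
cat(sprintf("up-regulated genes per tumor sample: median %d (range %d-%d)\n",
            as.integer(median(per_sample)), min(per_sample), max(per_sample)))
nonconv <- sum(vapply(models, function(m) length(m$warnings) > 0, logical(1)))
cat(sprintf("models with sampler warnings: %d\n", nonconv))
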