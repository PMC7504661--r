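#!/usr/bin/env Rscript
# Stage 4: stratify tumor samples by k-modes clustering of the binary
# activated-TF profiles; characterize each subgroup by its center sample.
# The cluster count has no printed selection rule, so a cost-vs-k elbow
# table is reported alongside the default k = 3.

suppressMessages(library(oncocascade))

outdir <- "results/run"
pvals <- read_expression_matrix(file.path(outdir, "tf_pvalues.tsv"))
binary <- binarize_profiles(pvals)  # rows = samples, columns = TFs

n_distinct <- nrow(unique(binary))
cat(sprintf("cost-vs-k elbow (%d distinct profiles):\n", n_distinct))
for (k in 2:min(5, n_distinct)) {
  fit_k <- kmodes_cluster(binary, k = k, n_init = 10, seed = 20262)
  cat(sprintf("  k = %d: cost = %d\n", k, fit_k$cost))
}

fit <- kmodes_cluster(binary, k = 3, n_init = 10, seed = 20262)
report <- subgroup_tf_report(fit)
pca <- project_profiles_2d(binary)

jsonlite::write_json(
  list(k = fit$k, labels = as.list(fit$labels),
       centers = as.list(fit$center_samples),
       group_tfs = fit$group_tf_sets, shared_tfs = report$shared,
       unique_tfs = report$unique_tfs, cost = fit$cost),
  file.path(outdir, "groups.json"), auto_unbox = TRUE, digits = NA)
write.table(data.frame(sample = rownames(pca), pca),
            file.path(outdir, "pca.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("k = 3 subgroups of sizes %s (cost %d)\n",
            paste(tabulate(fit$labels, 3), collapse = "/"), fit$cost))
for (g in names(fit$center_samples)) {
  cat(sprintf("  %s: center %s, TFs: %s\n", g, fit$center_samples[[g]],
              paste(fit$group_tf_sets[[g]], collapse = ", ")))
}
cat("TFs shared by all subgroups:",
    if (length(report$shared)) paste(report$shared, collapse = ", ") else "none", "\n")
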