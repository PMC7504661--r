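#!/usr/bin/env Rscript
# Stage 5: enumerate upstream signaling cascades from pathway start genes to
# each subgroup's activated TFs, score them by the mean up-regulation
# probability of member genes (taken from the subgroup's center sample),
# keep the top 3 per (pathway, TF), and merge the survivors into one core
# signaling network per subgroup.

suppressMessages(library(oncocascade))

indir <- "results/run/inputs"
outdir <- "results/run"
pathways <- lapply(sort(list.files(file.path(indir, "pathways"),
                                   pattern = "\\.sif$", full.names = TRUE)),
                   read_pathway_sif)
groups <- jsonlite::read_json(file.path(outdir, "groups.json"),
                              simplifyVector = TRUE)
probs <- read_expression_matrix(file.path(outdir, "probabilities.tsv"))

networks <- list()
for (g in names(groups$group_tfs)) {
  tfs <- groups$group_tfs[[g]]
  center <- groups$centers[[g]]
  cand <- collect_cascades(pathways, tfs, max_len = 12)
  retained <- score_and_prune(cand, probs[, center], top_k = 3)
  cat(sprintf("%s (center %s): %d cascades enumerated, %d retained, mean score %.3f\n",
              g, center, nrow(cand), nrow(retained),
              if (nrow(retained)) mean(retained$score) else NA))
  if (nrow(retained)) {
    net <- build_core_network(retained, pathways, tfs)
    networks[[g]] <- net
    write_core_network(net, file.path(outdir, paste0(g, "_network.graphml")))
  }
}
union_net <- union_core_networks(networks)
write_core_network(union_net, file.path(outdir, "union_network.graphml"))

cmp <- compare_groups(networks)
cat(sprintf("union network: %d genes, %d edges; %d genes common to all subgroups\n",
            nrow(union_net$nodes), nrow(union_net$edges), length(cmp$shared)))
for (g in names(cmp$unique_genes)) {
  cat(sprintf("  %s unique genes: %s\n", g,
              paste(cmp$unique_genes[[g]], collapse = ", ")))
}
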