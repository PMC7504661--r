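test_that("simulation is deterministic in (config, seed)", {
  cfg <- simulation_config(n_normal = 10, n_tumor = 9, n_genes = 120,
                           n_tfs = 8, targets_per_tf = c(5, 7),
                           active_tfs_per_group = 2, n_pathways = 3,
                           n_drugs = 10, seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$control, b$control)
  expect_identical(a$tumor, b$tumor)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(lapply(a$pathways, `[[`, "edges"),
                   lapply(b$pathways, `[[`, "edges"))
  expect_identical(a$synergy, b$synergy)
  expect_identical(a$truth$upregulated, b$truth$upregulated)
})

test_that("different seeds give different data", {
  cfg1 <- simulation_config(n_normal = 10, n_tumor = 9, n_genes = 120,
                            n_tfs = 8, seed = 7)
  cfg2 <- simulation_config(n_normal = 10, n_tumor = 9, n_genes = 120,
                            n_tfs = 8, seed = 8)
  expect_false(identical(simulate_expression(cfg1)$control,
                         simulate_expression(cfg2)$control))
})

test_that("config validation rejects degenerate settings", {
  expect_error(simulation_config(n_genes = 0, seed = 1), "n_genes")
  expect_error(simulation_config(planted_fold = 1.5, seed = 1), "planted_fold")
  expect_error(simulation_config(synergy_fraction = 1.2, seed = 1), "probability")
  expect_error(simulation_config(n_tfs = 3, n_subgroups = 3,
                                 active_tfs_per_group = 2, seed = 1),
               "active_tfs_per_group")
  expect_error(
    simulate_regulatory_network(simulation_config(seed = 1, n_genes = 30,
                                                  n_tfs = 10,
                                                  targets_per_tf = c(10, 12))),
    "infeasible")
})

test_that("at zero noise every planted tumor value exceeds twice its control mean", {
  cfg <- zero_noise_config()
  sim <- simulate_expression(cfg)
  cmeans <- rowMeans(sim$control)
  for (s in names(sim$truth$upregulated)[1:5]) {
    planted <- sim$truth$upregulated[[s]]
    expect_true(all(sim$tumor[planted, s] > 2 * cmeans[planted]))
  }
})

test_that("planted genes reach planted_fold times the control mean on average", {
  cfg <- simulation_config(n_normal = 88, n_tumor = 150, n_genes = 200,
                           n_tfs = 8, planted_fold = 4, noise_sd = 1,
                           seed = 11)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  g1_samples <- names(tr$subgroup_labels)[tr$subgroup_labels == 1]
  gene <- tr$upregulated[[g1_samples[1]]][1]
  vals <- sim$tumor[gene, g1_samples]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 4 * tr$mu[gene]), 3 * se)
})

test_that("fixed targets_per_tf gives every TF exactly that many targets", {
  cfg <- simulation_config(n_genes = 150, n_tfs = 8,
                           targets_per_tf = c(10, 10), seed = 3)
  net <- simulate_regulatory_network(cfg)
  counts <- table(net$network$edges$tf)
  expect_true(all(counts == 10))
  expect_equal(nrow(net$network$edges), 80)
})

test_that("active TF targets are disjoint from decoy TF targets", {
  cfg <- simulation_config(n_genes = 200, n_tfs = 10,
                           active_tfs_per_group = 2, seed = 5)
  net <- simulate_regulatory_network(cfg)
  active <- unlist(net$truth$active_tfs)
  active_targets <- unlist(net$truth$tf_targets[active])
  decoy_targets <- unlist(net$truth$tf_targets[setdiff(names(net$truth$tf_targets), active)])
  expect_length(intersect(active_targets, decoy_targets), 0)
  # Active TFs are also pairwise disjoint.
  expect_false(anyDuplicated(active_targets) > 0)
})

test_that("a planted active TF is enriched by the exact hypergeometric tail", {
  cfg <- zero_noise_config()
  net <- simulate_regulatory_network(cfg)
  expr <- simulate_expression(cfg, net)
  s <- names(expr$truth$subgroup_labels)[1]
  grp <- expr$truth$subgroup_labels[[s]]
  tf <- expr$truth$active_tfs[[grp]][1]
  up <- expr$truth$upregulated[[s]]
  targets <- net$truth$tf_targets[[tf]]
  N <- nrow(expr$control)
  p <- hyper_tail_bruteforce(length(intersect(targets, up)),
                             length(targets), length(up), N)
  expect_lt(p, 0.05)
})

test_that("fixed cascade_length gives planted paths of exactly that many edges", {
  cfg <- simulation_config(n_genes = 200, n_tfs = 8, n_pathways = 4,
                           cascade_length = c(3, 3), seed = 9)
  pw <- simulate_pathways(cfg)
  for (pc in pw$truth$planted_cascades) {
    expect_length(pc$nodes, 4)  # 3 edges = 4 nodes
  }
})

test_that("every planted cascade terminates at an active TF and is a pathway path", {
  cfg <- zero_noise_config()
  net <- simulate_regulatory_network(cfg)
  pw <- simulate_pathways(cfg, net)
  active <- unlist(net$truth$active_tfs)
  ids <- vapply(pw$pathways, `[[`, character(1), "id")
  for (pc in pw$truth$planted_cascades) {
    expect_true(pc$tf %in% active)
    expect_identical(pc$nodes[length(pc$nodes)], pc$tf)
    g <- pw$pathways[[match(pc$pathway, ids)]]
    for (j in seq_len(length(pc$nodes) - 1)) {
      expect_true(any(g$edges$source == pc$nodes[j] &
                        g$edges$target == pc$nodes[j + 1]))
    }
  }
})

test_that("synergy fraction bounds behave at the extremes and in expectation", {
  cfg0 <- simulation_config(n_genes = 200, n_tfs = 8, n_drugs = 12,
                            synergy_fraction = 0, seed = 13)
  expect_true(all(simulate_drug_screen(cfg0)$synergy$score <= 8))
  cfg1 <- simulation_config(n_genes = 200, n_tfs = 8, n_drugs = 12,
                            synergy_fraction = 1, seed = 13)
  expect_true(all(simulate_drug_screen(cfg1)$synergy$score > 8))
  # 0.2 of >= 500 screened pairs inside the binomial 99% interval.
  cfg <- simulation_config(n_genes = 200, n_tfs = 8, n_drugs = 35,
                           synergy_fraction = 0.2, seed = 13)
  screen <- simulate_drug_screen(cfg)
  n <- nrow(screen$synergy)
  expect_gte(n, 500)
  hits <- sum(screen$synergy$score > 8)
  expect_gte(hits, stats::qbinom(0.005, n, 0.2))
  expect_lte(hits, stats::qbinom(0.995, n, 0.2))
})

test_that("generated files round-trip through the readers without warnings", {
  cfg <- simulation_config(n_normal = 8, n_tumor = 6, n_genes = 120,
                           n_tfs = 8, n_pathways = 3, n_drugs = 10, seed = 17)
  sim <- simulate_study(cfg)
  outdir <- withr::local_tempdir()
  write_simulation(sim, outdir)
  expect_no_warning({
    ctrl <- read_expression_matrix(file.path(outdir, "control.tsv"))
    tum <- read_expression_matrix(file.path(outdir, "tumor.tsv"))
    net <- read_regulatory_network(file.path(outdir, "network.tsv"))
    sifs <- list.files(file.path(outdir, "pathways"), full.names = TRUE)
    pws <- lapply(sifs, read_pathway_sif)
    cat_ <- read_drug_catalog(file.path(outdir, "drugs.tsv"))
    syn <- read_synergy_table(file.path(outdir, "synergy.csv"))
  })
  # Full-precision round trip: bit-identical values.
  expect_identical(as.vector(ctrl), as.vector(sim$control))
  expect_identical(dimnames(ctrl), dimnames(sim$control))
  expect_identical(as.vector(tum), as.vector(sim$tumor))
  expect_identical(net$edges, sim$network$edges)
  expect_identical(lapply(pws, `[[`, "edges"),
                   lapply(sim$pathways, `[[`, "edges"))
})
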