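# Shared fixtures and independent oracles used across test files.

# Small, fast sampler settings for tests that do not probe tail accuracy.
fast_mcmc <- function(seed, predictive = 2000) {
  mcmc_settings(n_draws = 500, n_tune = 250, n_chains = 2,
                predictive_draws = predictive, seed = seed)
}

# Reduced-scale noiseless study used by recovery tests; memoised because the
# pipeline run is the most expensive fixture in the suite.
.fixture_cache <- new.env(parent = emptyenv())

zero_noise_config <- function() {
  simulation_config(n_normal = 20, n_tumor = 18, n_genes = 160, n_tfs = 9,
                    targets_per_tf = c(6, 8), n_subgroups = 3,
                    active_tfs_per_group = 2, planted_fold = 4,
                    noise_sd = 0, n_pathways = 3, cascade_length = c(3, 5),
                    n_drugs = 12, synergy_fraction = 0.25, seed = 42)
}

zero_noise_run <- function() {
  if (is.null(.fixture_cache$zero)) {
    pcfg <- pipeline_config(simulate = zero_noise_config(), seed = 42,
                            zero_var = "jitter",
                            mcmc = fast_mcmc(42, predictive = 1000))
    .fixture_cache$zero <- suppressWarnings(run_pipeline(pcfg))
  }
  .fixture_cache$zero
}

fixture_synergy_path <- function() {
  system.file("extdata", "validated_synergies_nci60.csv",
              package = "oncocascade", mustWork = TRUE)
}

# Build a drug catalog straight from a (normalized) synergy table's target
# annotation columns, so every listed drug is mappable.
catalog_from_synergy <- function(records) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    for (side in c(1, 2)) {
      drug <- records[[paste0("drug", side)]][i]
      targets <- trimws(strsplit(records[[paste0("targets", side)]][i], ",")[[1]])
      rows[[length(rows) + 1L]] <- data.frame(drug = drug, target = targets,
                                              stringsAsFactors = FALSE)
    }
  }
  df <- unique(do.call(rbind, rows))
  drug_catalog(df)
}

# --- independent oracles -------------------------------------------------

# Exact hypergeometric upper tail by direct combinatorial summation.
hyper_tail_bruteforce <- function(k, K, m, N) {
  if (k > min(K, m)) return(0)
  i <- seq(k, min(K, m))
  sum(choose(K, i) * choose(N - K, m - i)) / choose(N, m)
}

# Exhaustive simple-path enumeration by depth-first search over an edge
# list, independent of igraph.
dfs_simple_paths <- function(edges, from, to, max_len = Inf) {
  adj <- split(edges$target, edges$source)
  paths <- list()
  recurse <- function(node, path) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= max_len) return(invisible())
    for (nxt in adj[[node]]) {
      if (!nxt %in% path) recurse(nxt, c(path, nxt))
    }
  }
  if (from %in% c(edges$source, edges$target, to)) recurse(from, from)
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(keys)]
}

# Random directed graph as an edge list (no self loops, unique edges).
random_edgelist <- function(n_nodes, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  grid <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  keep <- stats::runif(nrow(grid)) < p_edge
  grid[keep, , drop = FALSE]
}

# Random DAG: edges only from lower to higher node index.
random_dag <- function(n_nodes, p_edge) {
  el <- random_edgelist(n_nodes, p_edge)
  el[el$source < el$target, , drop = FALSE]
}

# Adjusted Rand index between two labelings (mclust's implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
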