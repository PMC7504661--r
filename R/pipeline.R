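# End-to-end orchestration: up-regulation calling -> activated TFs ->
# k-modes subgrouping -> upstream cascades -> perturbation factors -> drug
# and synergy mapping, with a manifest that makes the run reproducible
# (seeds, parameter echo, per-stage counts, output checksums).

#' Pipeline configuration
#'
#' Thresholds default to the analysis' standard settings: significance 0.05
#' for both the up-regulation and the enrichment gate, fold change 2, k = 3
#' subgroups, top 3 cascades per (pathway, TF), synergy score threshold 8
#' (strict). Inputs are given either as file paths (`inputs`) or as a
#' [simulation_config()] (`simulate`), exactly one of the two.
#'
#' @param inputs Named list of paths: `control`, `tumor`, `network`,
#'   `pathways` (directory of SIF files), `drugs`, `synergy`; or NULL.
#' @param simulate A [simulation_config()] used to generate inputs in
#'   memory; or NULL.
#' @param alpha Significance level for both gates, in (0, 1).
#' @param fold_threshold Fold-change gate (>= 1).
#' @param k Number of subgroups.
#' @param top_k Cascades kept per (pathway, TF).
#' @param synergy_threshold Synergy score cutoff (strict).
#' @param max_len Maximum cascade length in edges.
#' @param n_init k-modes restarts.
#' @param scale Expression file scale, `"linear"` or `"log2"`.
#' @param seed Integer seed governing MCMC and clustering restarts.
#' @param mcmc An [mcmc_settings()]; defaults to the stock sampler settings
#'   with the pipeline seed.
#' @param zero_var Zero-variance control policy, `"error"` or `"jitter"`.
#' @return Validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL, alpha = 0.05,
                            fold_threshold = 2, k = 3, top_k = 3,
                            synergy_threshold = 8, max_len = 12L,
                            n_init = 10L, scale = c("linear", "log2"),
                            seed, mcmc = NULL,
                            zero_var = c("error", "jitter")) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  scale <- match.arg(scale)
  zero_var <- match.arg(zero_var)
  if (is.null(inputs) == is.null(simulate)) {
    stop("supply exactly one of 'inputs' (paths) or 'simulate' (a simulation_config)",
         call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("control", "tumor", "network", "pathways", "drugs", "synergy")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("'inputs' missing entries: ", paste(miss, collapse = ", "))
  }
  if (!is.null(simulate) && !inherits(simulate, "simulation_config")) {
    stop("'simulate' must be a simulation_config()")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(fold_threshold) || fold_threshold < 1) {
    stop("'fold_threshold' must be >= 1", call. = FALSE)
  }
  structure(list(inputs = inputs, simulate = simulate, alpha = alpha,
                 fold_threshold = fold_threshold,
                 k = assert_count(k, "k"), top_k = assert_count(top_k, "top_k"),
                 synergy_threshold = as.numeric(synergy_threshold),
                 max_len = assert_count(max_len, "max_len"),
                 n_init = assert_count(n_init, "n_init"), scale = scale,
                 seed = as.integer(seed),
                 mcmc = mcmc %||% mcmc_settings(seed = derive_seed(seed, 1L)),
                 zero_var = zero_var),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; a `simulate:` block is
#' passed to [simulation_config()]. Validation happens before any
#' computation.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    y$simulate <- do.call(simulation_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- simulate_study(config$simulate)
    return(sim)
  }
  paths <- config$inputs
  sifs <- sort(list.files(paths$pathways, pattern = "\\.sif$",
                          full.names = TRUE))
  if (!length(sifs)) stop("no .sif files under ", paths$pathways)
  list(control = read_expression_matrix(paths$control, config$scale),
       tumor = read_expression_matrix(paths$tumor, config$scale),
       network = read_regulatory_network(paths$network),
       pathways = lapply(sifs, read_pathway_sif),
       catalog = read_drug_catalog(paths$drugs),
       synergy = read_synergy_table(paths$synergy),
       truth = NULL)
}

#' Run the full pipeline
#'
#' Executes, in order: per-gene Bayesian null fits and up-regulation calls;
#' per-sample TF enrichment; k-modes subgrouping with center-sample
#' characterization; cascade enumeration, scoring and pruning per subgroup
#' (probabilities taken from the group's center sample); perturbation
#' factors per subgroup with a ranking over the shared genes; drug and
#' synergy mapping on the union of the subgroup networks. When `outdir` is
#' given, every stage output and a JSON manifest are written there.
#'
#' @param config A `pipeline_config` (or path to its YAML).
#' @param outdir Optional output directory.
#' @return List of stage results: `calls`, `activation`, `subgroups`,
#'   `tf_report`, `pca`, `cascades` (retained, per group), `networks` (per
#'   group), `comparison`, `pf` (per group), `ranking`, `drug_map`,
#'   `validated`, `target_ranking`, `truth` (when simulated), `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  inputs <- load_pipeline_inputs(config)
  universe <- rownames(inputs$control)

  calls <- call_upregulated(inputs$control, inputs$tumor,
                            settings = config$mcmc,
                            fold_threshold = config$fold_threshold,
                            alpha = config$alpha, zero_var = config$zero_var)
  models <- attr(calls, "models")

  act <- activation_matrix(calls, inputs$network, universe, config$alpha)
  binary <- binarize_profiles(act$p_values, config$alpha)

  groups <- kmodes_cluster(binary, k = config$k, n_init = config$n_init,
                           seed = derive_seed(config$seed, 3L))
  report <- subgroup_tf_report(groups)
  pca <- project_profiles_2d(binary)

  prob_all <- probability_matrix(models, inputs$tumor)
  cascades <- list(); networks <- list(); pf <- list()
  for (g in seq_len(groups$k)) {
    gname <- paste0("group", g)
    center <- groups$center_samples[[gname]]
    tfs <- groups$group_tf_sets[[gname]]
    probs <- prob_all[, center]
    cand <- collect_cascades(inputs$pathways, tfs, config$max_len)
    retained <- score_and_prune(cand, probs, config$top_k)
    cascades[[gname]] <- retained
    if (nrow(retained)) {
      net <- build_core_network(retained, inputs$pathways, tfs)
      networks[[gname]] <- net
      pf[[gname]] <- perturbation_factors(net, probs)
    }
  }
  comparison <- if (length(networks) >= 2L) compare_groups(networks) else NULL
  ranking <- if (!is.null(comparison)) rank_genes(pf, comparison$shared) else NULL

  # Drugs are mapped on the union of the subgroup networks.
  if (!length(networks)) {
    stop("no subgroup produced a core network (no cascades retained); ",
         "check that the pathways reach the activated TFs", call. = FALSE)
  }
  union_net <- union_core_networks(networks)
  drug_map <- map_drugs(union_net, inputs$catalog)
  validated <- filter_synergies(drug_map, inputs$synergy,
                                config$synergy_threshold)
  target_ranking <- rank_combination_targets(validated)

  manifest <- list(
    package = as.character(utils::packageVersion("oncocascade")),
    seed = config$seed,
    parameters = config[c("alpha", "fold_threshold", "k", "top_k",
                          "synergy_threshold", "max_len", "n_init", "scale")],
    counts = list(
      genes = length(universe),
      control_samples = ncol(inputs$control),
      tumor_samples = ncol(inputs$tumor),
      upregulated_calls = sum(calls$up),
      activated_tf_calls = sum(act$active),
      group_sizes = as.list(tabulate(groups$labels, groups$k)),
      cascades_retained = sum(vapply(cascades, nrow, integer(1))),
      drugs_mapped = length(unique(drug_map$drug)),
      validated_combinations = nrow(validated)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(calls = calls, activation = act, binary = binary,
                 subgroups = groups, tf_report = report, pca = pca,
                 cascades = cascades, networks = networks,
                 union_network = union_net, comparison = comparison,
                 pf = pf, ranking = ranking, drug_map = drug_map,
                 validated = validated, target_ranking = target_ranking,
                 truth = inputs$truth, manifest = manifest)
  if (!is.null(outdir)) {
    result$manifest <- write_pipeline_outputs(result, config, inputs, outdir)
  }
  result
}

write_pipeline_outputs <- function(result, config, inputs, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  calls <- result$calls; attr(calls, "models") <- NULL
  utils::write.table(calls, file.path(outdir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_matrix(result$activation$active,
                          file.path(outdir, "tf_active.tsv"))
  write_expression_matrix(result$activation$p_values,
                          file.path(outdir, "tf_pvalues.tsv"))
  utils::write.table(data.frame(sample = rownames(result$pca), result$pca),
                     file.path(outdir, "pca.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  groups_json <- list(k = result$subgroups$k,
                      labels = as.list(result$subgroups$labels),
                      centers = as.list(result$subgroups$center_samples),
                      group_tfs = result$subgroups$group_tf_sets,
                      shared_tfs = result$tf_report$shared,
                      unique_tfs = result$tf_report$unique_tfs,
                      cost = result$subgroups$cost)
  jsonlite::write_json(groups_json, file.path(outdir, "groups.json"),
                       auto_unbox = TRUE, digits = NA)
  for (gname in names(result$networks)) {
    write_core_network(result$networks[[gname]],
                       file.path(outdir, paste0(gname, "_network.graphml")))
  }
  if (!is.null(result$ranking)) {
    utils::write.table(result$ranking, file.path(outdir, "pf_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$drug_map, file.path(outdir, "drug_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$validated, file.path(outdir, "validated_combinations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$target_ranking, file.path(outdir, "target_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- result$manifest
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
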