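# Seeded synthetic-data generator. Produces every input the pipeline
# consumes -- control/tumor expression, a bipartite TF-target network, signed
# pathway graphs, a drug-target catalog and a synergy screen -- together with
# the planted ground truth (up-regulated genes, subgroup labels, active TFs,
# cascades, synergistic pairs) used by recovery tests. All outputs are pure
# functions of (config, seed).

#' Simulation configuration
#'
#' Scales default to a reduced-size mirror of a tumor-cohort study: 88
#' normal controls, a tumor cohort split into 3 subgroups, a TF-target
#' network an order of magnitude smaller than a TRANSFAC-derived one, and a
#' handful of signed pathways.
#'
#' @param n_normal Number of control samples (default 88).
#' @param n_tumor Number of tumor samples.
#' @param n_genes Number of non-TF genes (TFs are additional expression
#'   rows, so the expression matrix has `n_genes + n_tfs` genes).
#' @param n_tfs Number of transcription factors.
#' @param targets_per_tf Range `c(lo, hi)` of targets per TF.
#' @param n_subgroups Number of planted patient subgroups (default 3).
#' @param active_tfs_per_group Planted active TFs per subgroup (disjoint
#'   across subgroups).
#' @param planted_fold Expected fold change of planted up-regulated genes
#'   (default 4); must exceed 2 so planted genes clear the fold-change gate
#'   in expectation.
#' @param noise_sd Multiplier on the per-gene expression sd (default 1;
#'   0 gives noiseless data for exact-recovery tests).
#' @param tf_flip_noise Probability that a group's active TF is dropped for
#'   an individual tumor sample (default 0).
#' @param n_pathways Number of pathway graphs.
#' @param cascade_length Range `c(lo, hi)` of planted cascade lengths, in
#'   edges.
#' @param n_shared_genes Number of backbone transduction genes inserted into
#'   every planted cascade (default 2), so the subgroup core networks share
#'   genes and the cross-group perturbation-factor ranking is non-trivial;
#'   capped at `cascade_length[1] - 1` interior slots.
#' @param n_drugs Number of drugs in the catalog.
#' @param synergy_fraction Probability that a screened pair scores above the
#'   synergy threshold of 8.
#' @param seed Integer master seed; every stage derives its own child seed.
#' @param group_props Subgroup proportions (default equal).
#' @param mu_range,sigma_range Hyper-ranges for the per-gene normal law:
#'   mean drawn uniformly from `mu_range` (default `[2, 10]`), sd from
#'   `sigma_range` (default `[0.5, 2]`), spanning weak to strong expression
#'   without degenerate variance.
#' @param scale Scale on which expression files are written: `"linear"`
#'   (default, the scale all arithmetic uses) or `"log2"` (values are
#'   log2-transformed on write and re-exponentiated on read).
#' @return Validated object of class `simulation_config`.
#' @export
simulation_config <- function(n_normal = 88, n_tumor = 60, n_genes = 240,
                              n_tfs = 12, targets_per_tf = c(8, 12),
                              n_subgroups = 3, active_tfs_per_group = 2,
                              planted_fold = 4, noise_sd = 1,
                              tf_flip_noise = 0, n_pathways = 4,
                              cascade_length = c(3, 5), n_shared_genes = 2,
                              n_drugs = 24,
                              synergy_fraction = 0.2, seed,
                              group_props = NULL,
                              mu_range = c(2, 10), sigma_range = c(0.5, 2),
                              scale = c("linear", "log2")) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  cfg <- list(
    n_normal = assert_count(n_normal, "n_normal"),
    n_tumor = assert_count(n_tumor, "n_tumor"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_tfs = assert_count(n_tfs, "n_tfs"),
    targets_per_tf = assert_range(targets_per_tf, "targets_per_tf"),
    n_subgroups = assert_count(n_subgroups, "n_subgroups"),
    active_tfs_per_group = assert_count(active_tfs_per_group, "active_tfs_per_group"),
    planted_fold = assert_pos(planted_fold, "planted_fold"),
    noise_sd = { if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0"); as.numeric(noise_sd) },
    tf_flip_noise = assert_prob(tf_flip_noise, "tf_flip_noise"),
    n_pathways = assert_count(n_pathways, "n_pathways"),
    cascade_length = assert_range(cascade_length, "cascade_length"),
    n_shared_genes = assert_count(n_shared_genes, "n_shared_genes", min = 0L),
    n_drugs = assert_count(n_drugs, "n_drugs"),
    synergy_fraction = assert_prob(synergy_fraction, "synergy_fraction"),
    seed = as.integer(seed),
    group_props = group_props %||% rep(1 / n_subgroups, n_subgroups),
    mu_range = as.numeric(mu_range),
    sigma_range = as.numeric(sigma_range),
    scale = match.arg(scale))
  if (cfg$planted_fold <= 2) {
    stop("'planted_fold' must exceed 2 so planted genes clear the fold-change gate",
         call. = FALSE)
  }
  if (length(cfg$group_props) != cfg$n_subgroups ||
      any(cfg$group_props <= 0)) {
    stop("'group_props' must be ", cfg$n_subgroups, " positive proportions")
  }
  cfg$group_props <- cfg$group_props / sum(cfg$group_props)
  if (cfg$n_tfs < cfg$n_subgroups * cfg$active_tfs_per_group) {
    stop("n_tfs must be >= n_subgroups * active_tfs_per_group", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

sim_gene_names <- function(config) sprintf("g%04d", seq_len(config$n_genes))
sim_tf_names <- function(config) sprintf("TF%02d", seq_len(config$n_tfs))

#' Simulate the bipartite TF-target regulatory network
#'
#' The first `n_subgroups * active_tfs_per_group` TFs are the planted active
#' TFs, assigned to subgroups in blocks. Active TFs receive mutually
#' disjoint target sets (so planted enrichment is unambiguous); the
#' remaining (decoy) TFs draw their targets from a separate gene pool that
#' never overlaps the active targets.
#'
#' @param config A [simulation_config()].
#' @return List with `network` (a `regulatory_network`) and `truth`
#'   (`active_tfs`: list group -> TF vector; `tf_targets`: list TF ->
#'   target vector).
#' @export
simulate_regulatory_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 21L))
  genes <- sim_gene_names(config)
  tfs <- sim_tf_names(config)
  n_active <- config$n_subgroups * config$active_tfs_per_group
  active <- tfs[seq_len(n_active)]
  active_by_group <- split(active, rep(seq_len(config$n_subgroups),
                                       each = config$active_tfs_per_group))
  names(active_by_group) <- paste0("group", seq_len(config$n_subgroups))
  n_targets <- resample(seq(config$targets_per_tf[1], config$targets_per_tf[2]),
                      config$n_tfs, replace = TRUE)
  names(n_targets) <- tfs
  pool <- sample(genes)
  need_active <- sum(n_targets[active])
  hi <- config$targets_per_tf[2]
  if (need_active + hi > length(pool)) {
    stop("infeasible target allocation: ", need_active + hi,
         " target genes needed but only ", length(pool), " available; ",
         "increase n_genes or reduce TF counts", call. = FALSE)
  }
  tf_targets <- vector("list", config$n_tfs)
  names(tf_targets) <- tfs
  at <- 0L
  for (tf in active) {
    tf_targets[[tf]] <- sort(pool[(at + 1L):(at + n_targets[tf])])
    at <- at + n_targets[tf]
  }
  # Decoy pool: a slice of the remaining genes, shared among decoy TFs.
  decoy_pool <- pool[(at + 1L):min(length(pool), at + max(4L * hi, 2L * hi))]
  for (tf in setdiff(tfs, active)) {
    tf_targets[[tf]] <- sort(sample(decoy_pool, n_targets[tf]))
  }
  edges_tf <- rep(tfs, times = lengths(tf_targets))
  network <- regulatory_network(edges_tf, unlist(tf_targets, use.names = FALSE))
  list(network = network,
       truth = list(active_tfs = active_by_group, tf_targets = tf_targets))
}

# Deterministic subgroup labels: multinomial draw from group_props, with any
# empty group back-filled so every planted group is realized.
sim_group_labels <- function(config) {
  set.seed(derive_seed(config$seed, 23L))
  labels <- sample.int(config$n_subgroups, config$n_tumor, replace = TRUE,
                       prob = config$group_props)
  for (g in which(tabulate(labels, config$n_subgroups) == 0L)) {
    donor <- which.max(tabulate(labels, config$n_subgroups))
    labels[which(labels == donor)[1]] <- g
  }
  names(labels) <- sprintf("T%03d", seq_len(config$n_tumor))
  labels
}

#' Simulate control and tumor expression matrices
#'
#' Every expression row (regular genes and TFs) gets a gene-specific normal
#' law `N(mu_g, noise_sd * sigma_g)` with `mu_g`, `sigma_g` drawn from the
#' configured hyper-ranges. Control samples are pure draws from that law.
#' Each tumor sample belongs to a planted subgroup; the targets of its
#' group's active TFs are drawn with mean `planted_fold * mu_g` (the same
#' sd), all other genes from the control law.
#'
#' @param config A [simulation_config()].
#' @param network_sim Optional output of [simulate_regulatory_network()];
#'   regenerated from `config` when omitted (all stages are deterministic in
#'   the config, so the result is identical).
#' @return List with `control` and `tumor` (numeric matrices, genes x
#'   samples) and `truth` (`upregulated`: list sample -> planted gene set;
#'   `subgroup_labels`; `active_tfs`; `sample_active_tfs` after flip noise;
#'   `mu`, `sigma` per gene).
#' @export
simulate_expression <- function(config, network_sim = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(network_sim)) network_sim <- simulate_regulatory_network(config)
  all_genes <- c(sim_tf_names(config), sim_gene_names(config))
  all_genes <- sort(all_genes)
  set.seed(derive_seed(config$seed, 22L))
  mu <- stats::runif(length(all_genes), config$mu_range[1], config$mu_range[2])
  sigma <- stats::runif(length(all_genes), config$sigma_range[1], config$sigma_range[2])
  names(mu) <- names(sigma) <- all_genes
  labels <- sim_group_labels(config)
  set.seed(derive_seed(config$seed, 24L))
  control <- matrix(stats::rnorm(length(all_genes) * config$n_normal,
                                 mean = mu, sd = config$noise_sd * sigma),
                    nrow = length(all_genes), ncol = config$n_normal,
                    dimnames = list(all_genes,
                                    sprintf("N%03d", seq_len(config$n_normal))))
  active_by_group <- network_sim$truth$active_tfs
  tf_targets <- network_sim$truth$tf_targets
  tumor <- matrix(NA_real_, length(all_genes), config$n_tumor,
                  dimnames = list(all_genes, names(labels)))
  sample_tfs <- vector("list", config$n_tumor)
  names(sample_tfs) <- names(labels)
  upregulated <- vector("list", config$n_tumor)
  names(upregulated) <- names(labels)
  for (s in names(labels)) {
    grp_tfs <- active_by_group[[labels[[s]]]]
    kept <- grp_tfs[stats::runif(length(grp_tfs)) >= config$tf_flip_noise]
    sample_tfs[[s]] <- kept
    planted <- sort(unique(unlist(tf_targets[kept])))
    upregulated[[s]] <- planted
    means <- mu
    means[planted] <- config$planted_fold * mu[planted]
    tumor[, s] <- stats::rnorm(length(all_genes), means,
                               config$noise_sd * sigma)
  }
  list(control = control, tumor = tumor,
       truth = list(upregulated = upregulated,
                    subgroup_labels = labels,
                    active_tfs = active_by_group,
                    sample_active_tfs = sample_tfs,
                    mu = mu, sigma = sigma))
}

#' Simulate signed pathway graphs with planted cascades
#'
#' Each pathway carries one planted simple path from a fresh start gene
#' through transduction genes to a planted active TF (TFs are cycled across
#' pathways so every subgroup's TFs receive cascades). Decoy branches hang
#' off the planted path but never reach the TF, so at zero noise the
#' planted cascade is the unique start-to-TF path. Pathway genes are drawn
#' from the genes no TF targets, so they are never up-regulated by
#' construction.
#'
#' @param config A [simulation_config()].
#' @param network_sim Output of [simulate_regulatory_network()];
#'   regenerated when omitted.
#' @return List with `pathways` (list of `pathway_graph`) and `truth`
#'   (`planted_cascades`: list of `list(pathway, nodes, tf)`).
#' @export
simulate_pathways <- function(config, network_sim = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(network_sim)) network_sim <- simulate_regulatory_network(config)
  active_by_group <- network_sim$truth$active_tfs
  if (!length(unlist(active_by_group))) {
    stop("no active TFs in the regulatory network")
  }
  # Interleave groups so every subgroup receives a cascade as early as
  # possible: group1-TF1, group2-TF1, ..., group1-TF2, group2-TF2, ...
  active <- as.vector(do.call(rbind, active_by_group))
  if (config$n_pathways < config$n_subgroups) {
    warning("n_pathways < n_subgroups: some subgroups will have no planted cascade",
            call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 25L))
  free <- setdiff(sim_gene_names(config), network_sim$network$targets)
  free <- sample(free)
  n_decoy <- 3L
  per_pw <- config$cascade_length[2] + n_decoy
  n_shared <- min(config$n_shared_genes, config$cascade_length[1] - 1L)
  if (length(free) < config$n_pathways * per_pw + n_shared) {
    stop("not enough untargeted genes for pathway construction; increase n_genes",
         call. = FALSE)
  }
  shared <- if (n_shared > 0L) free[seq_len(n_shared)] else character(0)
  pathways <- vector("list", config$n_pathways)
  planted <- vector("list", config$n_pathways)
  at <- n_shared
  for (p in seq_len(config$n_pathways)) {
    len <- resample(seq(config$cascade_length[1], config$cascade_length[2]), 1L)
    tf <- active[(p - 1L) %% length(active) + 1L]
    chain <- free[(at + 1L):(at + len)]  # start + (len - 1) transduction genes
    at <- at + len
    # Splice the shared backbone into the interior so subgroup networks
    # overlap; the start node stays pathway-specific.
    if (n_shared > 0L) {
      chain[1L + seq_len(min(n_shared, len - 1L))] <-
        shared[seq_len(min(n_shared, len - 1L))]
    }
    nodes <- c(chain, tf)
    edges <- data.frame(source = nodes[-length(nodes)],
                        target = nodes[-1],
                        sign = sample(c(1L, 1L, 1L, -1L), len, replace = TRUE),
                        stringsAsFactors = FALSE)
    decoys <- free[(at + 1L):(at + n_decoy)]
    at <- at + n_decoy
    # Decoy branches: path node -> decoy (dead end or short chain); decoys
    # never feed back into the planted path or the TF.
    anchor <- sample(chain, n_decoy, replace = TRUE)
    dedges <- data.frame(source = c(anchor[1], anchor[2], decoys[2]),
                         target = c(decoys[1], decoys[2], decoys[3]),
                         sign = sample(c(1L, -1L), 3L, replace = TRUE),
                         stringsAsFactors = FALSE)
    id <- sprintf("pw%02d", p)
    pathways[[p]] <- pathway_graph(id, rbind(edges, dedges),
                                   name = sprintf("synthetic pathway %d", p))
    planted[[p]] <- list(pathway = id, nodes = nodes, tf = tf)
  }
  list(pathways = pathways, truth = list(planted_cascades = planted))
}

#' Simulate a drug-target catalog and synergy screen
#'
#' Drugs are split into "network" drugs, whose targets include planted
#' cascade genes, and decoy drugs targeting only genes outside every
#' cascade. The screen covers pairs of network drugs on two synthetic cell
#' lines; each screened pair scores above the synergy threshold of 8 with
#' probability `synergy_fraction` (scores drawn from Unif(8.5, 40)), and
#' below it otherwise (Unif(-10, 7.5)).
#'
#' @param config A [simulation_config()].
#' @param pathway_sim Output of [simulate_pathways()]; regenerated when
#'   omitted.
#' @return List with `catalog` (a `drug_catalog`), `synergy` (normalized
#'   synergy data.frame) and `truth` (`synergy_pairs`: data.frame of
#'   records with score > 8; `network_drugs`).
#' @export
simulate_drug_screen <- function(config, pathway_sim = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(pathway_sim)) pathway_sim <- simulate_pathways(config)
  if (!length(pathway_sim$pathways)) stop("no pathways supplied")
  set.seed(derive_seed(config$seed, 26L))
  core_genes <- unique(unlist(lapply(pathway_sim$truth$planted_cascades,
                                     `[[`, "nodes")))
  outside <- setdiff(sim_gene_names(config), core_genes)
  drugs <- sprintf("drug%02d", seq_len(config$n_drugs))
  n_net <- max(2L, ceiling(0.7 * config$n_drugs))
  rows <- list()
  for (i in seq_len(config$n_drugs)) {
    if (i <= n_net) {
      targets <- sample(core_genes, min(sample(1:2, 1L), length(core_genes)))
      if (stats::runif(1) < 0.3) targets <- c(targets, sample(outside, 1L))
    } else {
      targets <- sample(outside, sample(1:2, 1L))
    }
    rows[[i]] <- data.frame(drug = drugs[i], target = unique(targets),
                            stringsAsFactors = FALSE)
  }
  catalog <- drug_catalog(do.call(rbind, rows))
  net_drugs <- drugs[seq_len(n_net)]
  pairs <- t(utils::combn(net_drugs, 2L))
  cell_lines <- c("CL1", "CL2")
  rec <- expand.grid(pair = seq_len(nrow(pairs)), cell_line = cell_lines,
                     stringsAsFactors = FALSE)
  hi <- stats::runif(nrow(rec)) < config$synergy_fraction
  score <- ifelse(hi, stats::runif(nrow(rec), 8.5, 40),
                  stats::runif(nrow(rec), -10, 7.5))
  synergy <- normalize_synergy(data.frame(
    drug1 = pairs[rec$pair, 1], drug2 = pairs[rec$pair, 2],
    cell_line = rec$cell_line, score = round(score, 2),
    stringsAsFactors = FALSE))
  truth_pairs <- synergy[synergy$score > 8,
                         c("drug1", "drug2", "cell_line", "score"),
                         drop = FALSE]
  rownames(truth_pairs) <- NULL
  list(catalog = catalog, synergy = synergy,
       truth = list(synergy_pairs = truth_pairs, network_drugs = net_drugs))
}

#' Run the full generator
#'
#' Composes the four simulation stages and merges their truth records.
#'
#' @param config A [simulation_config()].
#' @return List with `control`, `tumor`, `network`, `pathways`, `catalog`,
#'   `synergy` and `truth` (the union of all stage truths).
#' @export
simulate_study <- function(config) {
  net <- simulate_regulatory_network(config)
  expr <- simulate_expression(config, net)
  pw <- simulate_pathways(config, net)
  screen <- simulate_drug_screen(config, pw)
  list(control = expr$control, tumor = expr$tumor,
       network = net$network, pathways = pw$pathways,
       catalog = screen$catalog, synergy = screen$synergy,
       truth = c(expr$truth, list(tf_targets = net$truth$tf_targets),
                 pw$truth, screen$truth),
       config = config)
}

#' Write a simulated study to disk
#'
#' Writes `control.tsv`, `tumor.tsv`, `network.tsv`, `pathways/<id>.sif`,
#' `drugs.tsv`, `synergy.csv` and `truth.json` under `outdir`, in the
#' formats the corresponding readers expect. Expression is written on the
#' configured scale.
#'
#' @param sim Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "pathways"), showWarnings = FALSE)
  scale <- sim$config$scale
  write_expression_matrix(sim$control, file.path(outdir, "control.tsv"), scale)
  write_expression_matrix(sim$tumor, file.path(outdir, "tumor.tsv"), scale)
  write_regulatory_network(sim$network, file.path(outdir, "network.tsv"))
  for (pw in sim$pathways) {
    write_pathway_sif(pw, file.path(outdir, "pathways", paste0(pw$id, ".sif")))
  }
  write_drug_catalog(sim$catalog, file.path(outdir, "drugs.tsv"))
  write_synergy_table(sim$synergy, file.path(outdir, "synergy.csv"))
  truth <- sim$truth
  truth$subgroup_labels <- as.list(truth$subgroup_labels)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
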