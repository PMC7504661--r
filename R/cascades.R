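# Upstream signaling reconstruction: start-node detection, exhaustive
# simple-path enumeration from pathway start genes to an activated TF,
# cascade scoring by the mean up-regulation probability of member genes,
# top-k pruning per (pathway, TF), and merging of retained cascades into a
# core signaling network with node roles.

#' Start nodes of a pathway graph
#'
#' Nodes with in-degree 0. A fully cyclic pathway has none; in that case the
#' members of "source" strongly connected components (components with no
#' incoming edge from outside themselves) are used instead, with a warning.
#'
#' @param pathway A `pathway_graph`.
#' @return Sorted character vector of start-node names.
#' @export
start_nodes <- function(pathway) {
  g <- pathway$graph
  if (igraph::vcount(g) == 0L) stop("empty pathway graph", call. = FALSE)
  indeg <- igraph::degree(g, mode = "in")
  starts <- names(indeg)[indeg == 0L]
  if (!length(starts)) {
    comp <- igraph::components(g, mode = "strong")
    cond <- igraph::contract(g, comp$membership)
    cond <- igraph::simplify(cond, remove.loops = TRUE)
    src <- which(igraph::degree(cond, mode = "in") == 0L)
    starts <- names(comp$membership)[comp$membership %in% src]
    warning(sprintf("pathway '%s' has no in-degree-0 node; using %d source-component node(s) as starts",
                    pathway$id, length(starts)), call. = FALSE)
  }
  sort(starts)
}

#' Enumerate signaling cascades from start nodes to a TF
#'
#' All simple directed paths from any start node to the TF with at most
#' `max_len` edges, in deterministic (lexicographic by node sequence) order.
#'
#' @param pathway A `pathway_graph`.
#' @param starts Character vector of start nodes (typically [start_nodes()]).
#' @param tf Target TF; must be a node of the pathway.
#' @param max_len Maximum path length in edges (default 12), capping the
#'   combinatorial explosion of simple paths.
#' @param budget Hard cap on the number of enumerated paths per
#'   (pathway, TF) pair; exceeding it is an error, prompting a smaller
#'   `max_len`.
#' @return List of character vectors (node sequences, start first, TF last).
#' @export
enumerate_cascades <- function(pathway, starts, tf, max_len = 12L,
                               budget = 1e5) {
  g <- pathway$graph
  if (!tf %in% pathway$nodes) {
    stop(sprintf("TF '%s' is not a node of pathway '%s'", tf, pathway$id),
         call. = FALSE)
  }
  starts <- intersect(starts, pathway$nodes)
  paths <- list()
  for (s in starts) {
    if (s == tf) next
    ps <- igraph::all_simple_paths(g, from = s, to = tf, mode = "out",
                                   cutoff = max_len)
    paths <- c(paths, lapply(ps, function(p) names(p)))
    if (length(paths) > budget) {
      stop(sprintf("path budget exceeded (> %g paths) for TF '%s' in pathway '%s'; lower max_len",
                   budget, tf, pathway$id), call. = FALSE)
    }
  }
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(keys)]
}

#' Score cascades and keep the top k per (pathway, TF)
#'
#' A cascade's score is the arithmetic mean of the up-regulation
#' probabilities of all its member genes (start, transduction genes and the
#' TF alike). Within each (pathway, TF) pair the `top_k` highest-scoring
#' cascades are retained to keep the merged network small; ties are broken
#' toward the shorter path, then lexicographically.
#'
#' @param cascades data.frame with columns `pathway`, `tf` and a list-column
#'   `nodes` (as assembled by the pipeline), or a list of such rows.
#' @param probabilities Named numeric vector, gene -> probability in
#'   `[0, 1]`. A cascade gene without an entry gets probability 0, with a
#'   warning.
#' @param top_k Cascades retained per (pathway, TF) pair (default 3).
#' @return data.frame of class `cascade_set` with columns `pathway`, `tf`,
#'   `nodes` (list), `length` (edges), `score`, sorted by pathway, tf,
#'   descending score.
#' @export
score_and_prune <- function(cascades, probabilities, top_k = 3) {
  if (!nrow(cascades)) {
    out <- cascades
    out$length <- integer(0); out$score <- numeric(0)
    class(out) <- c("cascade_set", "data.frame")
    return(out)
  }
  all_genes <- unique(unlist(cascades$nodes))
  missing <- setdiff(all_genes, names(probabilities))
  if (length(missing)) {
    warning("no probability for gene(s) ",
            paste(utils::head(missing, 5L), collapse = ", "),
            "; treated as 0", call. = FALSE)
    probabilities[missing] <- 0
  }
  cascades$score <- vapply(cascades$nodes,
                           function(nd) mean(probabilities[nd]),
                           numeric(1))
  cascades$length <- lengths(cascades$nodes) - 1L
  key <- vapply(cascades$nodes, paste, character(1), collapse = "\r")
  ord <- order(cascades$pathway, cascades$tf, -cascades$score,
               cascades$length, key)
  cascades <- cascades[ord, , drop = FALSE]
  grp <- paste(cascades$pathway, cascades$tf, sep = "\r")
  keep <- stats::ave(seq_along(grp), grp, FUN = seq_along) <= top_k
  out <- cascades[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cascade_set", "data.frame")
  out
}

#' Assemble a cascade table for a set of pathways and TFs
#'
#' Convenience wrapper: enumerates cascades from each pathway's start nodes
#' to each queried TF and stacks them into the data.frame consumed by
#' [score_and_prune()].
#'
#' @param pathways List of `pathway_graph` objects.
#' @param tfs Character vector of activated TFs to query.
#' @param max_len,budget Passed to [enumerate_cascades()].
#' @return data.frame with columns `pathway`, `tf`, `nodes` (list-column).
#' @export
collect_cascades <- function(pathways, tfs, max_len = 12L, budget = 1e5) {
  rows <- list()
  for (pw in pathways) {
    starts <- start_nodes(pw)
    for (tf in intersect(tfs, pw$nodes)) {
      paths <- enumerate_cascades(pw, starts, tf, max_len, budget)
      if (length(paths)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw$id, tf = tf, nodes = I(unname(paths)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pathway = character(0), tf = character(0),
                      nodes = I(list()), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge retained cascades into a core signaling network
#'
#' Unions the edges of all retained cascades, with signs looked up in the
#' source pathways. Node roles: `tf` for queried TFs, `start` for first
#' nodes of retained cascades that are not TFs, `transduction` otherwise.
#' Each merged edge carries provenance tags `"pathway/cascade-index"`; if
#' contributing pathways disagree on an edge's sign, both annotations are
#' kept and the edge is flagged.
#'
#' @param retained A `cascade_set` from [score_and_prune()]; must be
#'   nonempty.
#' @param pathways List of `pathway_graph` objects covering every retained
#'   cascade's pathway id.
#' @param tfs Character vector of queried TFs.
#' @return A [core_network()].
#' @export
build_core_network <- function(retained, pathways, tfs) {
  if (!nrow(retained)) stop("no retained cascades to merge", call. = FALSE)
  names(pathways) <- vapply(pathways, `[[`, character(1), "id")
  missing <- setdiff(unique(retained$pathway), names(pathways))
  if (length(missing)) stop("pathway(s) not supplied: ",
                            paste(missing, collapse = ", "))
  edge_rows <- list()
  for (i in seq_len(nrow(retained))) {
    nd <- retained$nodes[[i]]
    pw <- pathways[[retained$pathway[i]]]
    pe <- pw$edges
    for (j in seq_len(length(nd) - 1L)) {
      hit <- which(pe$source == nd[j] & pe$target == nd[j + 1L])
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        source = nd[j], target = nd[j + 1L], sign = pe$sign[hit[1]],
        tag = sprintf("%s/%d", retained$pathway[i], i),
        stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, edge_rows)
  key <- paste(raw$source, raw$target, sep = "\r")
  agg <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    signs <- unique(raw$sign[idx])
    data.frame(source = raw$source[idx[1]], target = raw$target[idx[1]],
               sign = signs[1],
               provenance = I(list(unique(raw$tag[idx]))),
               sign_conflict = length(signs) > 1L,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, agg)
  first_nodes <- unique(vapply(retained$nodes, `[[`, character(1), 1L))
  node_names <- sort(unique(unlist(retained$nodes)))
  role <- ifelse(node_names %in% tfs, "tf",
                 ifelse(node_names %in% first_nodes, "start", "transduction"))
  core_network(data.frame(name = node_names, role = role,
                          stringsAsFactors = FALSE),
               edges)
}

#' Compare core networks across subgroups
#'
#' @param networks Named list of >= 2 `core_network` objects (one per
#'   subgroup).
#' @return List with `shared` (genes in every network), `unique_genes` and
#'   `unique_tfs` (per network, genes/TFs present in that network only).
#' @export
compare_groups <- function(networks) {
  if (length(networks) < 2L) stop("need >= 2 core networks to compare")
  gene_sets <- lapply(networks, function(n) n$nodes$name)
  tf_sets <- lapply(networks, function(n) n$nodes$name[n$nodes$role == "tf"])
  shared <- sort(Reduce(intersect, gene_sets))
  uniq <- lapply(seq_along(networks), function(i) {
    sort(setdiff(gene_sets[[i]], unique(unlist(gene_sets[-i]))))
  })
  uniq_tf <- lapply(seq_along(networks), function(i) {
    sort(setdiff(tf_sets[[i]], unique(unlist(tf_sets[-i]))))
  })
  names(uniq) <- names(uniq_tf) <- names(networks)
  list(shared = shared, unique_genes = uniq, unique_tfs = uniq_tf)
}
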