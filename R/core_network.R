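# The merged "core" signaling network: union of retained cascades, with node
# roles (start / transduction / tf, plus drug nodes on export) and per-edge
# provenance back to the contributing (pathway, cascade) pairs.

node_roles <- c("start", "transduction", "tf", "drug")

#' Construct a core signaling network
#'
#' @param nodes data.frame with columns `name`, `role`
#'   (role in start/transduction/tf/drug; roles partition the node set).
#' @param edges data.frame with columns `source`, `target`, `sign` and a
#'   list-column `provenance` of character vectors (`"pathway/cascade"` tags);
#'   an edge merged from pathways that disagree on sign carries every
#'   annotation and is flagged in `sign_conflict`.
#' @return Object of class `core_network`.
#' @export
core_network <- function(nodes, edges) {
  nodes <- data.frame(name = as.character(nodes$name),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$name)) stop("duplicate node names in core network")
  if (!all(nodes$role %in% node_roles)) {
    stop("node roles must be one of: ", paste(node_roles, collapse = ", "))
  }
  if (is.null(edges$provenance)) edges$provenance <- replicate(nrow(edges), character(0), simplify = FALSE)
  if (is.null(edges$sign_conflict)) edges$sign_conflict <- logical(nrow(edges))
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$name)
  if (length(missing)) stop("edge endpoints missing from node table: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = node_roles))
  cat(sprintf("core_network: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

core_network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "sign")],
    directed = TRUE,
    vertices = network$nodes)
}

#' Union several core networks into one
#'
#' Node and edge sets are unioned; a node that carries different roles in
#' different networks keeps the strongest one (tf > start > transduction).
#'
#' @param networks Nonempty list of `core_network` objects.
#' @return A `core_network`.
#' @export
union_core_networks <- function(networks) {
  if (!length(networks)) stop("need >= 1 network to union")
  nodes <- unique(do.call(rbind, lapply(networks, `[[`, "nodes")))
  pr <- c(tf = 1L, start = 2L, transduction = 3L, drug = 4L)
  nodes <- nodes[order(nodes$name, pr[nodes$role]), , drop = FALSE]
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  edges <- do.call(rbind, lapply(networks, function(n) {
    n$edges[, c("source", "target", "sign"), drop = FALSE]
  }))
  edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
  core_network(nodes, edges)
}

#' Write a core signaling network to GraphML plus a flat edge TSV
#'
#' Node roles are stored as a GraphML vertex attribute `role`; edge signs and
#' collapsed provenance tags as edge attributes. Drug annotations (as from
#' [map_drugs()]) attach each drug as a role-`drug` node with unsigned edges
#' to its matched targets.
#'
#' @param network A `core_network`.
#' @param path Output GraphML path; a sibling `<path>.edges.tsv` flat edge
#'   list is written alongside.
#' @param drug_annotations Optional data.frame from [map_drugs()].
#' @return `path`, invisibly.
#' @export
write_core_network <- function(network, path, drug_annotations = NULL) {
  nodes <- network$nodes
  edges <- network$edges[, c("source", "target", "sign"), drop = FALSE]
  edges$provenance <- vapply(network$edges$provenance, paste, character(1),
                             collapse = ";")
  if (!is.null(drug_annotations) && nrow(drug_annotations)) {
    drugs <- unique(drug_annotations$drug)
    nodes <- rbind(nodes, data.frame(name = drugs, role = "drug",
                                     stringsAsFactors = FALSE))
    dedges <- data.frame(source = drug_annotations$drug,
                         target = drug_annotations$target,
                         sign = 0L, provenance = "drug_catalog",
                         stringsAsFactors = FALSE)
    edges <- rbind(edges, dedges)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  utils::write.table(edges, paste0(path, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a core signaling network from GraphML
#'
#' Inverse of [write_core_network()]; drug nodes and their unsigned edges are
#' split back out into an annotation table.
#'
#' @param path GraphML path.
#' @return List with `network` (a `core_network`) and `drug_annotations`
#'   (data.frame `drug`, `target`, possibly empty).
#' @export
read_core_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  name_col <- if ("name" %in% colnames(vdf)) "name" else "id"
  nodes <- data.frame(name = as.character(vdf[[name_col]] %||% character(0)),
                      role = as.character(vdf$role %||% character(0)),
                      stringsAsFactors = FALSE)
  is_drug_edge <- if (nrow(edf)) edf$sign == 0 else logical(0)
  drug_ann <- data.frame(drug = edf$from[is_drug_edge],
                         target = edf$to[is_drug_edge],
                         stringsAsFactors = FALSE)
  core_edges <- edf[!is_drug_edge, , drop = FALSE]
  prov <- strsplit(core_edges$provenance %||% character(nrow(core_edges)), ";",
                   fixed = TRUE)
  net <- core_network(
    nodes[nodes$role != "drug", , drop = FALSE],
    data.frame(source = core_edges$from, target = core_edges$to,
               sign = as.integer(core_edges$sign),
               provenance = I(prov), stringsAsFactors = FALSE))
  list(network = net, drug_annotations = drug_ann)
}
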