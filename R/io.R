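# Readers and writers for the pipeline's external formats: expression TSV,
# TF-target TSV, pathway SIF, drug-target TSV, synergy CSV, GraphML output.
# Gene/sample identifiers are opaque case-sensitive strings; orderings are
# canonicalized (sorted) on load so input order never leaks downstream.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Values must be dense and numeric: duplicate identifiers,
#' missing cells and non-numeric cells are hard errors (silent imputation
#' would corrupt the Bayesian null fitted downstream). Rows and columns are
#' sorted by identifier on load.
#'
#' @param path TSV file path.
#' @param scale `"linear"` (values used as-is) or `"log2"` (values are
#'   log2-transformed expression and are exponentiated on load, so all
#'   downstream fold-change and doubled-variable arithmetic happens on the
#'   linear scale).
#' @return Numeric matrix (genes x samples) with attribute `scale = "linear"`.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >= 1 sample column")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene rows in ", path, ": ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  samples <- colnames(df)[-1]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample columns in ", path, ": ",
         paste(utils::head(dup_s, 10L), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric expression values in column(s): ",
         paste(samples[bad], collapse = ", "), call. = FALSE)
  }
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s' in %s",
                 genes[idx[1]], samples[idx[2]], path), call. = FALSE)
  }
  rownames(mat) <- genes
  mat <- mat[order(genes), order(samples), drop = FALSE]
  if (scale == "log2") mat <- 2^mat
  attr(mat, "scale") <- "linear"
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix (genes x samples) with dimnames.
#' @param path Output TSV path.
#' @param scale If `"log2"`, values are log2-transformed before writing (the
#'   inverse of the reader's `scale = "log2"` handling).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (scale == "log2") mat <- log2(mat)
  # %.17g round-trips doubles exactly, so a written matrix reads back
  # bit-identical (up to the log2 transform).
  fmt <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  df <- data.frame(gene = rownames(mat), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-target regulatory network from TSV
#'
#' Two named columns, `tf` and `target`. Duplicate edges are an error.
#'
#' @param path TSV file path.
#' @return An object of class `regulatory_network`: list with `tfs`,
#'   `targets` (sorted character vectors) and `edges` (data.frame `tf`,
#'   `target`, sorted).
#' @export
read_regulatory_network <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% colnames(df))) {
    stop("regulatory network TSV needs columns 'tf' and 'target'")
  }
  regulatory_network(df$tf, df$target)
}

#' Construct a regulatory network from parallel TF/target vectors
#'
#' @param tf,target Character vectors of equal length, one edge per element.
#' @return A `regulatory_network` object.
#' @export
regulatory_network <- function(tf, target) {
  edges <- data.frame(tf = as.character(tf), target = as.character(target),
                      stringsAsFactors = FALSE)
  if (anyNA(edges) || any(edges$tf == "") || any(edges$target == "")) {
    stop("regulatory network edges must have nonempty tf and target")
  }
  if (anyDuplicated(edges)) {
    stop("duplicate TF-target edges: ",
         paste(utils::head(unique(paste(edges$tf[duplicated(edges)],
                                        edges$target[duplicated(edges)])), 5L),
               collapse = ", "))
  }
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(tfs = sort(unique(edges$tf)),
                 targets = sort(unique(edges$target)),
                 edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d TFs, %d targets, %d interactions\n",
              length(x$tfs), length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Write a regulatory network to TSV
#' @param network A `regulatory_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_regulatory_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

sif_relations <- c(activation = 1, inhibition = -1)

#' Construct a pathway graph
#'
#' A directed, signed gene graph. Edge signs are +1 (activation) or -1
#' (inhibition); self-loops are allowed, sign 0 is not.
#'
#' @param id Pathway identifier.
#' @param edges data.frame with columns `source`, `target`, `sign`.
#' @param name Human-readable pathway name (defaults to `id`).
#' @param nodes Optional extra (isolated) node names.
#' @return An object of class `pathway_graph` wrapping an igraph.
#' @export
pathway_graph <- function(id, edges, name = id, nodes = character(0)) {
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      sign = as.integer(edges$sign),
                      stringsAsFactors = FALSE)
  if (any(edges$source == "") || any(edges$target == "")) {
    stop("pathway node names must be nonempty")
  }
  if (!all(edges$sign %in% c(-1L, 1L))) {
    stop("edge signs must be +1 (activation) or -1 (inhibition)")
  }
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(edges$source, edges$target, nodes)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = all_nodes))
  structure(list(id = as.character(id), name = as.character(name),
                 nodes = all_nodes, edges = edges, graph = g),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s' (%s): %d nodes, %d signed edges\n",
              x$id, x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a pathway graph from an extended SIF file
#'
#' Each line is `source<TAB>relation<TAB>target` with relation one of
#' `activation` or `inhibition`. Any other relation, or a line without
#' exactly three fields, is an error.
#'
#' @param path SIF file path.
#' @param id Pathway identifier; defaults to the file name without extension.
#' @param name Pathway name; defaults to `id`.
#' @return A `pathway_graph`.
#' @export
read_pathway_sif <- function(path, id = NULL, name = NULL) {
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  name <- name %||% id
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty SIF file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop(sprintf("SIF line %d in %s does not have 3 tab-separated fields",
                 bad[1], path), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  unknown <- setdiff(unique(m[, 2]), names(sif_relations))
  if (length(unknown)) {
    stop("unknown SIF relation(s) ", paste(sQuote(unknown), collapse = ", "),
         "; accepted: ", paste(names(sif_relations), collapse = ", "),
         call. = FALSE)
  }
  pathway_graph(id, data.frame(source = m[, 1], target = m[, 3],
                               sign = unname(sif_relations[m[, 2]]),
                               stringsAsFactors = FALSE),
                name = name)
}

#' Write a pathway graph to SIF
#' @param pathway A `pathway_graph`.
#' @param path Output SIF path.
#' @return `path`, invisibly.
#' @export
write_pathway_sif <- function(pathway, path) {
  rel <- names(sif_relations)[match(pathway$edges$sign, sif_relations)]
  writeLines(paste(pathway$edges$source, rel, pathway$edges$target, sep = "\t"),
             path)
  invisible(path)
}

#' Read a drug-target catalog from TSV
#'
#' Two named columns, `drug` and `target`; (drug, target) pairs must be
#' unique. Drug names are matched case-insensitively downstream but stored
#' verbatim.
#'
#' @param path TSV file path.
#' @return data.frame of class `drug_catalog` with columns `drug`, `target`.
#' @export
read_drug_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("drug", "target") %in% colnames(df))) {
    stop("drug catalog TSV needs columns 'drug' and 'target'")
  }
  drug_catalog(df)
}

#' Construct a drug-target catalog
#' @param df data.frame with columns `drug`, `target`.
#' @return data.frame of class `drug_catalog`, sorted, unique pairs enforced.
#' @export
drug_catalog <- function(df) {
  df <- data.frame(drug = trimws(as.character(df$drug)),
                   target = trimws(as.character(df$target)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("duplicate (drug, target) pairs in catalog")
  df <- df[order(df$drug, df$target), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("drug_catalog", "data.frame")
  df
}

#' Write a drug-target catalog to TSV
#' @param catalog A `drug_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_drug_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-combination synergy table from CSV
#'
#' Requires columns `drug1`, `drug2`, `cell_line`, `score` (case-insensitive;
#' extra columns are kept). Each pair is order-normalized on load: `drug1` is
#' the lexicographically smaller name, and any paired companion columns
#' (names differing only in a trailing 1/2, e.g. `targets1`/`targets2`) are
#' swapped along, so `(A, B)` and `(B, A)` records compare equal.
#'
#' @param path CSV file path.
#' @return data.frame with normalized columns `drug1`, `drug2`, `cell_line`,
#'   `score` first.
#' @export
read_synergy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- tolower(colnames(df))
  need <- c("drug1", "drug2", "cell_line", "score")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("synergy CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$score)) stop("synergy scores must be numeric")
  normalize_synergy(df)
}

# Order-normalize drug pairs; swap any columns named <stem>1/<stem>2 together.
normalize_synergy <- function(df) {
  df$drug1 <- trimws(as.character(df$drug1))
  df$drug2 <- trimws(as.character(df$drug2))
  flip <- tolower(df$drug2) < tolower(df$drug1)
  if (any(flip)) {
    stems <- sub("1$", "", grep("1$", colnames(df), value = TRUE))
    stems <- stems[paste0(stems, "2") %in% colnames(df)]
    for (s in stems) {
      a <- paste0(s, "1"); b <- paste0(s, "2")
      tmp <- df[[a]][flip]
      df[[a]][flip] <- df[[b]][flip]
      df[[b]][flip] <- tmp
    }
  }
  front <- c("drug1", "drug2", "cell_line", "score")
  df <- df[, c(front, setdiff(colnames(df), front)), drop = FALSE]
  df <- df[order(df$cell_line, -df$score, df$drug1, df$drug2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a synergy table to CSV
#' @param df Synergy data.frame (as from [read_synergy_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synergy_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
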