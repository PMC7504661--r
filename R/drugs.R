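# Drug and drug-combination mapping onto core signaling networks: a drug is
# mapped when at least one of its catalog targets is a network gene;
# combinations from a synergy screen are "validated" when both members are
# mapped drugs and the combination score strictly exceeds the synergy
# threshold.

#' Map catalog drugs onto a core network
#'
#' A drug is mapped iff at least one of its targets is a node of the
#' network. Drug names are compared case-insensitively after trimming;
#' gene/target names are case-sensitive.
#'
#' @param network A `core_network`.
#' @param catalog A `drug_catalog` (columns `drug`, `target`).
#' @return data.frame with one row per matched (drug, target) pair: `drug`,
#'   `target`, `role` (the target's network role).
#' @export
map_drugs <- function(network, catalog) {
  hit <- catalog$target %in% network$nodes$name
  out <- data.frame(drug = catalog$drug[hit], target = catalog$target[hit],
                    stringsAsFactors = FALSE)
  out$role <- network$nodes$role[match(out$target, network$nodes$name)]
  out <- out[order(out$drug, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a synergy screen down to validated combinations
#'
#' Keeps records where both drugs are mapped onto the network and the
#' combination score strictly exceeds `threshold` (a score equal to the
#' threshold is excluded). Output rows are annotated with each member's
#' matched network targets and sorted by descending score within cell line.
#'
#' @param mapped Mapping table from [map_drugs()].
#' @param records Synergy data.frame (as from [read_synergy_table()];
#'   order-normalized pairs).
#' @param threshold Synergy score cutoff (default 8, strict).
#' @return data.frame with columns `drug1`, `drug2`, `targets1`, `targets2`
#'   (comma-joined matched targets), `score`, `cell_line`.
#' @export
filter_synergies <- function(mapped, records, threshold = 8) {
  records <- normalize_synergy(records)
  key <- function(x) tolower(trimws(x))
  target_of <- split(mapped$target, key(mapped$drug))
  keep <- key(records$drug1) %in% names(target_of) &
    key(records$drug2) %in% names(target_of) &
    records$score > threshold
  out <- records[keep, c("drug1", "drug2", "cell_line", "score"), drop = FALSE]
  out$targets1 <- vapply(key(out$drug1),
                         function(d) paste(sort(unique(target_of[[d]])), collapse = ","),
                         character(1), USE.NAMES = FALSE)
  out$targets2 <- vapply(key(out$drug2),
                         function(d) paste(sort(unique(target_of[[d]])), collapse = ","),
                         character(1), USE.NAMES = FALSE)
  out <- out[order(out$cell_line, -out$score, out$drug1, out$drug2),
             c("drug1", "drug2", "targets1", "targets2", "score", "cell_line"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank targets of validated synergistic combinations
#'
#' Targets are ranked by the number of validated combination rows they
#' appear in; each row contributes each of its listed targets once, even if
#' both combination members share the target. Ties are broken by target
#' name.
#'
#' @param validated Table from [filter_synergies()].
#' @param top_n Number of targets to return (default 10).
#' @return data.frame with `target`, `n_combinations`, `rank`.
#' @export
rank_combination_targets <- function(validated, top_n = 10) {
  if (!nrow(validated)) {
    return(data.frame(target = character(0), n_combinations = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  per_row <- lapply(seq_len(nrow(validated)), function(i) {
    unique(trimws(unlist(strsplit(
      c(validated$targets1[i], validated$targets2[i]), ",", fixed = TRUE))))
  })
  counts <- table(unlist(per_row))
  out <- data.frame(target = names(counts),
                    n_combinations = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_combinations, out$target), , drop = FALSE]
  out <- utils::head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
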