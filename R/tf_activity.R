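# Activated-TF inference: a TF is called active in a sample when its target
# set is over-represented among the sample's up-regulated genes
# (one-sided hypergeometric / Fisher over-representation test).

#' TF target-set enrichment for one sample
#'
#' For each TF, tests whether its targets are over-represented in the
#' sample's up-regulated gene set. With universe size `N` (all genes tested,
#' i.e. the expression matrix), `K` targets of the TF inside the universe,
#' `m` up-regulated genes and `k` up-regulated targets, the p-value is the
#' hypergeometric upper tail `P(X >= k)`, `X ~ Hypergeom(N, K, m)`. Network
#' edges to genes outside the universe are dropped before counting.
#'
#' @param upregulated Character vector of up-regulated genes (must be a
#'   subset of `universe`).
#' @param universe Character vector of all genes tested; must be nonempty.
#' @param network A `regulatory_network`.
#' @param alpha Activation gate: active iff p-value <= `alpha` (default
#'   0.05, inclusive). No multiple-testing correction is applied.
#' @return data.frame with one row per TF (network order): `tf`, `k`, `K`,
#'   `m`, `N`, `p_value`, `active`.
#' @export
tf_enrichment <- function(upregulated, universe, network, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  upregulated <- unique(as.character(upregulated))
  out <- setdiff(upregulated, universe)
  if (length(out)) {
    stop("up-regulated genes outside the universe: ",
         paste(utils::head(out, 5L), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  m <- length(upregulated)
  tfs <- network$tfs
  res <- lapply(tfs, function(tf) {
    targets <- intersect(network$edges$target[network$edges$tf == tf], universe)
    K <- length(targets)
    k <- length(intersect(targets, upregulated))
    # Upper tail P(X >= k); k = 0 gives p = 1.
    p <- stats::phyper(k - 1L, K, N - K, m, lower.tail = FALSE)
    data.frame(tf = tf, k = k, K = K, m = m, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$active <- res$p_value <= alpha
  rownames(res) <- NULL
  res
}

#' Per-sample TF activation matrices
#'
#' Runs [tf_enrichment()] on every tumor sample's up-regulated gene set.
#'
#' @param calls Call table from [call_upregulated()] (columns `sample`,
#'   `gene`, `up`).
#' @param network A `regulatory_network`.
#' @param universe Character vector of all genes tested (typically the
#'   expression matrix's genes).
#' @param alpha Activation gate passed to [tf_enrichment()].
#' @return List with `active` (binary matrix, samples x TFs) and `p_values`
#'   (same shape). A sample with zero called genes yields a row of zeros.
#' @export
activation_matrix <- function(calls, network, universe, alpha = 0.05) {
  samples <- sort(unique(calls$sample))
  if (!length(samples)) stop("no samples in call table", call. = FALSE)
  tfs <- network$tfs
  pmat <- matrix(NA_real_, length(samples), length(tfs),
                 dimnames = list(samples, tfs))
  for (s in samples) {
    up <- calls$gene[calls$sample == s & calls$up]
    pmat[s, ] <- tf_enrichment(up, universe, network, alpha)$p_value
  }
  list(active = (pmat <= alpha) + 0L, p_values = pmat)
}
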