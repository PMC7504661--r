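# Patient stratification on binary activated-TF profiles: k-modes clustering
# with Hamming dissimilarity, subgroup characterization by the center sample
# (the member closest to its cluster mode), and a 2-D PCA projection of the
# binary profiles for visualization coordinates.

#' Binarize a TF p-value matrix at a significance threshold
#'
#' @param p_values Numeric matrix of p-values in `[0, 1]` (samples x TFs).
#' @param alpha Threshold; entries with `p <= alpha` become 1 (inclusive,
#'   matching the activation gate).
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize_profiles <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  (p_values <= alpha) + 0L
}

# Hamming distances from every row of x to each mode (rows of modes).
hamming_to_modes <- function(x, modes) {
  # (x - m)^2 summed over columns equals the Hamming distance for 0/1 data.
  d <- matrix(0L, nrow(x), nrow(modes))
  for (j in seq_len(nrow(modes))) {
    d[, j] <- rowSums(x != matrix(modes[j, ], nrow(x), ncol(x), byrow = TRUE))
  }
  d
}

# Column-wise majority vector of a 0/1 matrix; ties go to 1 (deterministic).
majority_mode <- function(x) {
  as.integer(colSums(x) * 2L >= nrow(x))
}

# Huang-style density initialization: samples scored by the summed frequency
# of their own category per column; the k highest-scoring distinct rows seed
# the modes.
huang_init <- function(x, k) {
  freq1 <- colMeans(x)
  dens <- x %*% freq1 + (1 - x) %*% (1 - freq1)
  ord <- order(-dens, rownames(x))
  seen <- character(0)
  pick <- integer(0)
  for (i in ord) {
    key <- paste(x[i, ], collapse = "")
    if (!key %in% seen) {
      seen <- c(seen, key)
      pick <- c(pick, i)
      if (length(pick) == k) break
    }
  }
  x[pick, , drop = FALSE]
}

# Distinct rows of x as a matrix (first occurrence kept).
distinct_rows <- function(x) {
  x[!duplicated(apply(x, 1L, paste, collapse = "")), , drop = FALSE]
}

kmodes_once <- function(x, modes, max_iter = 100L) {
  n <- nrow(x); k <- nrow(modes)
  labels <- rep(0L, n)
  prev_cost <- Inf
  for (iter in seq_len(max_iter)) {
    d <- hamming_to_modes(x, modes)
    labels <- max.col(-d, ties.method = "first")
    # Re-seed any emptied cluster with the sample farthest from its mode;
    # the cost monotonicity guarantee restarts after a re-seed.
    empty <- which(tabulate(labels, k) == 0L)
    for (g in empty) {
      far <- which.max(d[cbind(seq_len(n), labels)])
      modes[g, ] <- x[far, ]
      labels[far] <- g
    }
    if (length(empty)) prev_cost <- Inf
    for (g in seq_len(k)) {
      modes[g, ] <- majority_mode(x[labels == g, , drop = FALSE])
    }
    cost <- sum(hamming_to_modes(x, modes)[cbind(seq_len(n), labels)])
    if (cost > prev_cost + 1e-9) {
      stop("internal error: k-modes cost increased across an iteration")
    }
    if (cost == prev_cost) break
    prev_cost <- cost
  }
  # Final assignment consistent with the final modes.
  d <- hamming_to_modes(x, modes)
  labels <- max.col(-d, ties.method = "first")
  cost <- sum(d[cbind(seq_len(n), labels)])
  list(labels = labels, modes = modes, cost = cost)
}

#' k-modes clustering of binary activation profiles
#'
#' Standard k-modes: Hamming dissimilarity, cluster modes updated as
#' per-column majority vectors, assignment ties broken toward the
#' lowest-numbered cluster. One run starts from Huang density-based seeding;
#' `n_init - 1` further runs start from random distinct rows; the lowest-cost
#' run wins. Groups are renumbered by descending size (ties by the group's
#' lexicographically smallest sample id) so reports are stable.
#'
#' @param x Binary matrix (samples x TFs) with sample rownames.
#' @param k Number of clusters; must not exceed the number of distinct rows.
#' @param n_init Number of initializations (>= 1).
#' @param seed Integer seed for the random restarts.
#' @param max_iter Iteration cap per run.
#' @return Object of class `subgroup_result`: `k`, `labels` (named integer
#'   vector), `modes` (k x TFs binary matrix), `center_samples`,
#'   `group_tf_sets` (active TFs of each center sample), `cost`, `seed`,
#'   `n_init`.
#' @export
kmodes_cluster <- function(x, k = 3, n_init = 10, seed, max_iter = 100L) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  k <- assert_count(k, "k")
  n_init <- assert_count(n_init, "n_init")
  if (is.null(rownames(x))) stop("'x' must have sample rownames")
  storage.mode(x) <- "integer"
  distinct <- distinct_rows(x)
  if (k > nrow(distinct)) {
    stop(sprintf("k = %d exceeds the number of distinct profiles (%d)",
                 k, nrow(distinct)), call. = FALSE)
  }
  set.seed(derive_seed(seed, 11L))
  best <- NULL
  for (run in seq_len(n_init)) {
    modes <- if (run == 1L) huang_init(x, k)
             else distinct[sample.int(nrow(distinct), k), , drop = FALSE]
    fit <- kmodes_once(x, modes, max_iter)
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  # Canonical group order: descending size, then smallest member sample id.
  sizes <- tabulate(best$labels, k)
  first_id <- vapply(seq_len(k),
                     function(g) min(rownames(x)[best$labels == g]),
                     character(1))
  ord <- order(-sizes, first_id)
  relabel <- match(seq_len(k), ord)
  labels <- relabel[best$labels]
  names(labels) <- rownames(x)
  modes <- best$modes[ord, , drop = FALSE]
  rownames(modes) <- paste0("group", seq_len(k))
  colnames(modes) <- colnames(x)
  res <- structure(list(k = k, labels = labels, modes = modes,
                        center_samples = NULL, group_tf_sets = NULL,
                        cost = best$cost, seed = as.integer(seed),
                        n_init = n_init),
                   class = "subgroup_result")
  res$center_samples <- vapply(seq_len(k), function(g) center_sample(x, res, g),
                               character(1))
  names(res$center_samples) <- rownames(modes)
  res$group_tf_sets <- lapply(res$center_samples, function(s) {
    colnames(x)[x[s, ] == 1L]
  })
  res
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("subgroup_result: k = %d, cost = %d, sizes = %s\n", x$k,
              x$cost, paste(tabulate(x$labels, x$k), collapse = "/")))
  cat("  centers:", paste(x$center_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Center sample of a subgroup
#'
#' The group member with minimum Hamming distance to the group's mode; ties
#' are broken by lexicographic sample id. The center sample's activated TFs
#' characterize the subgroup.
#'
#' @param x Binary matrix used for clustering.
#' @param result A `subgroup_result`.
#' @param group Group number in `1..k`.
#' @return The center sample id.
#' @export
center_sample <- function(x, result, group) {
  members <- names(result$labels)[result$labels == group]
  if (!length(members)) stop("group ", group, " is empty", call. = FALSE)
  mode <- result$modes[group, ]
  d <- rowSums(x[members, , drop = FALSE] !=
                 matrix(mode, length(members), ncol(x), byrow = TRUE))
  members[order(d, members)][1]
}

#' Shared and group-specific TF report
#'
#' Each group's TF set is the activated-TF set of its center sample; `shared`
#' is the intersection across groups and each group's `unique` set is its
#' difference against the union of the other groups.
#'
#' @param result A `subgroup_result`.
#' @return List with `shared`, `group_tfs` (list per group) and
#'   `unique_tfs` (list per group).
#' @export
subgroup_tf_report <- function(result) {
  sets <- result$group_tf_sets
  shared <- Reduce(intersect, sets)
  uniq <- lapply(seq_along(sets), function(g) {
    setdiff(sets[[g]], unique(unlist(sets[-g])))
  })
  names(uniq) <- names(sets)
  list(shared = sort(shared), group_tfs = sets, unique_tfs = uniq)
}

#' 2-D PCA projection of binary profiles
#'
#' Coordinates of the samples on the first two principal components of the
#' column-centered binary matrix (for plotting subgroup structure; the
#' plotting itself is left to the caller).
#'
#' @param x Binary matrix (samples x TFs), >= 2 samples.
#' @return data.frame with rownames = samples and columns `PC1`, `PC2`, plus
#'   attribute `"sdev"` carrying all singular-value-derived component sds.
#' @export
project_profiles_2d <- function(x) {
  if (nrow(x) < 2L) stop("need >= 2 samples for a 2-D projection")
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) stop("profiles have rank 0 (all identical)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(coords) < 2L) coords <- cbind(coords, PC2 = 0)
  out <- as.data.frame(coords[, 1:2, drop = FALSE])
  colnames(out) <- c("PC1", "PC2")
  attr(out, "sdev") <- pc$sdev
  out
}
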