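chain_pathway <- function(id = "chain") {
  pathway_graph(id, data.frame(source = c("A", "B"), target = c("B", "C"),
                               sign = c(1L, 1L)))
}

test_that("start nodes are the in-degree-zero genes", {
  expect_identical(start_nodes(chain_pathway()), "A")
  two_roots <- pathway_graph("p", data.frame(source = c("A", "B"),
                                             target = c("C", "C"),
                                             sign = c(1L, -1L)))
  expect_identical(start_nodes(two_roots), c("A", "B"))
})

test_that("start nodes match a brute-force in-degree scan on random DAGs", {
  set.seed(31)
  for (rep in 1:30) {
    el <- random_dag(sample(4:10, 1), 0.3)
    if (!nrow(el)) next
    el$sign <- 1L
    pw <- pathway_graph("r", el)
    manual <- sort(setdiff(unique(c(el$source, el$target)), el$target))
    expect_identical(start_nodes(pw), manual)
  }
})

test_that("fully cyclic pathways fall back to source components with a warning", {
  cyc <- pathway_graph("cyc", data.frame(source = c("A", "B", "C"),
                                         target = c("B", "C", "A"),
                                         sign = 1L))
  expect_warning(s <- start_nodes(cyc), "source-component")
  expect_setequal(s, c("A", "B", "C"))
})

test_that("cascade enumeration handles unreachable TFs and diamonds", {
  pw <- pathway_graph("p", data.frame(source = c("A", "A", "B", "C", "X"),
                                      target = c("B", "C", "D", "D", "Y"),
                                      sign = 1L))
  expect_length(enumerate_cascades(pw, "A", "Y"), 0)
  paths <- enumerate_cascades(pw, "A", "D")
  expect_length(paths, 2)
  expect_identical(paths[[1]], c("A", "B", "D"))
  expect_identical(paths[[2]], c("A", "C", "D"))
  expect_error(enumerate_cascades(pw, "A", "ZZ"), "not a node")
})

test_that("enumeration equals exhaustive DFS on random graphs", {
  set.seed(32)
  for (rep in 1:40) {
    el <- random_edgelist(sample(5:12, 1), 0.25)
    if (!nrow(el)) next
    el$sign <- 1L
    pw <- pathway_graph("r", el)
    nodes <- pw$nodes
    from <- sample(nodes, 1)
    to <- sample(setdiff(nodes, from), 1)
    got <- enumerate_cascades(pw, from, to, max_len = 12)
    want <- dfs_simple_paths(pw$edges, from, to, max_len = 12)
    expect_identical(got, want)
  }
})

test_that("the max_len cap restricts enumerated path length", {
  el <- data.frame(source = c("A", "B", "C", "A"),
                   target = c("B", "C", "D", "D"), sign = 1L)
  pw <- pathway_graph("p", el)
  expect_length(enumerate_cascades(pw, "A", "D", max_len = 1), 1)
  expect_length(enumerate_cascades(pw, "A", "D", max_len = 3), 2)
})

test_that("cascade scores are the arithmetic mean of member probabilities", {
  cc <- data.frame(pathway = "p1", tf = "T",
                   nodes = I(list(c("a", "b", "T"))))
  probs <- c(a = 0.9, b = 0.8, T = 0.7)
  scored <- score_and_prune(cc, probs)
  expect_equal(scored$score, 0.8)
  expect_equal(scored$length, 2L)
})

test_that("a lone cascade is retained regardless of score", {
  cc <- data.frame(pathway = "p1", tf = "T", nodes = I(list(c("a", "T"))))
  scored <- score_and_prune(cc, c(a = 0, T = 0))
  expect_equal(nrow(scored), 1)
})

test_that("missing probabilities warn and count as zero", {
  cc <- data.frame(pathway = "p1", tf = "T", nodes = I(list(c("a", "T"))))
  expect_warning(scored <- score_and_prune(cc, c(a = 0.5)), "treated as 0")
  expect_equal(scored$score, 0.25)
})

test_that("pruning equals brute-force sort-and-take-top-k and is order-invariant", {
  set.seed(33)
  genes <- paste0("g", 1:15)
  probs <- stats::setNames(runif(16), c(genes, "T"))
  paths <- lapply(1:10, function(i) {
    c(sample(genes, sample(2:4, 1)), "T")
  })
  cc <- data.frame(pathway = "p1", tf = "T", nodes = I(paths))
  got <- score_and_prune(cc, probs, top_k = 3)
  # Brute force: score all, sort by (-score, length, lexicographic), take 3.
  sc <- vapply(paths, function(p) mean(probs[p]), numeric(1))
  len <- lengths(paths) - 1
  key <- vapply(paths, paste, character(1), collapse = "\r")
  want <- paths[order(-sc, len, key)][1:3]
  expect_identical(unclass(got$nodes), want)
  # Shuffling the input rows leaves the retained set unchanged.
  perm <- sample(nrow(cc))
  got2 <- score_and_prune(cc[perm, ], probs, top_k = 3)
  expect_identical(unclass(got2$nodes), unclass(got$nodes))
})

test_that("raising a member gene's probability never lowers its cascade's rank", {
  probs <- c(a = 0.2, b = 0.4, c = 0.9, T = 0.5)
  cc <- data.frame(pathway = "p", tf = "T",
                   nodes = I(list(c("a", "T"), c("b", "T"), c("c", "T"))))
  before <- score_and_prune(cc, probs, top_k = 3)
  rank_before <- which(vapply(before$nodes, `[[`, character(1), 1) == "a")
  probs["a"] <- 0.95
  after <- score_and_prune(cc, probs, top_k = 3)
  rank_after <- which(vapply(after$nodes, `[[`, character(1), 1) == "a")
  expect_lte(rank_after, rank_before)
  expect_true(all(before$score >= 0 & before$score <= 1))
})

test_that("merged networks assign roles and deduplicate shared edges", {
  pw <- pathway_graph("p1", data.frame(source = c("A", "B", "A", "C"),
                                       target = c("B", "T", "C", "T"),
                                       sign = c(1L, -1L, 1L, 1L)))
  cc <- data.frame(pathway = "p1", tf = "T",
                   nodes = I(list(c("A", "B", "T"), c("A", "C", "T"))))
  scored <- score_and_prune(cc, c(A = 0.9, B = 0.5, C = 0.4, T = 0.8))
  net <- build_core_network(scored, list(pw), tfs = "T")
  roles <- stats::setNames(net$nodes$role, net$nodes$name)
  expect_identical(roles[["A"]], "start")
  expect_identical(roles[["B"]], "transduction")
  expect_identical(roles[["T"]], "tf")
  # Shared edge A->B appears once; edge signs come from the pathway.
  expect_equal(nrow(net$edges), 4)
  expect_equal(net$edges$sign[net$edges$source == "B"], -1L)
  shared_edge <- net$edges[net$edges$source == "A" & net$edges$target == "B", ]
  expect_length(shared_edge$provenance[[1]], 1)
})

test_that("two cascades sharing an edge merge provenance on that edge", {
  pw1 <- pathway_graph("p1", data.frame(source = c("A", "B"),
                                        target = c("B", "T"), sign = 1L))
  cc <- data.frame(pathway = c("p1", "p1"), tf = c("T", "T"),
                   nodes = I(list(c("A", "B", "T"), c("A", "B", "T"))))
  # Duplicate retained cascades share both edges without duplication.
  scored <- score_and_prune(cc, c(A = 1, B = 1, T = 1), top_k = 3)
  net <- build_core_network(scored, list(pw1), tfs = "T")
  expect_equal(nrow(net$edges), 2)
})

test_that("retained cascades re-validate as simple paths in their pathway", {
  res <- zero_noise_run()
  ids <- vapply(res$truth$planted_cascades, `[[`, character(1), "pathway")
  for (gname in names(res$cascades)) {
    cc <- res$cascades[[gname]]
    for (i in seq_len(nrow(cc))) {
      nodes <- cc$nodes[[i]]
      expect_false(anyDuplicated(nodes) > 0)
      expect_identical(nodes[length(nodes)], cc$tf[i])
    }
  }
  # Zero noise: the merged networks equal the planted cascade unions.
  for (gname in names(res$networks)) {
    tfs <- res$subgroups$group_tf_sets[[gname]]
    planted <- Filter(function(p) p$tf %in% tfs, res$truth$planted_cascades)
    want_nodes <- sort(unique(unlist(lapply(planted, `[[`, "nodes"))))
    expect_identical(res$networks[[gname]]$nodes$name, want_nodes)
  }
})

test_that("group comparison reports shared and unique genes", {
  n1 <- core_network(data.frame(name = c("A", "B", "T1"),
                                role = c("start", "transduction", "tf")),
                     data.frame(source = c("A", "B"), target = c("B", "T1"),
                                sign = 1L))
  n2 <- core_network(data.frame(name = c("A", "C", "T2"),
                                role = c("start", "transduction", "tf")),
                     data.frame(source = c("A", "C"), target = c("C", "T2"),
                                sign = 1L))
  cmp <- compare_groups(list(g1 = n1, g2 = n2))
  expect_identical(cmp$shared, "A")
  expect_identical(cmp$unique_genes$g1, c("B", "T1"))
  expect_identical(cmp$unique_tfs$g2, "T2")
  cmp_same <- compare_groups(list(g1 = n1, g2 = n1))
  expect_identical(cmp_same$shared, sort(n1$nodes$name))
  expect_length(unlist(cmp_same$unique_genes), 0)
  n3 <- core_network(data.frame(name = c("X", "T3"), role = c("start", "tf")),
                     data.frame(source = "X", target = "T3", sign = 1L))
  expect_length(compare_groups(list(n1, n3))$shared, 0)
})
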