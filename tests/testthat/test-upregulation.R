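test_that("stock vague priors are accepted and are the defaults", {
  p <- prior_spec()
  expect_equal(p$w0, 0)
  expect_equal(p$v0, 1e4)
  expect_equal(p$a0, 1e-3)
  expect_equal(p$b0, 1e-3)
  expect_error(prior_spec(v0 = -1), "v0")
  expect_error(prior_spec(a0 = 0), "a0")
})

test_that("near-constant controls localize the posterior mean at the constant", {
  set.seed(2)
  ctrl <- rep(7, 30) + rnorm(30, 0, 1e-6)
  m <- fit_null_model(ctrl, settings = fast_mcmc(5))
  expect_lt(abs(mean(m$mu) - 7), 1e-2)
  expect_true(all(m$sigma2 > 0))
})

test_that("zero-variance controls error by default and jitter on request", {
  ctrl <- rep(3, 20)
  expect_error(fit_null_model(ctrl, settings = fast_mcmc(5)), "variance")
  expect_warning(m <- fit_null_model(ctrl, settings = fast_mcmc(5),
                                     zero_var = "jitter"), "jitter")
  expect_lt(abs(mean(m$mu) - 3), 1e-2)
})

test_that("posterior-predictive tails match the closed-form Student-t predictive", {
  set.seed(1)
  ctrl <- rnorm(88, 5, 1)
  m <- fit_null_model(ctrl, settings = mcmc_settings(predictive_draws = 20000,
                                                     seed = 99))
  n <- length(ctrl)
  scale <- sd(ctrl) * sqrt(1 + 1 / n)
  qs <- quantile(m$predictive, c(0.90, 0.95, 0.99))
  for (q in qs) {
    mcmc_tail <- mean(m$predictive >= q)
    t_tail <- pt((q - mean(ctrl)) / scale, df = n - 1, lower.tail = FALSE)
    expect_lt(abs(mcmc_tail - t_tail), 0.01)
  }
})

test_that("the doubled-density integrates to one and the model is well formed", {
  set.seed(3)
  m <- fit_null_model(rnorm(50, 4, 0.8), settings = fast_mcmc(7))
  total <- sum(diff(m$grid) * (head(m$density, -1) + tail(m$density, -1)) / 2)
  expect_lt(abs(total - 1), 1e-3)
  expect_true(all(m$density >= 0))
  expect_length(m$predictive, 2000)
  expect_true(all(m$sigma2 > 0))
})

test_that("doubled p-values equal the change-of-variables tail on raw draws", {
  set.seed(4)
  m <- fit_null_model(rnorm(88, 5, 1),
                      settings = mcmc_settings(predictive_draws = 20000,
                                               seed = 17))
  xs <- quantile(2 * m$predictive, c(0.25, 0.5, 0.75, 0.9, 0.95, 0.99))
  for (x in xs) {
    expect_lt(abs(pvalue_doubled(m, x) - mean(m$predictive >= x / 2)), 0.005)
  }
})

test_that("p-values hit the bounds outside the doubled support", {
  set.seed(5)
  m <- fit_null_model(rnorm(40, 6, 1), settings = fast_mcmc(9))
  expect_gt(pvalue_doubled(m, min(m$grid) - 10), 0.995)
  expect_equal(pvalue_doubled(m, max(m$grid) + 10), 0)
})

test_that("p-values are monotone non-increasing on a dense grid", {
  set.seed(6)
  m <- fit_null_model(rnorm(40, 6, 1), settings = fast_mcmc(9))
  xs <- seq(min(m$grid) - 1, max(m$grid) + 1, length.out = 500)
  p <- pvalue_doubled(m, xs)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(diff(gene_probability(m, xs)) >= -1e-12))
})

test_that("threshold inversion is consistent with the p-value", {
  set.seed(7)
  m <- fit_null_model(rnorm(88, 5, 1),
                      settings = mcmc_settings(predictive_draws = 8000,
                                               seed = 23))
  # alpha = 0.5 lands near the doubled median.
  expect_lt(abs(invert_threshold(m, 0.5) - median(2 * m$predictive)), 0.2)
  for (a in c(0.01, 0.05, 0.1)) {
    xstar <- invert_threshold(m, a)
    expect_lte(pvalue_doubled(m, xstar), a)
    # Tail mass just left of the threshold still exceeds alpha.
    left <- m$grid[max(which(m$grid < xstar))]
    expect_gt(pvalue_doubled(m, left), a)
  }
  expect_error(invert_threshold(m, 1.2), "alpha")
  # gene_probability at the 0.05 threshold is ~0.95 by complement.
  expect_lt(abs(gene_probability(m, invert_threshold(m, 0.05)) - 0.95), 0.01)
})

test_that("the tail mass beyond the 0.05 threshold is calibrated", {
  set.seed(8)
  m <- fit_null_model(rnorm(88, 5, 1),
                      settings = mcmc_settings(predictive_draws = 8000,
                                               seed = 31))
  xstar <- invert_threshold(m, 0.05)
  expect_lt(abs(pvalue_doubled(m, xstar) - 0.05), 0.005)
})

test_that("both gates are required to flag a gene", {
  # Tight controls: fold 2.1 is huge evidence, p ~ 0 -> flagged.
  # Wide controls: fold 2.1 is unremarkable, p large -> not flagged.
  set.seed(9)
  control <- rbind(tight = rnorm(60, 10, 0.05), wide = rnorm(60, 10, 4))
  colnames(control) <- sprintf("N%02d", 1:60)
  tumor <- cbind(T1 = c(tight = 2.1 * mean(control["tight", ]),
                        wide = 2.1 * mean(control["wide", ])))
  calls <- call_upregulated(control, tumor, settings = fast_mcmc(3))
  expect_true(calls$up[calls$gene == "tight"])
  expect_false(calls$up[calls$gene == "wide"])
  expect_gt(calls$p_value[calls$gene == "wide"], 0.05)
  # Equal to the control mean: fold gate fails everywhere.
  tumor0 <- cbind(T1 = rowMeans(control))
  calls0 <- call_upregulated(control, tumor0, settings = fast_mcmc(3))
  expect_false(any(calls0$up))
})

test_that("gene-set mismatches are rejected with the offenders named", {
  control <- matrix(rnorm(20, 5), 2, 10,
                    dimnames = list(c("gA", "gB"), sprintf("N%02d", 1:10)))
  tumor <- matrix(rnorm(2, 5), 2, 1,
                  dimnames = list(c("gA", "gZ"), "T1"))
  expect_error(call_upregulated(control, tumor, settings = fast_mcmc(3)), "gZ")
})

test_that("calls are reproducible and planted genes are recovered under noise", {
  cfg <- simulation_config(n_normal = 88, n_tumor = 12, n_genes = 60,
                           n_tfs = 6, targets_per_tf = c(5, 6),
                           active_tfs_per_group = 1, planted_fold = 4,
                           noise_sd = 0.5, seed = 21)
  sim <- simulate_expression(cfg)
  calls <- call_upregulated(sim$control, sim$tumor, settings = fast_mcmc(11))
  calls2 <- call_upregulated(sim$control, sim$tumor, settings = fast_mcmc(11))
  expect_identical(calls$up, calls2$up)
  truth <- sim$truth$upregulated
  tp <- fp <- pos <- neg <- 0
  for (s in names(truth)) {
    flagged <- calls$gene[calls$sample == s & calls$up]
    planted <- truth[[s]]
    others <- setdiff(rownames(sim$tumor), planted)
    tp <- tp + length(intersect(flagged, planted))
    fp <- fp + length(intersect(flagged, others))
    pos <- pos + length(planted)
    neg <- neg + length(others)
  }
  expect_gte(tp / pos, 0.95)
  expect_lte(fp / neg, 0.05)
})

test_that("the Benjamini-Hochberg option tightens the gate", {
  set.seed(10)
  control <- matrix(rnorm(300, 8, 1), 5, 60,
                    dimnames = list(paste0("g", 1:5), sprintf("N%02d", 1:60)))
  tumor <- cbind(T1 = rowMeans(control) * c(4, 1, 1, 1, 2.2))
  raw <- call_upregulated(control, tumor, settings = fast_mcmc(13))
  bh <- call_upregulated(control, tumor, settings = fast_mcmc(13),
                         adjust = "BH")
  expect_true("p_adjusted" %in% colnames(bh))
  expect_true(all(bh$p_adjusted >= bh$p_value - 1e-12))
  expect_true(all(bh$up <= raw$up))
})
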