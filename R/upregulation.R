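#' Prior specification for the per-gene Bayesian null
#'
#' Independent semi-conjugate priors for the normal control model:
#' `mu ~ Normal(w0, v0)` (v0 a variance) and `sigma2 ~ InverseGamma(a0, b0)`.
#' The defaults are vague so the posterior is dominated by the control data.
#'
#' @param w0 Prior mean of `mu`.
#' @param v0 Prior variance of `mu`; must be positive.
#' @param a0,b0 Shape and rate of the inverse-gamma prior on `sigma2`; both
#'   must be positive.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(w0 = 0, v0 = 1e4, a0 = 1e-3, b0 = 1e-3) {
  assert_pos(v0, "v0"); assert_pos(a0, "a0"); assert_pos(b0, "b0")
  structure(list(w0 = as.numeric(w0), v0 = as.numeric(v0),
                 a0 = as.numeric(a0), b0 = as.numeric(b0)),
            class = "prior_spec")
}

#' MCMC sampler settings
#'
#' @param n_draws Post-warmup draws per chain (>= 500 recommended).
#' @param n_tune Warmup (tuning) iterations per chain, discarded.
#' @param n_chains Number of chains; at least 2 so split-Rhat is defined.
#' @param predictive_draws Number of posterior-predictive draws used to build
#'   the doubled-variable density.
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_draws = 2000, n_tune = 1000, n_chains = 2,
                          predictive_draws = 4000, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  n_draws <- assert_count(n_draws, "n_draws")
  n_tune <- assert_count(n_tune, "n_tune", min = 0L)
  n_chains <- assert_count(n_chains, "n_chains")
  if (n_chains < 2L) stop("'n_chains' must be >= 2 for convergence diagnostics",
                          call. = FALSE)
  predictive_draws <- assert_count(predictive_draws, "predictive_draws")
  structure(list(n_draws = n_draws, n_tune = n_tune, n_chains = n_chains,
                 predictive_draws = predictive_draws, seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Two-block Gibbs sampler for the semi-conjugate normal model.
# Full conditionals:
#   mu    | sigma2, D ~ Normal(m_n, v_n),  v_n = 1/(1/v0 + n/sigma2)
#   sigma2| mu,     D ~ InvGamma(a0 + n/2, b0 + sum((y - mu)^2)/2)
# Returns a list with matrices mu, sigma2 of shape n_draws x n_chains.
gibbs_normal_ig <- function(y, priors, settings) {
  n <- length(y)
  ybar <- mean(y)
  s2 <- stats::var(y)
  total <- settings$n_tune + settings$n_draws
  mu_draws <- matrix(NA_real_, settings$n_draws, settings$n_chains)
  s2_draws <- matrix(NA_real_, settings$n_draws, settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    # Overdispersed chain starts around the data summary.
    mu <- ybar + (ch - (settings$n_chains + 1) / 2) * sqrt(s2)
    sigma2 <- s2 * 2^(ch - 1)
    for (it in seq_len(total)) {
      v_n <- 1 / (1 / priors$v0 + n / sigma2)
      m_n <- v_n * (priors$w0 / priors$v0 + n * ybar / sigma2)
      mu <- stats::rnorm(1L, m_n, sqrt(v_n))
      a_n <- priors$a0 + n / 2
      b_n <- priors$b0 + 0.5 * sum((y - mu)^2)
      sigma2 <- 1 / stats::rgamma(1L, shape = a_n, rate = b_n)
      if (it > settings$n_tune) {
        mu_draws[it - settings$n_tune, ch] <- mu
        s2_draws[it - settings$n_tune, ch] <- sigma2
      }
    }
  }
  list(mu = mu_draws, sigma2 = s2_draws)
}

# Split-Rhat (potential scale reduction on split chains) for a draws matrix
# of shape n_draws x n_chains.
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  seqs <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[(n - half + 1):n, j])
  }))
  m <- ncol(seqs)
  n_ <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, stats::var)
  B <- n_ * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n_ - 1) / n_ * W + B / n_) / W)
}

#' Fit the Bayesian null model for one gene on its control values
#'
#' Samples the posterior of `(mu, sigma2)` for a normal model of control
#' expression under vague Normal/Inverse-Gamma priors by Gibbs sampling
#' (both full conditionals are conjugate), draws from the posterior
#' predictive distribution of a new observation `x`, and builds the
#' empirical density of the doubled variable `y = 2x` by kernel density
#' estimation. The upper-tail mass of that doubled density is the
#' up-regulation p-value: a tumor value is extreme only if it is large even
#' relative to a doubling of the control distribution.
#'
#' @param control Numeric vector of control-sample expression values
#'   (>= 3 finite values).
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param gene Optional gene identifier stored on the model.
#' @param zero_var One of `"error"` (default) or `"jitter"`. An (effectively)
#'   zero-variance control vector degenerates the inverse-gamma posterior;
#'   with `"jitter"` a deterministic jitter of sd 1e-6 is added instead, with
#'   a warning.
#' @return An object of class `gene_null_model` with posterior draws,
#'   posterior-predictive draws, the doubled-density grid, and the tail-mass
#'   (survival) function tabulated on that grid. A split-Rhat above 1.05 for
#'   either parameter is recorded in `$warnings`.
#' @export
fit_null_model <- function(control, priors = prior_spec(), settings,
                           gene = NA_character_, zero_var = c("error", "jitter")) {
  zero_var <- match.arg(zero_var)
  control <- as.numeric(control)
  if (length(control) < 3L || !all(is.finite(control))) {
    stop("need >= 3 finite control values", call. = FALSE)
  }
  if (!inherits(settings, "mcmc_settings")) stop("'settings' must be mcmc_settings()")
  warnings <- character(0)
  if (stats::var(control) < 1e-12) {
    if (zero_var == "error") {
      stop("control values have (near) zero variance; refit with zero_var = \"jitter\" ",
           "or supply informative controls", call. = FALSE)
    }
    set.seed(derive_seed(settings$seed, 7L))
    control <- control + stats::rnorm(length(control), 0, 1e-6)
    warnings <- c(warnings, "zero-variance controls: jitter sd 1e-6 added")
    warning("zero-variance controls: jitter sd 1e-6 added", call. = FALSE)
  }
  set.seed(derive_seed(settings$seed, 1L))
  post <- gibbs_normal_ig(control, priors, settings)
  rhat <- c(mu = split_rhat(post$mu), sigma2 = split_rhat(post$sigma2))
  if (any(rhat > 1.05, na.rm = TRUE)) {
    warnings <- c(warnings,
                  sprintf("split-Rhat > 1.05 (mu %.3f, sigma2 %.3f): sampler may not have converged",
                          rhat[["mu"]], rhat[["sigma2"]]))
  }
  mu <- as.vector(post$mu)
  sigma2 <- as.vector(post$sigma2)
  set.seed(derive_seed(settings$seed, 2L))
  idx <- sample.int(length(mu), settings$predictive_draws, replace = TRUE)
  predictive <- stats::rnorm(settings$predictive_draws, mu[idx], sqrt(sigma2[idx]))
  doubled <- 2 * predictive
  # Silverman rule-of-thumb bandwidth; grid spans the draws +/- 3 bandwidths.
  dens <- stats::density(doubled, bw = "nrd0", n = 1024L)
  surv <- tail_mass_grid(dens$x, dens$y)
  structure(list(gene = gene, mu = mu, sigma2 = sigma2,
                 predictive = predictive,
                 grid = dens$x, density = dens$y, surv = surv,
                 bandwidth = dens$bw,
                 n_control = length(control), control_mean = mean(control),
                 priors = priors, settings = settings,
                 rhat = rhat, warnings = warnings),
            class = "gene_null_model")
}

# Upper-tail mass of a tabulated density by trapezoidal integration,
# accumulated from the right and clamped to [0, 1].
tail_mass_grid <- function(x, y) {
  n <- length(x)
  cell <- (y[-n] + y[-1]) / 2 * diff(x)
  surv <- c(rev(cumsum(rev(cell))), 0)
  pmin(pmax(surv, 0), 1)
}

#' @export
print.gene_null_model <- function(x, ...) {
  cat(sprintf("gene_null_model (%s): %d controls, %d posterior draws, %d predictive draws\n",
              x$gene, x$n_control, length(x$mu), length(x$predictive)))
  cat(sprintf("  posterior mean mu = %.3f, sigma2 = %.3f; split-Rhat %.3f / %.3f\n",
              mean(x$mu), mean(x$sigma2), x$rhat[["mu"]], x$rhat[["sigma2"]]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

check_fitted <- function(model) {
  if (!inherits(model, "gene_null_model")) {
    stop("'model' must be a fitted gene_null_model", call. = FALSE)
  }
}

#' Doubled-variable p-value
#'
#' The upper-tail probability `P(Y >= x)` of the doubled posterior-predictive
#' variable `Y = 2X`, evaluated at a tumor expression value by interpolating
#' the tabulated tail mass of the kernel density of the doubled draws.
#' Monotonically non-increasing in `x`.
#'
#' @param model A fitted [fit_null_model()] object.
#' @param x Numeric vector of tumor expression values.
#' @return Numeric p-values in `[0, 1]`, one per element of `x`.
#' @export
pvalue_doubled <- function(model, x) {
  check_fitted(model)
  p <- stats::approx(model$grid, model$surv, xout = x, rule = 2)$y
  pmin(pmax(p, 0), 1)
}

#' Up-regulation probability of a gene value
#'
#' The complement of the doubled-variable p-value,
#' `1 - P(Y >= x)`; non-decreasing in `x` and used downstream as the
#' per-gene evidence both for cascade scoring and for the perturbation
#' factor's expression-change term.
#'
#' @inheritParams pvalue_doubled
#' @return Probabilities in `[0, 1]`.
#' @export
gene_probability <- function(model, x) {
  1 - pvalue_doubled(model, x)
}

#' Invert the doubled-density threshold at a significance level
#'
#' Returns the smallest grid value `x*` whose upper-tail mass under the
#' doubled density is at most `alpha` — the decision threshold: values above
#' `x*` have p-value below `alpha`.
#'
#' @param model A fitted [fit_null_model()] object.
#' @param alpha Significance level in (0, 1).
#' @return The threshold expression value.
#' @export
invert_threshold <- function(model, alpha) {
  check_fitted(model)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  }
  model$grid[min(which(model$surv <= alpha))]
}

#' Fit null models for every gene of a control matrix
#'
#' @param control Numeric matrix, genes in rows (rownames required), control
#'   samples in columns.
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()]; each gene gets a seed derived from
#'   `settings$seed` and its row index, so the fit is reproducible and
#'   independent of gene subsetting order.
#' @param zero_var Passed to [fit_null_model()].
#' @return Named list of `gene_null_model` objects.
#' @export
fit_null_models <- function(control, priors = prior_spec(), settings,
                            zero_var = c("error", "jitter")) {
  zero_var <- match.arg(zero_var)
  if (is.null(rownames(control))) stop("'control' must have gene rownames")
  genes <- rownames(control)
  models <- lapply(seq_along(genes), function(i) {
    s <- settings
    s$seed <- derive_seed(settings$seed, 100L + i)
    fit_null_model(control[i, ], priors = priors, settings = s,
                   gene = genes[i], zero_var = zero_var)
  })
  names(models) <- genes
  models
}

#' Call up-regulated genes per tumor sample
#'
#' For every (tumor sample, gene) pair, computes the fold change of the tumor
#' value over the mean control expression and the doubled-variable p-value
#' under the gene's Bayesian null, and flags the pair as up-regulated when
#' both gates hold: fold change >= `fold_threshold` AND p-value <= `alpha`.
#'
#' @param control,tumor Numeric matrices (genes x samples) sharing the full
#'   gene set; mismatches are an error naming the offending genes.
#' @param priors,settings Passed to [fit_null_models()] when `models` is NULL.
#' @param fold_threshold Minimum fold change (default 2, inclusive).
#' @param alpha Maximum p-value (default 0.05, inclusive).
#' @param models Optional precomputed model list from [fit_null_models()],
#'   reused across pipeline stages.
#' @param adjust One of `"none"` (default, the raw gate) or `"BH"`
#'   (Benjamini-Hochberg within each sample, gating on the adjusted value).
#' @param zero_var Passed to [fit_null_models()].
#' @return A data.frame with one row per (sample, gene): `sample`, `gene`,
#'   `value`, `control_mean`, `fold_change`, `p_value`, `up`. The fitted
#'   model list is attached as attribute `"models"`.
#' @export
call_upregulated <- function(control, tumor, priors = prior_spec(), settings,
                             fold_threshold = 2, alpha = 0.05, models = NULL,
                             adjust = c("none", "BH"),
                             zero_var = c("error", "jitter")) {
  adjust <- match.arg(adjust)
  zero_var <- match.arg(zero_var)
  if (is.null(rownames(control)) || is.null(rownames(tumor))) {
    stop("control and tumor matrices must have gene rownames")
  }
  only_c <- setdiff(rownames(control), rownames(tumor))
  only_t <- setdiff(rownames(tumor), rownames(control))
  if (length(only_c) || length(only_t)) {
    stop("gene sets differ between control and tumor matrices; offenders: ",
         paste(utils::head(c(only_c, only_t), 10L), collapse = ", "), call. = FALSE)
  }
  genes <- rownames(control)
  if (is.null(models)) {
    models <- fit_null_models(control, priors, settings, zero_var = zero_var)
  }
  models <- models[genes]
  cmeans <- vapply(models, `[[`, numeric(1), "control_mean")
  if (any(cmeans <= 0)) {
    stop("non-positive mean control expression (fold change undefined) for: ",
         paste(utils::head(genes[cmeans <= 0], 10L), collapse = ", "), call. = FALSE)
  }
  tumor <- tumor[genes, , drop = FALSE]
  samples <- colnames(tumor)
  pmat <- vapply(seq_along(genes),
                 function(i) pvalue_doubled(models[[i]], tumor[i, ]),
                 numeric(ncol(tumor)))
  pmat <- matrix(pmat, nrow = ncol(tumor), ncol = length(genes),
                 dimnames = list(samples, genes))
  calls <- data.frame(
    sample = rep(samples, times = length(genes)),
    gene = rep(genes, each = length(samples)),
    value = as.vector(t(tumor)),
    control_mean = rep(cmeans, each = length(samples)),
    stringsAsFactors = FALSE
  )
  calls$fold_change <- calls$value / calls$control_mean
  calls$p_value <- as.vector(pmat)
  gate_p <- calls$p_value
  if (adjust == "BH") {
    calls$p_adjusted <- stats::ave(calls$p_value, calls$sample,
                                   FUN = function(p) stats::p.adjust(p, "BH"))
    gate_p <- calls$p_adjusted
  }
  calls$up <- calls$fold_change >= fold_threshold & gate_p <= alpha
  calls <- calls[order(calls$sample, calls$gene), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "models") <- models
  calls
}

#' Up-regulation probability matrix
#'
#' Evaluates [gene_probability()] for every gene model at every tumor value.
#'
#' @param models Named list from [fit_null_models()].
#' @param tumor Numeric matrix (genes x samples); genes must all have models.
#' @return Matrix (genes x samples) of probabilities in `[0, 1]`.
#' @export
probability_matrix <- function(models, tumor) {
  genes <- rownames(tumor)
  missing <- setdiff(genes, names(models))
  if (length(missing)) {
    stop("no fitted model for: ", paste(utils::head(missing, 10L), collapse = ", "))
  }
  out <- t(vapply(genes,
                  function(g) gene_probability(models[[g]], tumor[g, ]),
                  numeric(ncol(tumor))))
  dimnames(out) <- dimnames(tumor)
  out
}
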