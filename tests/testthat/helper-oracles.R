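# Independent oracles and fixture builders shared across the suite.

# Long-format expression tibble over a complete grid; values from `fill`
# (function of row index) or random nonnegative.
make_long_df <- function(genes, conditions, times, reps, fill = NULL) {
  df <- tidyr::expand_grid(
    gene = genes, condition = conditions, time = times, replicate = seq_len(reps)
  )
  df$value <- if (is.null(fill)) abs(rnorm(nrow(df))) else fill(seq_len(nrow(df)))
  df
}

# Normal-equations least squares, coded independently of the package's
# Gram-based solver: explicit residuals, no shared helpers.
oracle_ls <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  list(coefficients = drop(beta), rss = sum(r * r))
}

# Brute-force best-subset search over all size-k candidate subsets using the
# normal-equations oracle; design = [intercept, self lag, subset lags].
oracle_best_subset <- function(tr, target, k, intercept = TRUE) {
  genes <- tr$gene_ids
  y <- tr$responses[, target]
  cands <- setdiff(genes, target)
  combos <- utils::combn(cands, k, simplify = FALSE)
  best <- NULL
  for (cc in combos) {
    X <- cbind(
      if (intercept) rep(1, nrow(tr$predictors)) else NULL,
      tr$predictors[, target],
      tr$predictors[, cc, drop = FALSE]
    )
    fit <- oracle_ls(X, y)
    if (is.null(best) || fit$rss < best$rss * (1 - 1e-12)) {
      best <- list(subset = cc, rss = fit$rss, coefficients = fit$coefficients)
    }
  }
  best
}

# Upper tail of the F(d1, d2) distribution via the regularized incomplete
# beta function (pbeta), independent of pf().
oracle_f_tail <- function(f, d1, d2) {
  pbeta(d2 / (d2 + d1 * f), d2 / 2, d1 / 2)
}

# Closed-form mean/variance of a normal truncated below at `lower`.
oracle_truncnorm_moments <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  lam <- dnorm(a) / (1 - pnorm(a))
  list(
    mean = mu + sigma * lam,
    variance = sigma^2 * (1 + a * lam - lam^2)
  )
}

# A transition set built directly from matrices (bypasses build_transitions)
# for regression-level tests.
manual_transitions <- function(predictors, responses, genes) {
  colnames(predictors) <- genes
  colnames(responses) <- genes
  structure(
    list(
      predictors = predictors, responses = responses,
      labels = tibble::tibble(
        condition = paste0("c", seq_len(nrow(predictors))),
        from = "T1", to = "T2"
      ),
      gene_ids = genes, virtual_shift = FALSE
    ),
    class = "transition_set"
  )
}

quiet_network <- function(...) suppressWarnings(sample_network(...))
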