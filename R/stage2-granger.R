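#' Granger-causality F-test for one regulator of a fitted model
#'
#' Tests whether a regulator contributes significantly to predicting the
#' target beyond the other selected regulators: the reduced model (self lag,
#' intercept, and the remaining regulators) is refit, and
#' `F = (rss_reduced - rss_full) / (rss_full / df_den)` with one numerator
#' degree of freedom is referred to the upper F tail.
#'
#' Two degenerate situations are handled explicitly. A perfect full fit
#' (`rss_full` below `1e-12 * sum(y^2)`) with a worse reduced fit yields an
#' infinite F and p = 0 (the regulator is kept); when both fits are perfect
#' there is no information to attribute and the regulator is removed.
#'
#' @param fit A `sparse_fit` from [best_subset_fit()].
#' @param regulator One of `fit$regulators`.
#' @param transitions The `transition_set` the fit was computed on.
#' @param alpha Significance level (study default 0.05).
#' @param literal If `TRUE`, apply the literal rejection rule "reject the
#'   regulator when p < alpha" (which removes significant regulators); the
#'   default keeps a regulator iff p < alpha, the standard Granger
#'   convention consistent with removing false positives.
#' @return One-row tibble: `target`, `regulator`, `f_stat`, `p_value`,
#'   `kept`, `df_num`, `df_den`.
#' @export
granger_test <- function(fit, regulator, transitions, alpha = 0.05,
                         literal = FALSE) {
  stopifnot(inherits(fit, "sparse_fit"))
  if (!regulator %in% fit$regulators) {
    abort(paste0(regulator, " is not a regulator of target ", fit$target))
  }
  gs <- transition_gram(transitions, intercept = fit$intercept_on)
  granger_test_gram(gs, fit, regulator, alpha = alpha, literal = literal)
}

granger_test_gram <- function(gs, fit, regulator, alpha = 0.05,
                              literal = FALSE) {
  genes <- gs$gene_ids
  off <- gs$col_offset
  tcol <- match(fit$target, genes)
  k <- length(fit$regulators)
  p_full <- k + 1 + as.integer(gs$intercept)  # regulators + self (+ intercept)
  df_den <- gs$n_obs - p_full
  if (df_den < 1) {
    abort(sprintf(
      "no residual degrees of freedom (n = %d, model size %d); add observations or reduce k",
      gs$n_obs, p_full
    ))
  }
  fixed <- c(if (gs$intercept) 1L else integer(0), tcol + off)
  full_cols <- c(fixed, match(fit$regulators, genes) + off)
  red_cols <- c(fixed, match(setdiff(fit$regulators, regulator), genes) + off)
  rss_full <- ls_from_gram(gs, full_cols, tcol)$rss
  rss_red <- ls_from_gram(gs, red_cols, tcol)$rss

  tol <- 1e-12 * max(gs$yty[tcol], .Machine$double.xmin)
  if (rss_full <= tol && rss_red <= tol) {
    f_stat <- 0
    p_value <- 1
  } else if (rss_full <= tol) {
    f_stat <- Inf
    p_value <- 0
  } else {
    f_stat <- max(rss_red - rss_full, 0) / (rss_full / df_den)
    p_value <- pf(f_stat, 1, df_den, lower.tail = FALSE)
  }
  kept <- if (literal) p_value >= alpha else p_value < alpha
  tibble::tibble(
    target = fit$target, regulator = regulator, f_stat = f_stat,
    p_value = p_value, kept = kept, df_num = 1L, df_den = as.integer(df_den)
  )
}

#' Remove regulators without significant marginal contribution
#'
#' Each of the fit's `k` regulators is tested one by one against the other
#' `k - 1` (marginal, simultaneous tests at a single preset level; no
#' multiple-testing correction and no sequential re-pruning). Surviving
#' regulators' coefficients are re-estimated by a final least-squares fit on
#' the surviving set; the result may have an empty regulator set.
#'
#' @inheritParams granger_test
#' @return A `sparse_fit` on the surviving regulators, with the per-regulator
#'   test table attached as attribute `"granger"`.
#' @export
prune_fit <- function(fit, transitions, alpha = 0.05, literal = FALSE) {
  gs <- transition_gram(transitions, intercept = fit$intercept_on)
  prune_fit_gram(gs, fit, alpha = alpha, literal = literal)
}

prune_fit_gram <- function(gs, fit, alpha = 0.05, literal = FALSE) {
  if (length(fit$regulators) == 0) {
    attr(fit, "granger") <- tibble::tibble(
      target = character(), regulator = character(), f_stat = numeric(),
      p_value = numeric(), kept = logical(), df_num = integer(),
      df_den = integer()
    )
    return(fit)
  }
  tests <- dplyr::bind_rows(lapply(fit$regulators, function(r) {
    granger_test_gram(gs, fit, r, alpha = alpha, literal = literal)
  }))
  survivors <- tests$regulator[tests$kept]
  genes <- gs$gene_ids
  off <- gs$col_offset
  tcol <- match(fit$target, genes)
  fixed <- c(if (gs$intercept) 1L else integer(0), tcol + off)
  cols <- c(fixed, match(survivors, genes) + off)
  refit <- ls_from_gram(gs, cols, tcol)
  nf <- length(fixed)
  out <- new_sparse_fit(
    target = fit$target,
    regulators = survivors,
    coefficients = if (length(survivors)) {
      refit$coefficients[(nf + 1):(nf + length(survivors))]
    } else numeric(0),
    self_coefficient = refit$coefficients[nf],
    intercept = if (gs$intercept) refit$coefficients[1] else 0,
    rss = refit$rss,
    n_obs = gs$n_obs,
    k = fit$k,
    intercept_on = gs$intercept,
    rank_deficient = refit$rank_deficient
  )
  attr(out, "granger") <- tests
  out
}
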