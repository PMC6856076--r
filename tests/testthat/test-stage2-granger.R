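# Build a fixed 4-gene instance where the target has two strong regulators
# and one decoy selected at k = 3.
make_granger_instance <- function(n = 18, null_coef = 0, noise_sd = 0.3) {
  genes <- c("y", "a", "b", "z")
  P <- matrix(abs(rnorm(n * 4)), n, 4)
  R <- matrix(abs(rnorm(n * 4)), n, 4)
  R[, 1] <- 1 + 0.4 * P[, 1] + 1.2 * P[, 2] - 0.9 * P[, 3] +
    null_coef * P[, 4] + rnorm(n, sd = noise_sd)
  manual_transitions(P, R, genes)
}

test_that("F statistic and p value match the incomplete-beta oracle", {
  set.seed(31)
  for (i in 1:10) {
    tr <- make_granger_instance()
    fit <- best_subset_fit(tr, "y", k = 3)
    for (reg in fit$regulators) {
      res <- granger_test(fit, reg, tr)
      # recompute F from independently coded least squares
      X_full <- cbind(1, tr$predictors[, "y"],
                      tr$predictors[, fit$regulators, drop = FALSE])
      X_red <- cbind(1, tr$predictors[, "y"],
                     tr$predictors[, setdiff(fit$regulators, reg),
                                   drop = FALSE])
      y <- tr$responses[, "y"]
      rss_f <- oracle_ls(X_full, y)$rss
      rss_r <- oracle_ls(X_red, y)$rss
      df_den <- nrow(X_full) - ncol(X_full)
      f_expected <- (rss_r - rss_f) / (rss_f / df_den)
      expect_equal(res$f_stat, f_expected, tolerance = 1e-8)
      expect_equal(res$p_value, oracle_f_tail(res$f_stat, 1, df_den),
                   tolerance = 1e-10)
      expect_equal(res$df_den, df_den)
    }
  }
})

test_that("p decreases as F grows for fixed degrees of freedom", {
  f <- c(0, 0.5, 1, 2, 5, 20)
  p <- pf(f, 1, 12, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  expect_equal(oracle_f_tail(f, 1, 12), p, tolerance = 1e-12)
})

test_that("degenerate fits follow the attribution rules", {
  set.seed(32)
  genes <- c("y", "a", "b")
  P <- matrix(abs(rnorm(30)), 10, 3)
  R <- P

  # exact dependence on a: full fit perfect, reduced not -> F = Inf, kept
  R[, 1] <- 2 * P[, 2]
  tr <- manual_transitions(P, R, genes)
  fit <- best_subset_fit(tr, "y", k = 1)
  res <- granger_test(fit, "a", tr)
  expect_identical(res$f_stat, Inf)
  expect_equal(res$p_value, 0)
  expect_true(res$kept)

  # response exactly reproducible without the regulator: F = 0, p = 1, removed
  R[, 1] <- 3 * P[, 1]  # self lag alone suffices
  tr <- manual_transitions(P, R, genes)
  fit <- best_subset_fit(tr, "y", k = 1)
  res <- granger_test(fit, fit$regulators[1], tr)
  expect_equal(res$f_stat, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$kept)
})

test_that("pruning removes a decoy, keeps true regulators, and refits survivors", {
  set.seed(33)
  kept_true <- 0
  removed_decoy <- 0
  for (i in 1:20) {
    tr <- make_granger_instance(n = 18, noise_sd = 0.15)
    fit <- best_subset_fit(tr, "y", k = 3)
    pruned <- prune_fit(fit, tr, alpha = 0.05)
    gr <- attr(pruned, "granger")
    expect_equal(nrow(gr), 3)
    expect_true(all(pruned$regulators %in% fit$regulators))
    if (all(c("a", "b") %in% pruned$regulators)) kept_true <- kept_true + 1
    if (!"z" %in% pruned$regulators) removed_decoy <- removed_decoy + 1
    # survivors' coefficients equal a fresh least-squares fit on that set
    if (length(pruned$regulators) > 0) {
      X <- cbind(1, tr$predictors[, "y"],
                 tr$predictors[, pruned$regulators, drop = FALSE])
      o <- oracle_ls(X, tr$responses[, "y"])
      expect_equal(
        unname(c(pruned$intercept, pruned$self_coefficient,
                 pruned$coefficients)),
        unname(o$coefficients), tolerance = 1e-8
      )
    }
  }
  expect_gte(kept_true, 18)     # strong true effects survive
  expect_gte(removed_decoy, 16) # the null decoy is nearly always cut
})

test_that("the literal rejection rule inverts the decision", {
  set.seed(34)
  tr <- make_granger_instance(n = 18, noise_sd = 0.15)
  fit <- best_subset_fit(tr, "y", k = 3)
  std <- granger_test(fit, "a", tr, literal = FALSE)
  lit <- granger_test(fit, "a", tr, literal = TRUE)
  expect_equal(std$p_value, lit$p_value)
  expect_equal(std$kept, !lit$kept)
})

test_that("all-null pruning can empty the regulator set", {
  set.seed(35)
  genes <- c("y", "a", "b", "z")
  P <- matrix(abs(rnorm(18 * 4)), 18, 4)
  R <- matrix(abs(rnorm(18 * 4)), 18, 4)  # responses unrelated to predictors
  tr <- manual_transitions(P, R, genes)
  fit <- best_subset_fit(tr, "y", k = 3)
  pruned <- prune_fit(fit, tr, alpha = 1e-6)
  expect_length(pruned$regulators, 0)
  expect_true(is.finite(pruned$rss))
})

test_that("insufficient residual degrees of freedom raise an informative error", {
  set.seed(36)
  genes <- c("y", "a", "b", "z")
  P <- matrix(abs(rnorm(5 * 4)), 5, 4)
  tr <- manual_transitions(P, P, genes)
  fit <- best_subset_fit(tr, "y", k = 3)
  expect_error(granger_test(fit, fit$regulators[1], tr),
               "degrees of freedom")
})
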