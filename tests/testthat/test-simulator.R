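test_that("sampled networks have the declared sparsity, signs and stability", {
  gt <- quiet_network(10, k_true = 2, seed = 51)
  A <- gt$coefficients
  offdiag <- A * (1 - diag(10))
  expect_true(all(rowSums(offdiag != 0) == 2))
  expect_lt(max(Mod(eigen(A, only.values = TRUE)$values)), 1)
  expect_true(all(diag(A) > 0 & diag(A) < 1))

  # all-activating when sign_prob = 0
  gt0 <- quiet_network(10, k_true = 2, sign_prob = 0, seed = 52)
  expect_true(all(true_edges(gt0)$coefficient > 0))

  # seeded reproducibility, without disturbing the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  g1 <- quiet_network(10, k_true = 2, seed = 53)
  g2 <- quiet_network(10, k_true = 2, seed = 53)
  expect_identical(g1$coefficients, g2$coefficients)
  set.seed(99)
  expect_identical(rnorm(1), before)

  expect_error(sample_network(3, k_true = 3), "smaller")
})

test_that("noise-free simulation is the deterministic trajectory, replicated", {
  gt <- quiet_network(6, k_true = 2, process_sd = 0, measurement_sd = 0,
                      seed = 54)
  ds <- simulate_dataset(gt, n_conditions = 3, n_times = 4, n_replicates = 3,
                         seed = 55)
  df <- tibble::as_tibble(ds)
  spread <- dplyr::summarise(
    dplyr::group_by(df, gene, condition, time),
    d = max(value) - min(value), .groups = "drop"
  )
  expect_true(all(spread$d == 0))
  expect_equal(unname(dim_grid(ds)), c(6L, 3L, 4L, 3L))

  # the latent recursion holds across consecutive times (after undoing the
  # per-gene nonnegativity shift, which only changes the intercept)
  ds_signed <- simulate_dataset(gt, n_conditions = 3, n_times = 4,
                                n_replicates = 1, nonneg = "none", seed = 55)
  m <- tidyr::pivot_wider(tibble::as_tibble(ds_signed),
                          id_cols = c("gene", "condition"),
                          names_from = "time", values_from = "value")
  for (cond in unique(m$condition)) {
    sub <- m[m$condition == cond, ]
    ord <- match(gt$gene_ids, sub$gene)
    x_t <- sub$T1[ord]
    x_next <- drop(gt$coefficients %*% x_t) + gt$intercepts
    expect_equal(sub$T2[ord], unname(x_next), tolerance = 1e-10)
  }
})

test_that("study-shaped simulation round-trips through the long TSV format", {
  gt <- quiet_network(74, k_true = 3, seed = 56)
  ds <- simulate_dataset(gt, n_conditions = 18, n_times = 3,
                         n_replicates = 3, seed = 57)
  expect_equal(unname(dim_grid(ds)), c(74L, 18L, 3L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds, path)
  ds2 <- read_expression(path)
  expect_identical(ds2$value, ds$value)
})

test_that("trajectories remain bounded over long horizons", {
  gt <- quiet_network(8, k_true = 2, seed = 58)
  A <- gt$coefficients
  x <- rep(10, 8)
  for (i in 1:1000) x <- drop(A %*% x) + gt$intercepts
  expect_true(all(is.finite(x)))
  expect_lt(max(abs(x)), 1e3)
})

test_that("recovery metrics score predictions against the simulated truth", {
  gt <- quiet_network(6, k_true = 2, seed = 59)
  truth <- true_edges(gt)
  as_net <- function(edges) {
    structure(edges, gene_ids = gt$gene_ids, n_perturbations = 1L,
              class = c("weighted_network", class(tibble::tibble())))
  }
  perfect <- as_net(tibble::tibble(
    regulator = truth$regulator, target = truth$target,
    existence_weight = 1, consensus_sign = truth$sign, sign_weight = 1,
    n_occurrences = 1L
  ))
  m <- evaluate_recovery(perfect, gt, threshold = 0.5)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$sign_accuracy, 1)
  expect_equal(m$aupr, 1)

  empty <- as_net(tibble::tibble(
    regulator = character(), target = character(),
    existence_weight = numeric(), consensus_sign = character(),
    sign_weight = numeric(), n_occurrences = integer()
  ))
  m0 <- evaluate_recovery(empty, gt, threshold = 0.5)
  expect_identical(m0$precision, NA_real_)  # distinguished null, not 0
  expect_equal(m0$recall, 0)

  # random prediction: expected precision ~ true edge density (Monte Carlo)
  set.seed(60)
  density <- nrow(truth) / (6 * 5)
  precs <- replicate(300, {
    pairs <- expand.grid(regulator = gt$gene_ids, target = gt$gene_ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]
    pick <- pairs[sample(nrow(pairs), 8), ]
    rand <- as_net(tibble::tibble(
      regulator = pick$regulator, target = pick$target,
      existence_weight = 1, consensus_sign = "activation", sign_weight = 1,
      n_occurrences = 1L
    ))
    evaluate_recovery(rand, gt, threshold = 0.5)$precision
  })
  se <- sd(precs) / sqrt(length(precs))
  expect_lt(abs(mean(precs) - density), 4 * se + 0.01)
})

test_that("pr_curve sweeps thresholds consistently with point metrics", {
  set.seed(61)
  gt <- quiet_network(6, k_true = 2, seed = 61)
  ds <- simulate_dataset(gt, n_conditions = 8, seed = 62)
  fit <- causnet_infer(ds, k = 2, n_perturbations = 20, seed = 63,
                       virtual_shift = FALSE)
  curve <- pr_curve(fit$full_network, gt)
  expect_true(all(diff(curve$recall) >= 0))  # descending thresholds
  m <- evaluate_recovery(fit$full_network, gt, threshold = curve$threshold[1])
  expect_equal(curve$precision[1], m$precision)
})
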