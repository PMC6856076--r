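make_stats <- function(values_by_cell) {
  # values_by_cell: named list "gene|condition|time" -> replicate vector
  rows <- lapply(names(values_by_cell), function(key) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    v <- values_by_cell[[key]]
    tibble::tibble(gene = p[1], condition = p[2], time = p[3],
                   replicate = seq_along(v), value = v)
  })
  summarize_replicates(expression_dataset(dplyr::bind_rows(rows)))
}

test_that("zero-variance cells reproduce their means exactly", {
  st <- make_stats(list(
    "g|c|T1" = c(5, 5, 5),
    "g|c|T2" = c(2, 2, 2)
  ))
  set.seed(41)
  out <- perturb_dataset(st)
  expect_identical(out$value, c(5, 2))
})

test_that("truncated draws are nonnegative and match closed-form moments", {
  # a cell with mean 0 and positive variance: heavy truncation
  n_draws <- 10000
  cells <- list(mu = c(0, 2, 0.5), s2 = c(1, 0.25, 1))
  st <- make_stats(list(
    "g|c|T1" = c(0, 0, 0), "g|c|T2" = c(0, 0, 0)
  ))
  set.seed(42)
  for (j in seq_along(cells$mu)) {
    mu <- cells$mu[j]
    s2 <- cells$s2[j]
    st2 <- st
    st2$mean <- c(mu, mu)
    st2$variance <- c(s2 * 3, s2 * 3)  # sem mode divides by n = 3
    draws <- replicate(n_draws, perturb_dataset(st2)$value[1])
    expect_true(all(draws >= 0))
    o <- oracle_truncnorm_moments(mu, sqrt(s2))
    se_mean <- sqrt(o$variance / n_draws)
    expect_lt(abs(mean(draws) - o$mean), 3 * se_mean)
    # SE of the sample variance of a (truncated) normal, approximated by
    # sqrt(2/(n-1)) * variance; generous for the skewed case
    se_var <- sqrt(2 / (n_draws - 1)) * o$variance * 2
    expect_lt(abs(var(draws) - o$variance), 3 * se_var)
  }
})

test_that("variance modes scale the Gaussian as documented", {
  st <- make_stats(list("g|c|T1" = c(4, 5, 6), "g|c|T2" = c(4, 5, 6)))
  # mean 5, s^2 = 1, n = 3; truncation at 0 is negligible here
  draws_for <- function(mode, n = 4000) {
    set.seed(43)
    replicate(n, perturb_dataset(st, variance_mode = mode)$value[1])
  }
  v_sem <- var(draws_for("sem"))
  v_sample <- var(draws_for("sample"))
  v_pop <- var(draws_for("population"))
  # far from the truncation boundary, variances approximate s^2/n, s^2,
  # and s^2 (n-1)/n
  expect_equal(v_sem, 1 / 3, tolerance = 0.15)
  expect_equal(v_sample, 1, tolerance = 0.15)
  expect_equal(v_pop, 2 / 3, tolerance = 0.15)
})

test_that("signed datasets are perturbed without truncation", {
  df <- make_long_df("g", "c", c("T1", "T2"), 3,
                     fill = function(i) rep(c(-5, 0), each = 3)[i])
  st <- summarize_replicates(expression_dataset(df, signed = TRUE))
  st$variance <- c(3, 3)
  set.seed(44)
  draws <- replicate(2000, perturb_dataset(st)$value[1])
  expect_lt(mean(draws), 0)  # untruncated around -5
  expect_equal(mean(draws), -5, tolerance = 0.1)
})

test_that("perturbation with a single replicate is refused", {
  df <- make_long_df("g", "c", c("T1", "T2"), 1)
  st <- summarize_replicates(expression_dataset(df))
  expect_error(perturb_dataset(st), "at least 2 replicates")
})

test_that("aggregation computes existence and sign weights as occurrence fractions", {
  genes <- c("a", "b", "c")
  run <- function(edges) {
    structure(edges, gene_ids = genes, provenance = 1,
              class = c("single_run_network", class(tibble::tibble())))
  }
  act <- tibble::tibble(regulator = "a", target = "b", sign = "activation",
                        coefficient = 1)
  rep_ <- tibble::tibble(regulator = "a", target = "b", sign = "repression",
                         coefficient = -1)
  none <- tibble::tibble(regulator = character(), target = character(),
                         sign = character(), coefficient = numeric())

  # present as activation in 20 of 100 runs
  runs <- c(replicate(20, run(act), simplify = FALSE),
            replicate(80, run(none), simplify = FALSE))
  net <- aggregate_networks(runs)
  expect_equal(net$existence_weight, 0.2)
  expect_equal(net$consensus_sign, "activation")
  expect_equal(net$sign_weight, 1)
  expect_equal(net$n_occurrences, 20L)
  expect_equal(attr(net, "n_perturbations"), 100L)

  # 50 activation + 50 repression: existence 1, ambiguous, sign weight 0.5
  runs <- c(replicate(50, run(act), simplify = FALSE),
            replicate(50, run(rep_), simplify = FALSE))
  net <- aggregate_networks(runs)
  expect_equal(net$existence_weight, 1)
  expect_equal(net$consensus_sign, "ambiguous")
  expect_equal(net$sign_weight, 0.5)

  # aggregation is invariant to run order
  set.seed(45)
  net2 <- aggregate_networks(sample(runs))
  expect_equal(tibble::as_tibble(net2), tibble::as_tibble(net))

  # mixed gene universes refused
  bad <- run(act)
  attr(bad, "gene_ids") <- c("a", "b")
  expect_error(aggregate_networks(list(run(act), bad)), "universe")
})

test_that("thresholding keeps edges at or above the cut and nests across cuts", {
  set.seed(46)
  gt <- quiet_network(6, k_true = 2, seed = 46)
  ds <- simulate_dataset(gt, n_conditions = 8, seed = 47)
  fit <- causnet_infer(ds, k = 2, n_perturbations = 30, seed = 48,
                       virtual_shift = FALSE)
  net <- fit$full_network
  expect_equal(tibble::as_tibble(threshold_network(net, 0)),
               tibble::as_tibble(net), ignore_attr = TRUE)
  expect_equal(nrow(threshold_network(net, 1.01)), 0)
  key <- function(n) paste(n$regulator, n$target)
  k06 <- key(threshold_network(net, 0.6))
  k02 <- key(threshold_network(net, 0.2))
  k01 <- key(threshold_network(net, 0.1))
  expect_true(all(k06 %in% k02))
  expect_true(all(k02 %in% k01))
  expect_equal(attr(threshold_network(net, 0.2), "min_weight"), 0.2)
})
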