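# One truncated-normal draw per element, lower-truncated at `lower`
# (vectorized inverse-CDF; exact mean when sd = 0).
rtruncnorm_lower <- function(mean, sd, lower = 0) {
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- pnorm(lower, mean[pos], sd[pos])
    u <- runif(sum(pos), min = lo, max = 1)
    # guard u == 1 from floating point at extreme truncation
    u <- pmin(u, 1 - .Machine$double.eps)
    out[pos] <- qnorm(u, mean[pos], sd[pos])
    out[pos] <- pmax(out[pos], lower)
  }
  out
}

#' Draw one perturbed expression grid from replicate statistics
#'
#' Generates one random expression value per (gene, condition, time) cell
#' from a Gaussian centered at the replicate mean, truncated below at zero
#' (a Gaussian approximation of bootstrapping the replicates). The Gaussian
#' variance is controlled by `variance_mode`:
#'
#' * `"sem"` (default): `s^2 / n`, the squared standard error of the mean.
#'   This matches the variance of the mean of a size-2 bootstrap resample
#'   when n = 3 replicates, the resampling scheme the perturbation
#'   approximates.
#' * `"sample"`: the unbiased sample variance `s^2`.
#' * `"population"`: `s^2 (n - 1) / n`.
#'
#' Cells with zero replicate variance reproduce their mean exactly.
#' Truncation is skipped for datasets loaded in signed mode. Randomness
#' comes from the current R RNG stream; seed before calling for
#' reproducibility.
#'
#' @param stats A `replicate_stats` tibble from [summarize_replicates()].
#' @param variance_mode One of `"sem"`, `"sample"`, `"population"`.
#' @return A tibble (`gene`, `condition`, `time`, `value`) carrying the same
#'   ordering attributes as `stats`, usable directly by
#'   [build_transitions()].
#' @export
perturb_dataset <- function(stats,
                            variance_mode = c("sem", "sample", "population")) {
  stopifnot(inherits(stats, "replicate_stats"))
  variance_mode <- match.arg(variance_mode)
  if (any(stats$n < 2)) {
    abort("perturbation needs at least 2 replicates per cell for a variance")
  }
  v <- switch(variance_mode,
    sem = stats$variance / stats$n,
    sample = stats$variance,
    population = stats$variance * (stats$n - 1) / stats$n
  )
  sds <- sqrt(v)
  value <- if (isTRUE(attr(stats, "signed"))) {
    rnorm(nrow(stats), mean = stats$mean, sd = sds)
  } else {
    rtruncnorm_lower(stats$mean, sds, lower = 0)
  }
  out <- tibble::tibble(
    gene = stats$gene, condition = stats$condition, time = stats$time,
    value = value
  )
  for (a in c("gene_ids", "condition_ids", "time_grid", "signed")) {
    attr(out, a) <- attr(stats, a)
  }
  out
}

# Closed-form mean and variance of a Gaussian truncated below at `lower`
# (used by tests and documented diagnostics).
truncnorm_moments <- function(mean, sd, lower = 0) {
  a <- (lower - mean) / sd
  lambda <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  m <- mean + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  list(mean = m, variance = v)
}

# Edge table of one Stage I+II run: drops zero coefficients, no self edges.
edges_from_fits <- function(fits) {
  rows <- purrr::map(fits, function(f) {
    if (length(f$regulators) == 0) return(NULL)
    keep <- f$coefficients != 0
    if (!any(keep)) return(NULL)
    tibble::tibble(
      regulator = f$regulators[keep],
      target = f$target,
      sign = classify_sign(unname(f$coefficients[keep])),
      coefficient = unname(f$coefficients[keep])
    )
  })
  dplyr::bind_rows(rows)
}

new_single_run_network <- function(edges, gene_ids, provenance) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(regulator = character(), target = character(),
                            sign = character(), coefficient = numeric())
  }
  structure(edges, gene_ids = gene_ids, provenance = provenance,
            class = c("single_run_network", class(tibble::tibble())))
}

#' Aggregate single-run networks into a confidence-weighted network
#'
#' Combines the signed directed networks reconstructed from each
#' perturbation into one weighted network. For every ordered
#' (regulator, target) pair, the existence weight is the fraction of runs in
#' which the edge appeared; the consensus sign is the majority sign over
#' those appearances (`"ambiguous"` on an exact tie), and the sign weight is
#' the majority fraction (always at least 0.5).
#'
#' @param runs List of single-run networks (from perturbation runs), all
#'   over the same gene universe.
#' @return A tibble of class `weighted_network` with columns `regulator`,
#'   `target`, `existence_weight`, `consensus_sign`, `sign_weight`,
#'   `n_occurrences`; rows ordered by regulator then target in canonical
#'   gene order. The number of perturbations is attribute
#'   `"n_perturbations"`.
#' @export
aggregate_networks <- function(runs) {
  if (length(runs) == 0) abort("no runs to aggregate")
  gene_ids <- attr(runs[[1]], "gene_ids")
  for (r in runs) {
    if (!identical(attr(r, "gene_ids"), gene_ids)) {
      abort("runs cover different gene universes")
    }
  }
  B <- length(runs)
  all_edges <- dplyr::bind_rows(lapply(runs, tibble::as_tibble))
  if (nrow(all_edges) == 0) {
    out <- tibble::tibble(
      regulator = character(), target = character(),
      existence_weight = numeric(), consensus_sign = character(),
      sign_weight = numeric(), n_occurrences = integer()
    )
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(all_edges, .data$regulator, .data$target),
      n_occurrences = dplyr::n(),
      n_act = sum(.data$sign == "activation"),
      n_rep = sum(.data$sign == "repression"),
      .groups = "drop"
    )
    out <- dplyr::mutate(
      out,
      existence_weight = .data$n_occurrences / B,
      consensus_sign = dplyr::case_when(
        .data$n_act > .data$n_rep ~ "activation",
        .data$n_rep > .data$n_act ~ "repression",
        .default = "ambiguous"
      ),
      sign_weight = pmax(.data$n_act, .data$n_rep) / .data$n_occurrences
    )
    out <- dplyr::arrange(
      out, match(.data$regulator, gene_ids), match(.data$target, gene_ids)
    )
    out <- out[, c("regulator", "target", "existence_weight",
                   "consensus_sign", "sign_weight", "n_occurrences")]
  }
  structure(out, gene_ids = gene_ids, n_perturbations = B,
            class = c("weighted_network", class(tibble::tibble())))
}

#' Keep edges at or above an existence-weight cut-off
#'
#' Published analyses of this method family read networks at cut-offs such
#' as 0.1, 0.2 and 0.6; the applied threshold is recorded in the
#' `"min_weight"` attribute of the result.
#'
#' @param net A `weighted_network`.
#' @param min_weight Minimum existence weight (>= 0).
#' @return The filtered `weighted_network`.
#' @export
threshold_network <- function(net, min_weight) {
  stopifnot(inherits(net, "weighted_network"), min_weight >= 0)
  out <- net[net$existence_weight >= min_weight, , drop = FALSE]
  attr(out, "gene_ids") <- attr(net, "gene_ids")
  attr(out, "n_perturbations") <- attr(net, "n_perturbations")
  attr(out, "min_weight") <- min_weight
  class(out) <- class(net)
  out
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf(
    "<weighted_network> %d edge(s) over %d genes, aggregated from %d run(s)\n",
    nrow(x), length(attr(x, "gene_ids")), attr(x, "n_perturbations")
  ))
  if (!is.null(attr(x, "min_weight"))) {
    cat(sprintf("  existence weight >= %g\n", attr(x, "min_weight")))
  }
  NextMethod()
}

#' Plot a weighted network as a signed adjacency matrix
#'
#' Tiles are regulator (x) by target (y); fill encodes the consensus sign
#' and opacity the existence weight.
#'
#' @param object A `weighted_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weighted_network <- function(object, ...) {
  genes <- attr(object, "gene_ids")
  df <- tibble::as_tibble(object)
  df$regulator <- factor(df$regulator, levels = genes)
  df$target <- factor(df$target, levels = rev(genes))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$regulator, y = .data$target,
    fill = .data$consensus_sign, alpha = .data$existence_weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      activation = "#1b7837", repression = "#762a83", ambiguous = "grey40"
    )) +
    ggplot2::scale_alpha(range = c(0.15, 1), limits = c(0, 1)) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = "regulator", y = "target",
                  fill = "sign", alpha = "existence\nweight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
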