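#' Run the full three-stage network inference pipeline
#'
#' End-to-end inference on a replicated expression time course:
#' replicate summarization, then for each of `n_perturbations` perturbed
#' datasets (truncated-Gaussian draws per cell) a best-subset lagged
#' regression per target (Stage I) followed by Granger F-test pruning
#' (Stage II), and finally aggregation of the reconstructed networks into
#' per-edge existence and sign confidence weights (Stage III). The
#' unperturbed point-estimate network is computed as well and reported
#' separately; it does not enter the weights.
#'
#' Perturbation runs use independent RNG substreams derived
#' deterministically from `seed`, so results are bit-identical across
#' repeated calls and invariant to run order.
#'
#' @param data An [expression_dataset], or a long-format data frame
#'   acceptable to [expression_dataset()].
#' @param k Regulators selected per target in Stage I (study default 3).
#' @param alpha Granger significance level (study default 0.05).
#' @param n_perturbations Number of perturbation runs B (study default 100).
#' @param virtual_shift Wrap the last time point onto the first per
#'   condition, adding the overnight transition (default `TRUE`).
#' @param variance_mode Perturbation variance: `"sem"` (default),
#'   `"sample"`, or `"population"`; see [perturb_dataset()].
#' @param granger_literal Use the literal "reject when p < alpha" rule; see
#'   [granger_test()].
#' @param intercept Include an intercept in every regression (default
#'   `TRUE`).
#' @param seed Master seed; required whenever `n_perturbations > 0` so no
#'   run is silently nondeterministic.
#' @param weight_threshold Existence-weight cut-off applied to the reported
#'   network (0 keeps everything; published analyses read 0.1 / 0.2 / 0.6).
#' @param conditions Optional condition subset to analyze (e.g. one
#'   photoperiod's conditions).
#' @param genes Optional gene subset/ordering (character vector or path to a
#'   one-id-per-line file).
#' @param engine Stage I search engine, `"exhaustive"` or `"greedy"`.
#' @return An object of class `causnet_fit`: `network` (thresholded
#'   [aggregate_networks()] result), `full_network` (unthresholded),
#'   `point_estimate` (single-run network on the unperturbed means),
#'   `config` (all settings), and `log` (per-stage timings).
#' @export
#' @examples
#' gt <- sample_network(6, k_true = 2, seed = 1)
#' ds <- simulate_dataset(gt, n_conditions = 8, seed = 2)
#' fit <- causnet_infer(ds, k = 2, n_perturbations = 5, seed = 3,
#'                      virtual_shift = FALSE)
#' tidy(fit)
causnet_infer <- function(data, k = 3, alpha = 0.05, n_perturbations = 100,
                          virtual_shift = TRUE,
                          variance_mode = c("sem", "sample", "population"),
                          granger_literal = FALSE, intercept = TRUE,
                          seed = NULL, weight_threshold = 0,
                          conditions = NULL, genes = NULL,
                          engine = c("exhaustive", "greedy")) {
  variance_mode <- match.arg(variance_mode)
  engine <- match.arg(engine)
  t0 <- proc.time()[["elapsed"]]
  if (!inherits(data, "expression_dataset")) {
    data <- expression_dataset(data, genes = genes)
  } else if (!is.null(genes)) {
    if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
      genes <- read_gene_list(genes)
    }
    data <- expression_dataset(tibble::as_tibble(data), genes = genes,
                               signed = attr(data, "signed"))
  }
  if (!is.null(conditions)) {
    keep <- attr(data, "condition_ids") %in% conditions
    if (!any(keep)) abort("condition subset matches no conditions")
    data <- expression_dataset(
      dplyr::filter(tibble::as_tibble(data), .data$condition %in% conditions),
      genes = attr(data, "gene_ids"), signed = attr(data, "signed")
    )
  }
  if (n_perturbations > 0 && is.null(seed)) {
    abort("a master seed is required when n_perturbations > 0")
  }
  if (n_perturbations > 0 && attr(data, "n_replicates") < 2) {
    abort("perturbation analysis needs at least 2 replicates per cell")
  }
  stats <- summarize_replicates(data)
  gene_ids <- attr(data, "gene_ids")
  timings <- list()

  one_run <- function(means, provenance) {
    tr <- build_transitions(means, virtual_shift = virtual_shift)
    gs <- transition_gram(tr, intercept = intercept)
    fits <- lapply(gene_ids, function(tg) {
      f <- fit_target(gs, tg, k = k, engine = engine)
      prune_fit_gram(gs, f, alpha = alpha, literal = granger_literal)
    })
    names(fits) <- gene_ids
    new_single_run_network(edges_from_fits(fits), gene_ids, provenance)
  }

  t1 <- proc.time()[["elapsed"]]
  point <- suppressWarnings(one_run(stats, "point-estimate"))
  timings$point_estimate <- proc.time()[["elapsed"]] - t1

  network <- NULL
  full_network <- NULL
  if (n_perturbations > 0) {
    sub_seeds <- local_seed(seed,
      sample.int(.Machine$integer.max - 1L, n_perturbations))
    t2 <- proc.time()[["elapsed"]]
    runs <- lapply(seq_len(n_perturbations), function(i) {
      means <- local_seed(sub_seeds[i],
                          perturb_dataset(stats, variance_mode = variance_mode))
      suppressWarnings(one_run(means, i))
    })
    timings$perturbations <- proc.time()[["elapsed"]] - t2
    full_network <- aggregate_networks(runs)
    network <- threshold_network(full_network, weight_threshold)
  }
  timings$total <- proc.time()[["elapsed"]] - t0

  config <- list(
    k = k, alpha = alpha, n_perturbations = n_perturbations,
    virtual_shift = virtual_shift, variance_mode = variance_mode,
    granger_literal = granger_literal, intercept = intercept, seed = seed,
    weight_threshold = weight_threshold, engine = engine,
    n_genes = length(gene_ids),
    n_conditions = length(attr(data, "condition_ids")),
    n_times = length(attr(data, "time_grid")),
    n_replicates = attr(data, "n_replicates")
  )
  structure(
    list(network = network, full_network = full_network,
         point_estimate = point, config = config,
         log = tibble::tibble(stage = names(timings),
                              seconds = unlist(timings))),
    class = "causnet_fit"
  )
}

#' @export
print.causnet_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<causnet_fit> %d genes x %d conditions x %d times x %d reps; k = %d, alpha = %g, B = %d\n",
    cfg$n_genes, cfg$n_conditions, cfg$n_times, cfg$n_replicates, cfg$k,
    cfg$alpha, cfg$n_perturbations
  ))
  if (!is.null(x$network)) {
    cat(sprintf("weighted network: %d edge(s) at weight >= %g\n",
                nrow(x$network), cfg$weight_threshold))
  }
  cat(sprintf("point estimate: %d edge(s)\n", nrow(x$point_estimate)))
  invisible(x)
}

#' @export
tidy.causnet_fit <- function(x, ...) {
  if (!is.null(x$network)) {
    tibble::as_tibble(x$network)
  } else {
    tibble::as_tibble(x$point_estimate)
  }
}

#' @export
glance.causnet_fit <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    n_genes = cfg$n_genes, n_conditions = cfg$n_conditions,
    n_times = cfg$n_times, n_replicates = cfg$n_replicates, k = cfg$k,
    alpha = cfg$alpha, n_perturbations = cfg$n_perturbations,
    virtual_shift = cfg$virtual_shift, seed = cfg$seed %||% NA_integer_,
    n_edges = if (!is.null(x$network)) nrow(x$network) else NA_integer_,
    n_point_edges = nrow(x$point_estimate),
    elapsed = x$log$seconds[x$log$stage == "total"]
  )
}

#' @export
autoplot.causnet_fit <- function(object, ...) {
  if (is.null(object$full_network)) {
    abort("no weighted network to plot (n_perturbations was 0)")
  }
  autoplot(object$full_network, ...)
}

config_fingerprint <- function(config) {
  s <- paste(names(config), vapply(config, function(v) paste(format(v),
             collapse = ","), ""), sep = "=", collapse = ";")
  # small stable rolling hash; identifies the configuration in headers
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 268435399
  sprintf("%07x", h)
}

metadata_header <- function(config = NULL) {
  lines <- c(
    paste0("# causnet version: ",
           as.character(utils::packageVersion("causnet")))
  )
  if (!is.null(config)) {
    lines <- c(
      lines,
      paste0("# config hash: ", config_fingerprint(config)),
      paste0("# seed: ", config$seed %||% "none"),
      paste0("# k: ", config$k, "; alpha: ", config$alpha,
             "; perturbations: ", config$n_perturbations,
             "; virtual_shift: ", config$virtual_shift,
             "; weight_threshold: ", config$weight_threshold)
    )
  }
  lines
}

#' Write a weighted edge list as TSV
#'
#' Columns: regulator, target, sign, existence_weight, sign_weight,
#' n_occurrences; deterministic row order (regulator then target in
#' canonical gene order). A commented metadata header (version, config
#' hash, seed) enables exact reproduction.
#'
#' @param net A `weighted_network` or a `causnet_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_network_tsv <- function(net, path) {
  config <- NULL
  if (inherits(net, "causnet_fit")) {
    config <- net$config
    net <- net$network %||% net$full_network
  }
  stopifnot(inherits(net, "weighted_network"))
  out <- tibble::tibble(
    regulator = net$regulator, target = net$target,
    sign = net$consensus_sign, existence_weight = net$existence_weight,
    sign_weight = net$sign_weight, n_occurrences = net$n_occurrences
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(config), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(lapply(out, format_plain), sep = "\t")), con)
  }
  invisible(path)
}

format_plain <- function(x) {
  if (is.numeric(x)) formatC(x, format = "g", digits = 15) else as.character(x)
}

#' Read a weighted edge list written by [export_network_tsv()]
#'
#' @param path Path to the TSV (commented metadata lines are skipped).
#' @return A `weighted_network` tibble.
#' @export
read_network_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  genes <- unique(c(df$regulator, df$target))
  out <- tibble::tibble(
    regulator = df$regulator, target = df$target,
    existence_weight = df$existence_weight, consensus_sign = df$sign,
    sign_weight = df$sign_weight, n_occurrences = df$n_occurrences
  )
  structure(out, gene_ids = genes, n_perturbations = NA_integer_,
            class = c("weighted_network", class(tibble::tibble())))
}

#' Export a network in Cytoscape SIF format
#'
#' One line per edge: `regulator<TAB>relation<TAB>target`, with relation
#' `activates`, `represses`, or `ambiguous`; deterministic row order; an
#' empty network gives an empty (zero-line) file. Edge weights travel in the
#' companion TSV written by [export_network_tsv()].
#'
#' @param net A `weighted_network` or `causnet_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(net, path) {
  if (inherits(net, "causnet_fit")) net <- net$network %||% net$full_network
  stopifnot(inherits(net, "weighted_network"))
  relation <- c(activation = "activates", repression = "represses",
                ambiguous = "ambiguous")[net$consensus_sign]
  lines <- if (nrow(net) > 0) {
    paste(net$regulator, relation, net$target, sep = "\t")
  } else {
    character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes are genes; edges carry `existence_weight`, `sign`, and
#' `sign_weight` attributes. The file validates against the GraphML schema
#' and is readable by generic GraphML parsers (Cytoscape, igraph, networkx).
#'
#' @param net A `weighted_network` or `causnet_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  if (inherits(net, "causnet_fit")) net <- net$network %||% net$full_network
  stopifnot(inherits(net, "weighted_network"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  xml2::xml_add_child(doc, "key", id = "name", `for` = "node",
                      attr.name = "name", attr.type = "string")
  for (key in list(
    c(id = "existence_weight", type = "double"),
    c(id = "sign", type = "string"),
    c(id = "sign_weight", type = "double")
  )) {
    xml2::xml_add_child(doc, "key", id = key[["id"]], `for` = "edge",
                        attr.name = key[["id"]], attr.type = key[["type"]])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "network",
                               edgedefault = "directed")
  for (g in attr(net, "gene_ids")) {
    node <- xml2::xml_add_child(graph, "node", id = g)
    nd <- xml2::xml_add_child(node, "data", key = "name")
    xml2::xml_set_text(nd, g)
  }
  if (nrow(net) > 0) {
    for (i in seq_len(nrow(net))) {
      e <- xml2::xml_add_child(graph, "edge", source = net$regulator[i],
                               target = net$target[i])
      d1 <- xml2::xml_add_child(e, "data", key = "existence_weight")
      xml2::xml_set_text(d1, formatC(net$existence_weight[i], format = "g",
                                     digits = 15))
      d2 <- xml2::xml_add_child(e, "data", key = "sign")
      xml2::xml_set_text(d2, net$consensus_sign[i])
      d3 <- xml2::xml_add_child(e, "data", key = "sign_weight")
      xml2::xml_set_text(d3, formatC(net$sign_weight[i], format = "g",
                                     digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Diagnostics table of Stage I/II fits
#'
#' Runs Stages I and II once on the unperturbed replicate means and returns
#' the per-target fits and per-regulator Granger tests, for inspection or
#' TSV export.
#'
#' @inheritParams causnet_infer
#' @return A list of two tibbles: `fits` (target, regulator, coefficient,
#'   sign, rss) and `granger` (target, regulator, f_stat, p_value, kept).
#' @export
causnet_diagnostics <- function(data, k = 3, alpha = 0.05,
                                virtual_shift = TRUE, intercept = TRUE,
                                granger_literal = FALSE,
                                engine = c("exhaustive", "greedy")) {
  engine <- match.arg(engine)
  if (!inherits(data, "expression_dataset")) data <- expression_dataset(data)
  stats <- summarize_replicates(data)
  tr <- build_transitions(stats, virtual_shift = virtual_shift)
  gs <- transition_gram(tr, intercept = intercept)
  gene_ids <- attr(data, "gene_ids")
  fits <- lapply(gene_ids, function(tg) fit_target(gs, tg, k = k,
                                                   engine = engine))
  pruned <- lapply(fits, function(f) {
    prune_fit_gram(gs, f, alpha = alpha, literal = granger_literal)
  })
  fit_tbl <- dplyr::bind_rows(lapply(pruned, function(f) {
    tt <- tidy(f)
    if (nrow(tt) > 0) tt$rss <- f$rss
    tt
  }))
  granger_tbl <- dplyr::bind_rows(lapply(pruned, function(f) attr(f, "granger")))
  list(fits = fit_tbl, granger = granger_tbl)
}
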