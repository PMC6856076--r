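#' Construct a validated replicated expression dataset
#'
#' An `expression_dataset` is a long-format tibble of normalized expression
#' values over a complete grid of genes x conditions x time points x
#' replicates, the input shape for lagged network inference: for every
#' (gene, condition, time) cell exactly `n_replicates` finite values must be
#' present. Values are required to be nonnegative (normalized expression)
#' unless `signed = TRUE`, which also disables truncation at zero in the
#' perturbation stage downstream.
#'
#' @param data A data frame with columns `gene`, `condition`, `time`,
#'   `replicate`, `value`.
#' @param genes Optional character vector fixing the gene universe and its
#'   canonical order (e.g. a curated gene list); genes absent from it are
#'   dropped. Default: first-appearance order in `data`.
#' @param signed If `TRUE`, permit negative values (e.g. pre-centered data).
#'
#' @return A tibble of class `expression_dataset` in canonical row order,
#'   carrying the gene/condition/time orderings and replicate count as
#'   attributes.
#' @export
#' @examples
#' ds <- expression_dataset(tibble::tibble(
#'   gene = rep(c("a", "b"), each = 6),
#'   condition = "c1",
#'   time = rep(rep(c("T1", "T3", "T5"), each = 2), 2),
#'   replicate = rep(1:2, 6),
#'   value = abs(rnorm(12))
#' ))
#' dim_grid(ds)
expression_dataset <- function(data, genes = NULL, signed = FALSE) {
  required <- c("gene", "condition", "time", "replicate", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "expression data must have columns gene, condition, time, replicate, ",
      "value; missing: ", paste(missing_cols, collapse = ", ")
    ))
  }
  df <- tibble::as_tibble(data[required])
  df$gene <- as.character(df$gene)
  df$condition <- as.character(df$condition)
  df$time <- as.character(df$time)
  df$value <- as.numeric(df$value)

  if (!is.null(genes)) {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) abort("gene list contains duplicate ids")
    unknown <- setdiff(genes, unique(df$gene))
    if (length(unknown) > 0) {
      abort(paste0(
        "gene list names genes absent from the data: ",
        paste(head(unknown, 5), collapse = ", ")
      ))
    }
    df <- df[df$gene %in% genes, , drop = FALSE]
    gene_ids <- genes
  } else {
    gene_ids <- unique(df$gene)
  }
  condition_ids <- unique(df$condition)
  time_grid <- unique(df$time)

  if (length(time_grid) < 2) {
    abort("at least 2 time points are required for a lagged model")
  }
  if (any(!is.finite(df$value))) {
    abort("expression values must be finite")
  }
  if (!signed && any(df$value < 0)) {
    bad <- df[df$value < 0, ][1, ]
    abort(sprintf(
      "negative expression value at (%s, %s, %s); use signed = TRUE for centered data",
      bad$gene, bad$condition, bad$time
    ))
  }

  # complete-grid check: every cell has the same replicate count
  counts <- dplyr::count(df, .data$gene, .data$condition, .data$time)
  n_rep <- counts$n[1]
  full <- tidyr::expand_grid(
    gene = gene_ids, condition = condition_ids, time = time_grid
  )
  chk <- dplyr::left_join(full, counts, by = c("gene", "condition", "time"))
  bad <- chk[is.na(chk$n) | chk$n != n_rep, , drop = FALSE]
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(sprintf(
      "incomplete expression grid: cell (%s, %s, %s) has %d replicate(s), expected %d",
      b$gene, b$condition, b$time, ifelse(is.na(b$n), 0L, b$n), n_rep
    ))
  }

  df <- dplyr::arrange(
    df,
    match(.data$gene, gene_ids),
    match(.data$condition, condition_ids),
    match(.data$time, time_grid),
    .data$replicate
  )
  structure(
    df,
    gene_ids = gene_ids,
    condition_ids = condition_ids,
    time_grid = time_grid,
    n_replicates = as.integer(n_rep),
    signed = signed,
    class = c("expression_dataset", class(tibble::tibble()))
  )
}

#' Grid dimensions of an expression dataset
#'
#' @param ds An `expression_dataset`.
#' @return Named integer vector `(genes, conditions, times, replicates)`.
#' @export
dim_grid <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  c(
    genes = length(attr(ds, "gene_ids")),
    conditions = length(attr(ds, "condition_ids")),
    times = length(attr(ds, "time_grid")),
    replicates = attr(ds, "n_replicates")
  )
}

#' Read replicated expression data from a delimited file
#'
#' Long format is a tab-separated file with header columns
#' `gene`, `condition`, `time`, `replicate`, `value`. Wide format has a
#' `gene` column followed by one column per sample named
#' `<condition>:<time>:<replicate>`.
#'
#' @param path Path to the file.
#' @param format `"long"` (default) or `"wide"`.
#' @param genes Optional path to a plain-text gene list (one id per line) or
#'   a character vector; fixes the gene universe and canonical order.
#' @inheritParams expression_dataset
#' @return An [expression_dataset].
#' @export
read_expression <- function(path, format = c("long", "wide"), genes = NULL,
                            signed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.character(genes) && length(genes) == 1 && file.exists(genes)) {
    genes <- read_gene_list(genes)
  }
  if (format == "long") {
    # value parsed via base strtod (correctly rounded) for exact round trips
    df <- readr::read_tsv(
      path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(value = readr::col_character())
    )
    df$value <- as.numeric(df$value)
  } else {
    wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (names(wide)[1] != "gene") abort("wide format needs first column 'gene'")
    df <- tidyr::pivot_longer(wide, -"gene", names_to = "sample",
                              values_to = "value")
    parts <- strsplit(df$sample, ":", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      abort("wide column names must be '<condition>:<time>:<replicate>'")
    }
    df$condition <- vapply(parts, `[`, "", 1)
    df$time <- vapply(parts, `[`, "", 2)
    df$replicate <- vapply(parts, `[`, "", 3)
    df$sample <- NULL
  }
  expression_dataset(df, genes = genes, signed = signed)
}

#' Write an expression dataset as a long-format TSV
#'
#' Rows are written in canonical (gene, condition, time, replicate) order so
#' a read/write round trip is exact.
#'
#' @param ds An [expression_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  out <- tibble::as_tibble(ds)
  # full binary precision so a write/read round trip is exact
  out$value <- sprintf("%.17g", out$value)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Per-cell replicate mean and sample variance
#'
#' Summarizes biological replicates of each (gene, condition, time) cell into
#' the mean and the unbiased (n-1 denominator) sample variance. The means
#' feed the lagged regressions; the variances parameterize the
#' truncated-Gaussian perturbation stage.
#'
#' @param ds An [expression_dataset].
#' @return A tibble of class `replicate_stats` with columns `gene`,
#'   `condition`, `time`, `mean`, `variance`, `n`.
#' @export
summarize_replicates <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ds), .data$gene, .data$condition,
                    .data$time),
    mean = mean(.data$value),
    variance = if (dplyr::n() > 1) stats::var(.data$value) else 0,
    n = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(
    out,
    match(.data$gene, attr(ds, "gene_ids")),
    match(.data$condition, attr(ds, "condition_ids")),
    match(.data$time, attr(ds, "time_grid"))
  )
  structure(
    out,
    gene_ids = attr(ds, "gene_ids"),
    condition_ids = attr(ds, "condition_ids"),
    time_grid = attr(ds, "time_grid"),
    n_replicates = attr(ds, "n_replicates"),
    signed = attr(ds, "signed"),
    class = c("replicate_stats", class(tibble::tibble()))
  )
}

# Accept a replicate_stats tibble (uses `mean`) or a plain mean grid with a
# `value` column; returns a list of per-time gene matrices plus orderings.
mean_grid_matrices <- function(means) {
  col <- if ("mean" %in% names(means)) "mean" else "value"
  gene_ids <- attr(means, "gene_ids") %||% unique(means$gene)
  condition_ids <- attr(means, "condition_ids") %||% unique(means$condition)
  time_grid <- attr(means, "time_grid") %||% unique(means$time)
  arr <- array(
    NA_real_,
    dim = c(length(condition_ids), length(gene_ids), length(time_grid)),
    dimnames = list(condition_ids, gene_ids, time_grid)
  )
  arr[cbind(
    match(means$condition, condition_ids),
    match(means$gene, gene_ids),
    match(means$time, time_grid)
  )] <- means[[col]]
  if (anyNA(arr)) abort("mean grid is incomplete")
  list(arr = arr, gene_ids = gene_ids, condition_ids = condition_ids,
       time_grid = time_grid, signed = isTRUE(attr(means, "signed")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build time-lagged transition samples from a mean expression grid
#'
#' Each row of a transition set pairs the expression of all genes at a source
#' time point (the predictors) with their expression at the following time
#' point (the responses), within one condition. With `virtual_shift = TRUE`
#' an additional wrapped transition (last time point -> first time point of
#' the same condition) is added per condition, standing in for the overnight
#' interval that the sampling design leaves unobserved.
#'
#' @param means A `replicate_stats` tibble (from [summarize_replicates()]) or
#'   a mean grid with columns `gene`, `condition`, `time`, `value`.
#' @param virtual_shift Add the wrapped last-to-first transition per
#'   condition.
#' @return An object of class `transition_set`: predictor and response
#'   matrices (rows = transitions, columns = genes in canonical order) and a
#'   label tibble (`condition`, `from`, `to`).
#' @export
build_transitions <- function(means, virtual_shift = FALSE) {
  g <- mean_grid_matrices(means)
  n_t <- length(g$time_grid)
  if (n_t < 2) abort("at least 2 time points are required")
  src <- seq_len(n_t - 1)
  dst <- src + 1
  if (virtual_shift) {
    src <- c(src, n_t)
    dst <- c(dst, 1L)
  }
  pred <- do.call(rbind, lapply(seq_along(src), function(i) g$arr[, , src[i]]))
  resp <- do.call(rbind, lapply(seq_along(src), function(i) g$arr[, , dst[i]]))
  labels <- tibble::tibble(
    condition = rep(g$condition_ids, times = length(src)),
    from = rep(g$time_grid[src], each = length(g$condition_ids)),
    to = rep(g$time_grid[dst], each = length(g$condition_ids))
  )
  # canonical row order: condition-major within transition blocks; reorder to
  # condition, then transition, for readability
  ord <- order(match(labels$condition, g$condition_ids),
               match(labels$from, g$time_grid))
  structure(
    list(
      predictors = pred[ord, , drop = FALSE],
      responses = resp[ord, , drop = FALSE],
      labels = labels[ord, ],
      gene_ids = g$gene_ids,
      virtual_shift = virtual_shift
    ),
    class = "transition_set"
  )
}

#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf(
    "<transition_set> %d transitions x %d genes (virtual shift: %s)\n",
    nrow(x$predictors), length(x$gene_ids),
    ifelse(x$virtual_shift, "on", "off")
  ))
  print(x$labels, n = 6)
  invisible(x)
}

#' @export
tidy.transition_set <- function(x, ...) {
  pred <- x$predictors
  resp <- x$responses
  colnames(pred) <- paste0(x$gene_ids, "_from")
  colnames(resp) <- paste0(x$gene_ids, "_to")
  dplyr::bind_cols(x$labels, tibble::as_tibble(pred), tibble::as_tibble(resp))
}
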