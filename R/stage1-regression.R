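#' Ordinary least squares with a minimum-norm fallback
#'
#' Fits `response ~ design` by QR; if the design is rank deficient the
#' minimum-norm solution is returned via the singular value decomposition and
#' flagged.
#'
#' @param design Numeric matrix (rows = observations).
#' @param response Numeric vector.
#' @return A list with `coefficients`, `rss`, and `rank_deficient`.
#' @export
least_squares <- function(design, response) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  if (nrow(design) == 0) abort("least_squares: zero observations")
  if (nrow(design) != length(response)) {
    abort("design and response disagree on the number of observations")
  }
  qrd <- qr(design)
  if (qrd$rank == ncol(design)) {
    beta <- qr.coef(qrd, response)
    deficient <- FALSE
  } else {
    sv <- svd(design)
    tol <- max(dim(design)) * .Machine$double.eps * max(sv$d, 1)
    pos <- sv$d > tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], response)) / sv$d[pos])
    beta <- drop(beta)
    deficient <- TRUE
  }
  resid <- response - drop(design %*% beta)
  list(coefficients = unname(beta), rss = sum(resid^2),
       rank_deficient = deficient)
}

# Precompute the Gram system shared by every subset fit on one transition
# set: design columns are [intercept?, gene 1, ..., gene G] lagged values.
# Solving each (k+2)x(k+2) subsystem from this is what makes the exhaustive
# search tractable at study scale.
transition_gram <- function(transitions, intercept = TRUE) {
  Z <- transitions$predictors
  if (intercept) Z <- cbind(`(Intercept)` = 1, Z)
  list(
    gram = crossprod(Z),
    xty = crossprod(Z, transitions$responses),  # one column per target
    yty = colSums(transitions$responses^2),
    n_obs = nrow(Z),
    intercept = intercept,
    gene_ids = transitions$gene_ids,
    col_offset = if (intercept) 1L else 0L
  )
}

# Least squares for one column subset straight from the Gram system.
# idx are 1-based columns of the full design. Normal equations are always
# consistent, so rss = y'y - b'X'y for the exact solution.
ls_from_gram <- function(gs, idx, target_col) {
  A <- gs$gram[idx, idx, drop = FALSE]
  b <- gs$xty[idx, target_col]
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  deficient <- is.null(beta)
  if (deficient) {
    sv <- svd(A)
    tol <- nrow(A) * .Machine$double.eps * max(sv$d, 1)
    pos <- sv$d > tol
    beta <- drop(sv$v[, pos, drop = FALSE] %*%
                   (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos]))
  }
  rss <- gs$yty[target_col] - 2 * sum(beta * b) + drop(crossprod(beta, A %*% beta))
  list(coefficients = beta, rss = max(rss, 0), rank_deficient = deficient)
}

new_sparse_fit <- function(target, regulators, coefficients, self_coefficient,
                           intercept, rss, n_obs, k, intercept_on,
                           rank_deficient) {
  structure(
    list(
      target = target,
      regulators = regulators,
      coefficients = setNames(coefficients, regulators),
      self_coefficient = self_coefficient,
      intercept = intercept,
      rss = rss,
      n_obs = n_obs,
      k = k,
      intercept_on = intercept_on,
      rank_deficient = rank_deficient
    ),
    class = "sparse_fit"
  )
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("<sparse_fit> target %s: %d regulator(s), rss %.4g (n = %d)\n",
              x$target, length(x$regulators), x$rss, x$n_obs))
  if (length(x$regulators) > 0) {
    print(tidy(x))
  }
  invisible(x)
}

#' @export
tidy.sparse_fit <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    regulator = x$regulators,
    coefficient = unname(x$coefficients),
    sign = classify_sign(unname(x$coefficients))
  )
}

#' @export
glance.sparse_fit <- function(x, ...) {
  tibble::tibble(
    target = x$target, n_regulators = length(x$regulators), rss = x$rss,
    n_obs = x$n_obs, self_coefficient = x$self_coefficient,
    intercept = x$intercept, rank_deficient = x$rank_deficient
  )
}

#' Best size-k regulator subset for one target gene
#'
#' Exhaustively enumerates every size-`k` subset of the candidate regulators
#' and fits, for each, the lagged linear model whose design holds an
#' intercept (optional), the target's own lagged expression, and the `k`
#' candidate genes' lagged expression; the subset with the minimum residual
#' sum of squares is returned with its signed coefficients. Ties in rss
#' (within 1e-12 relative) resolve to the subset earliest in canonical gene
#' order. The target's own lag is part of the model but is never reported as
#' an edge.
#'
#' @param transitions A `transition_set` from [build_transitions()].
#' @param target Target gene id.
#' @param k Number of regulators to select (the sparsity bound; the study
#'   default downstream is 3).
#' @param candidates Candidate regulator ids; default all genes except the
#'   target.
#' @param intercept Include an intercept absorbing the mean nominal
#'   production rate (default `TRUE`).
#' @param engine `"exhaustive"` (default; the definition of the method) or
#'   `"greedy"` forward selection for large gene sets.
#' @return A `sparse_fit` object.
#' @export
best_subset_fit <- function(transitions, target, k = 3, candidates = NULL,
                            intercept = TRUE,
                            engine = c("exhaustive", "greedy")) {
  engine <- match.arg(engine)
  gs <- transition_gram(transitions, intercept = intercept)
  fit_target(gs, target, k = k, candidates = candidates, engine = engine)
}

# Shared worker: fit one target from a precomputed Gram system.
fit_target <- function(gs, target, k, candidates = NULL,
                       engine = "exhaustive") {
  genes <- gs$gene_ids
  if (!target %in% genes) abort(paste0("unknown target gene: ", target))
  if (is.null(candidates)) candidates <- setdiff(genes, target)
  if (target %in% candidates) {
    abort("candidates must not include the target gene")
  }
  if (length(candidates) < k) {
    abort(sprintf("need at least k = %d candidates, got %d", k,
                  length(candidates)))
  }
  # candidates in canonical order so the lexicographic tie-break is canonical
  candidates <- genes[genes %in% candidates]
  tcol <- match(target, genes)
  off <- gs$col_offset
  fixed <- c(if (gs$intercept) 1L else integer(0), tcol + off)
  cand_cols <- match(candidates, genes) + off

  if (engine == "exhaustive") {
    res <- best_subset_search(gs$gram, gs$xty[, tcol], gs$yty[tcol],
                              fixed - 1L, cand_cols - 1L, as.integer(k))
    chosen_cols <- res$subset + 1L
    coefs <- res$coefficients
    rss <- res$rss
    deficient <- res$rank_deficient
  } else {
    sel <- greedy_forward(gs, tcol, fixed, cand_cols, k)
    chosen_cols <- sel$cols
    fitted <- ls_from_gram(gs, c(fixed, chosen_cols), tcol)
    coefs <- fitted$coefficients
    rss <- fitted$rss
    deficient <- fitted$rank_deficient
  }
  nf <- length(fixed)
  regs <- genes[chosen_cols - off]
  if (deficient) {
    warn(sprintf("best design for target %s is rank deficient", target))
  }
  new_sparse_fit(
    target = target,
    regulators = regs,
    coefficients = coefs[(nf + 1):(nf + k)],
    self_coefficient = coefs[nf],
    intercept = if (gs$intercept) coefs[1] else 0,
    rss = rss,
    n_obs = gs$n_obs,
    k = k,
    intercept_on = gs$intercept,
    rank_deficient = deficient
  )
}

# Greedy forward selection: add the candidate giving the largest rss drop,
# k times. Matches the exhaustive search when effects are strong; offered for
# gene sets where C(G-1, k) is out of reach.
greedy_forward <- function(gs, tcol, fixed, cand_cols, k) {
  chosen <- integer(0)
  remaining <- cand_cols
  for (step in seq_len(k)) {
    rsss <- vapply(remaining, function(cc) {
      ls_from_gram(gs, c(fixed, chosen, cc), tcol)$rss
    }, 0)
    pick <- which.min(rsss)
    chosen <- c(chosen, remaining[pick])
    remaining <- remaining[-pick]
  }
  list(cols = sort(chosen))
}

#' Classify a regression coefficient as activation or repression
#'
#' Positive coefficients indicate activation, negative repression; an exact
#' zero carries no regulation and yields `NA` (the edge is dropped).
#'
#' @param coefficient Numeric vector of coefficients.
#' @return Character vector: `"activation"`, `"repression"`, or `NA`.
#' @export
classify_sign <- function(coefficient) {
  dplyr::case_when(
    coefficient > 0 ~ "activation",
    coefficient < 0 ~ "repression",
    .default = NA_character_
  )
}

# All-targets Stage I sweep on one transition set; returns a named list of
# sparse_fit objects. Used by the pipeline per perturbation.
fit_all_targets <- function(transitions, k = 3, intercept = TRUE,
                            engine = "exhaustive", targets = NULL) {
  gs <- transition_gram(transitions, intercept = intercept)
  targets <- targets %||% gs$gene_ids
  fits <- lapply(targets, function(tg) {
    fit_target(gs, tg, k = k, engine = engine)
  })
  names(fits) <- targets
  fits
}
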