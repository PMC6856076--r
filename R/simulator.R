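#' Sample a sparse signed ground-truth regulatory network
#'
#' Draws a ground-truth coefficient matrix for the discrete-time linear
#' expression model `x(t+1) = A x(t) + b + noise`: every gene (row) receives
#' exactly `k_true` off-diagonal regulators chosen uniformly, with
#' coefficient magnitudes uniform in `coeff_range` and negative sign with
#' probability `sign_prob`, plus a self-persistence term on the diagonal.
#' Cycles and feedback loops are permitted — the matrix is never forced
#' acyclic. If the spectral radius exceeds `spectral_cap` the matrix is
#' rescaled to it (so trajectories stay bounded), and off-diagonal
#' magnitudes are then floored at `effect_floor` so true edges remain
#' statistically visible at small designs; if the two constraints conflict
#' the spectral cap wins and a warning is issued.
#'
#' @param n_genes Number of genes G.
#' @param k_true True regulators per gene (< G).
#' @param coeff_range Magnitude range (low, high) for off-diagonal
#'   coefficients, `0 < low <= high`.
#' @param sign_prob Probability an edge is repressing (negative).
#' @param self_range Range for the diagonal self-persistence term, inside
#'   (0, 1).
#' @param intercept_range Range for the per-gene basal production term `b`.
#' @param process_sd Standard deviation of the Gaussian nominal-production
#'   noise entering the dynamics.
#' @param measurement_sd Standard deviation of the replicate-level
#'   measurement noise.
#' @param spectral_cap Upper bound imposed on the spectral radius.
#' @param effect_floor Minimum off-diagonal magnitude after rescaling.
#' @param seed Optional seed (caller's RNG stream is left untouched).
#' @return An object of class `ground_truth`: `coefficients` (G x G matrix,
#'   rows = targets, columns = regulators), `intercepts`, `process_sd`,
#'   `measurement_sd`, `gene_ids`.
#' @export
sample_network <- function(n_genes, k_true, coeff_range = c(0.3, 0.8),
                           sign_prob = 0.3, self_range = c(0.2, 0.5),
                           intercept_range = c(0.5, 2),
                           process_sd = 0.1, measurement_sd = 0.1,
                           spectral_cap = 0.95, effect_floor = 0.3,
                           seed = NULL) {
  if (k_true >= n_genes) abort("k_true must be smaller than n_genes")
  if (coeff_range[1] <= 0 || coeff_range[1] > coeff_range[2]) {
    abort("coeff_range must satisfy 0 < low <= high")
  }
  local_seed(seed, {
    gene_ids <- sprintf("g%02d", seq_len(n_genes))
    A <- matrix(0, n_genes, n_genes, dimnames = list(gene_ids, gene_ids))
    for (i in seq_len(n_genes)) {
      regs <- sample(setdiff(seq_len(n_genes), i), k_true)
      mag <- runif(k_true, coeff_range[1], coeff_range[2])
      sgn <- ifelse(runif(k_true) < sign_prob, -1, 1)
      A[i, regs] <- sgn * mag
    }
    diag(A) <- runif(n_genes, self_range[1], self_range[2])
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho > spectral_cap) {
      A <- A * (spectral_cap / rho)
      off <- A != 0 & row(A) != col(A)
      small <- off & abs(A) < effect_floor
      if (any(small)) {
        A[small] <- sign(A[small]) * effect_floor
        rho2 <- max(Mod(eigen(A, only.values = TRUE)$values))
        if (rho2 > spectral_cap) {
          # stability wins over the floor; warn only on a material violation
          A <- A * (spectral_cap / rho2)
          if (min(abs(A[off])) < 0.8 * effect_floor) {
            warn("effect floor relaxed to keep the spectral radius bounded")
          }
        }
      }
    }
    b <- runif(n_genes, intercept_range[1], intercept_range[2])
    structure(
      list(coefficients = A, intercepts = setNames(b, gene_ids),
           process_sd = process_sd, measurement_sd = measurement_sd,
           gene_ids = gene_ids),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d genes, %d true edges, process sd %.3g, measurement sd %.3g\n",
    length(x$gene_ids), nrow(true_edges(x)), x$process_sd, x$measurement_sd
  ))
  invisible(x)
}

#' True edge list of a ground-truth network
#'
#' @param gt A `ground_truth` object.
#' @return Tibble `regulator`, `target`, `coefficient`, `sign`
#'   (off-diagonal nonzeros; the self-persistence diagonal is not an edge).
#' @export
true_edges <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  A <- gt$coefficients
  idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
  out <- tibble::tibble(
    regulator = gt$gene_ids[idx[, "col"]],
    target = gt$gene_ids[idx[, "row"]],
    coefficient = A[idx]
  )
  out$sign <- classify_sign(out$coefficient)
  dplyr::arrange(out, match(.data$regulator, gt$gene_ids),
                 match(.data$target, gt$gene_ids))
}

#' Simulate a replicated multi-condition expression time course
#'
#' Generates data from the discrete-time linear-Gaussian model underlying
#' the inference method. Per condition, an initial state is drawn around the
#' model's fixed point `(I - A)^{-1} b` (standard deviation `init_sd`,
#' giving cross-condition diversity analogous to genotype or photoperiod
#' contrasts), the latent trajectory follows
#' `x(t+1) = A x(t) + b + eta_t` with i.i.d. Gaussian process noise, and
#' each replicate adds Gaussian measurement noise to the latent value.
#'
#' Nonnegativity handling (`nonneg`): `"shift"` (default) adds one constant
#' per gene so all its values are nonnegative — an affine change that
#' preserves the linear dynamics (only the effective intercept changes), so
#' the coefficient matrix remains exactly recoverable; `"clip"` truncates at
#' zero (breaks linearity; off by default); `"none"` leaves values signed
#' and marks the dataset as signed.
#'
#' @param gt A `ground_truth` from [sample_network()].
#' @param n_conditions,n_times,n_replicates Design geometry (defaults mirror
#'   a typical multi-genotype photoperiod study: 18 conditions, 3 daily time
#'   points, 3 biological replicates).
#' @param init_sd Standard deviation of the initial-state draw around the
#'   fixed point.
#' @param nonneg `"shift"`, `"clip"`, or `"none"`.
#' @param seed Optional seed.
#' @return An [expression_dataset].
#' @export
simulate_dataset <- function(gt, n_conditions = 18, n_times = 3,
                             n_replicates = 3, init_sd = 1,
                             nonneg = c("shift", "clip", "none"),
                             seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  nonneg <- match.arg(nonneg)
  if (n_times < 2) abort("n_times must be at least 2")
  G <- length(gt$gene_ids)
  local_seed(seed, {
    A <- gt$coefficients
    b <- gt$intercepts
    mu <- solve(diag(G) - A, b)
    # latent[, g, t] per condition
    lat <- array(NA_real_, dim = c(n_conditions, G, n_times))
    for (cc in seq_len(n_conditions)) {
      x <- mu + rnorm(G, sd = init_sd)
      lat[cc, , 1] <- x
      for (tt in seq_len(n_times - 1)) {
        x <- drop(A %*% x) + b + rnorm(G, sd = gt$process_sd)
        lat[cc, , tt + 1] <- x
      }
    }
    obs <- array(
      rep(lat, n_replicates) +
        rnorm(length(lat) * n_replicates, sd = gt$measurement_sd),
      dim = c(n_conditions, G, n_times, n_replicates)
    )
    signed <- FALSE
    if (nonneg == "shift") {
      for (g in seq_len(G)) {
        m <- min(obs[, g, , ])
        if (m < 0) obs[, g, , ] <- obs[, g, , ] - m
      }
    } else if (nonneg == "clip") {
      obs[obs < 0] <- 0
    } else {
      signed <- TRUE
    }
    condition_ids <- sprintf("c%02d", seq_len(n_conditions))
    time_grid <- paste0("T", seq_len(n_times))
    df <- tidyr::expand_grid(
      gene = gt$gene_ids, condition = condition_ids, time = time_grid,
      replicate = seq_len(n_replicates)
    )
    df$value <- obs[cbind(
      match(df$condition, condition_ids),
      match(df$gene, gt$gene_ids),
      match(df$time, time_grid),
      df$replicate
    )]
    expression_dataset(df, genes = gt$gene_ids, signed = signed)
  })
}

#' Score an inferred weighted network against the simulated truth
#'
#' Edges with existence weight at or above `threshold` are called positive
#' and compared with the ground-truth edge set: precision, recall, F1, the
#' fraction of true-positive edges whose consensus sign matches the true
#' coefficient sign, and the area under the precision-recall curve swept
#' over the observed existence weights. When no edge is predicted,
#' precision (and F1, sign accuracy) is `NA`, a distinguished null — never
#' silently 0 or 1.
#'
#' @param net A `weighted_network`.
#' @param gt The `ground_truth` the data were simulated from.
#' @param threshold Existence-weight cut-off for the point metrics.
#' @return One-row tibble: `precision`, `recall`, `f1`, `sign_accuracy`,
#'   `aupr`, `n_predicted`, `n_true`.
#' @export
evaluate_recovery <- function(net, gt, threshold = 0.5) {
  stopifnot(inherits(net, "weighted_network"), inherits(gt, "ground_truth"))
  if (!setequal(attr(net, "gene_ids"), gt$gene_ids)) {
    abort("network and ground truth cover different gene universes")
  }
  truth <- true_edges(gt)
  truth_key <- paste(truth$regulator, truth$target, sep = "\r")
  pred <- net[net$existence_weight >= threshold, , drop = FALSE]
  pred_key <- paste(pred$regulator, pred$target, sep = "\r")
  tp_idx <- pred_key %in% truth_key
  tp <- sum(tp_idx)
  n_pred <- nrow(pred)
  n_true <- nrow(truth)
  precision <- if (n_pred == 0) NA_real_ else tp / n_pred
  recall <- if (n_true == 0) NA_real_ else tp / n_true
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  sign_accuracy <- if (tp == 0) {
    NA_real_
  } else {
    true_sign <- truth$sign[match(pred_key[tp_idx], truth_key)]
    mean(pred$consensus_sign[tp_idx] == true_sign)
  }
  tibble::tibble(
    precision = precision, recall = recall, f1 = f1,
    sign_accuracy = sign_accuracy,
    aupr = aupr(net, truth_key), n_predicted = n_pred, n_true = n_true
  )
}

# Area under the precision-recall curve over existence-weight thresholds:
# edges ranked by weight, curve stepped at each distinct weight, integrated
# over recall increments.
aupr <- function(net, truth_key) {
  n_true <- length(truth_key)
  if (n_true == 0) return(NA_real_)
  if (nrow(net) == 0) return(0)
  key <- paste(net$regulator, net$target, sep = "\r")
  w <- net$existence_weight
  is_tp <- key %in% truth_key
  ord <- order(-w)
  w <- w[ord]
  is_tp <- is_tp[ord]
  cum_tp <- cumsum(is_tp)
  n_pred <- seq_along(is_tp)
  # evaluate only at the last index of each distinct weight (threshold sweep)
  last <- which(w != c(w[-1], NA_real_) | seq_along(w) == length(w))
  prec <- cum_tp[last] / n_pred[last]
  rec <- cum_tp[last] / n_true
  prev_rec <- c(0, rec[-length(rec)])
  sum((rec - prev_rec) * prec)
}

#' Precision-recall curve over existence-weight thresholds
#'
#' @param net A `weighted_network`.
#' @param gt The matching `ground_truth`.
#' @return Tibble `threshold`, `precision`, `recall` (one row per distinct
#'   weight, descending).
#' @export
pr_curve <- function(net, gt) {
  truth <- true_edges(gt)
  truth_key <- paste(truth$regulator, truth$target, sep = "\r")
  thresholds <- sort(unique(net$existence_weight), decreasing = TRUE)
  purrr::map_dfr(thresholds, function(th) {
    m <- evaluate_recovery(net, gt, threshold = th)
    tibble::tibble(threshold = th, precision = m$precision,
                   recall = m$recall)
  })
}

#' Write a ground-truth edge list as TSV
#'
#' @param gt A `ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  readr::write_tsv(true_edges(gt), path, progress = FALSE)
  invisible(path)
}
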