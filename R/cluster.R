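#' Two-way clustering of the core trans-association matrix
#'
#' Hierarchically clusters the core-set CpG x gene matrix of (corrected) t
#' statistics with Euclidean distance, cutting both trees at k = 2. Entries
#' of non-significant pairs should be set to 0 before calling (the
#' convention used when rendering the association heatmap, where absence of
#' signal is blank). The result is deterministic and invariant to row or
#' column permutations of the input.
#'
#' @param t_matrix numeric CpG x gene matrix, no missing entries.
#' @param linkage agglomeration method (default `"complete"`; `"ward.D2"`
#'   and `"average"` are sensible alternatives).
#' @return a `trans_heatmap` list: `matrix`, `row_clusters`,
#'   `col_clusters` (named integer vectors in {1, 2}), `row_order`,
#'   `col_order`, `row_tree`, `col_tree`.
#' @export
cluster_core_set <- function(t_matrix, linkage = "complete") {
  stopifnot(is.matrix(t_matrix))
  .stop_if(anyNA(t_matrix), "matrix has missing entries; set non-significant pairs to 0")
  .stop_if(nrow(t_matrix) < 2 || ncol(t_matrix) < 2,
           "need at least 2 rows and 2 columns")
  .stop_if(all(t_matrix == 0), "all-zero matrix: no valid 2-cluster split")
  row_tree <- stats::hclust(stats::dist(t_matrix), method = linkage)
  col_tree <- stats::hclust(stats::dist(t(t_matrix)), method = linkage)
  structure(list(matrix = t_matrix,
                 row_clusters = stats::cutree(row_tree, k = 2),
                 col_clusters = stats::cutree(col_tree, k = 2),
                 row_order = row_tree$order,
                 col_order = col_tree$order,
                 row_tree = row_tree, col_tree = col_tree,
                 linkage = linkage),
            class = "trans_heatmap")
}

#' @export
print.trans_heatmap <- function(x, ...) {
  cat(sprintf("<trans_heatmap> %d CpGs x %d genes, %s linkage; row clusters %d/%d, column clusters %d/%d\n",
              nrow(x$matrix), ncol(x$matrix), x$linkage,
              sum(x$row_clusters == 1), sum(x$row_clusters == 2),
              sum(x$col_clusters == 1), sum(x$col_clusters == 2)))
  invisible(x)
}

#' Plot the clustered trans-association heatmap
#' @param x a `trans_heatmap`.
#' @param ... passed to [stats::heatmap()].
#' @export
plot.trans_heatmap <- function(x, ...) {
  stats::heatmap(x$matrix,
                 Rowv = stats::as.dendrogram(x$row_tree),
                 Colv = stats::as.dendrogram(x$col_tree),
                 scale = "none",
                 col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}

#' Min-max normalization of a per-feature profile across cell types
#'
#' `x_norm = (x - min(x)) / max(x - min(x))`, applied per row (gene or
#' CpG), so every non-constant profile spans exactly [0, 1]. Constant
#' profiles are undefined and emitted as `NA` rather than an error; the
#' operation is idempotent.
#'
#' @param x numeric matrix, features x cell types (or a single profile
#'   vector).
#' @return matrix (or vector) of the same shape.
#' @export
minmax_normalize_profiles <- function(x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  .stop_if(ncol(x) == 0, "empty profile")
  .stop_if(ncol(x) < 2, "need >= 2 cell types")
  lo <- apply(x, 1, min, na.rm = TRUE)
  span <- apply(x, 1, max, na.rm = TRUE) - lo
  out <- (x - lo) / span
  out[span == 0, ] <- NA_real_
  if (vec) out <- drop(out)
  out
}

#' Welch t test of a cluster's normalized medians between cell-type groups
#'
#' Given per-feature median normalized values across cell types, tests
#' whether the members of one cluster differ between two groups of cell
#' types (e.g. naive versus late-activated compartments). Each member
#' contributes the mean of its values over the group's cell types; a
#' two-sample Welch (unequal-variance) t test compares the members'
#' group-A values against their group-B values. Run it separately per
#' cluster.
#'
#' @param profiles feature x cell-type matrix of (normalized) medians.
#' @param members character vector of features in the cluster.
#' @param group_a,group_b character vectors of cell-type column names.
#' @param paired pair the per-member group means instead of the default
#'   two-sample Welch comparison.
#' @return list with `t`, `p`, `n`.
#' @export
differential_group_test <- function(profiles, members, group_a, group_b,
                                    paired = FALSE) {
  .stop_if(length(group_a) == 0 || length(group_b) == 0, "empty cell-type group")
  .stop_if(length(members) == 0, "empty member set")
  rows <- profiles[members, , drop = FALSE]
  a <- rowMeans(rows[, group_a, drop = FALSE], na.rm = TRUE)
  b <- rowMeans(rows[, group_b, drop = FALSE], na.rm = TRUE)
  keep <- is.finite(a) & is.finite(b)
  .stop_if(sum(keep) < 2, "fewer than 2 members with values in both groups")
  a <- a[keep]; b <- b[keep]
  # Welch computed directly so that near-constant groups with separated
  # means give t = +-Inf, p = 0 instead of an error
  if (paired) {
    d <- a - b
    se <- stats::sd(d) / sqrt(length(d))
    est <- mean(d)
    df <- length(d) - 1
  } else {
    va <- stats::var(a) / length(a)
    vb <- stats::var(b) / length(b)
    se <- sqrt(va + vb)
    est <- mean(a) - mean(b)
    df <- if (va + vb == 0) 1 else
      (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  }
  if (se == 0) {
    t <- if (est == 0) 0 else sign(est) * Inf
  } else t <- est / se
  list(t = t, p = if (t == 0) 1 else 2 * stats::pt(-abs(t), df),
       n = sum(keep))
}

#' Apply clocks to sorted-cell methylation profiles
#'
#' @param clocks named list of [clock_model()] objects.
#' @param sorted_ref a `sorted_cell_reference` (see
#'   [emit_sorted_cell_reference()]) or a list with `beta` (sample x CpG)
#'   and `samples` (data.frame `sample`, `donor`, `lineage`, `phenotype`).
#' @param max_missing_frac forwarded to [predict_age()].
#' @return data.frame: one row per sample x clock with `sample`, `donor`,
#'   `lineage`, `phenotype`, `clock`, `predicted_age`.
#' @export
predict_sorted_cell_ages <- function(clocks, sorted_ref,
                                     max_missing_frac = 0.2) {
  info <- sorted_ref$samples
  beta <- sorted_ref$beta
  out <- lapply(names(clocks), function(nm) {
    pred <- predict_age(clocks[[nm]], beta, max_missing_frac = max_missing_frac)
    data.frame(info, clock = nm, predicted_age = pred$predicted_age,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Paired naive-versus-activated age-prediction differences
#'
#' For every clock x lineage, pairs each donor's activated sample with its
#' naive sample, and reports the median paired difference (activated -
#' naive, years) with a paired t-test p value.
#'
#' @param predictions output of [predict_sorted_cell_ages()].
#' @return a `delta_age_result` data.frame: `clock`, `lineage`,
#'   `median_delta`, `p`, `n_donors`, `stars`.
#' @export
paired_delta_age <- function(predictions) {
  combos <- unique(predictions[, c("clock", "lineage")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- predictions[predictions$clock == combos$clock[i] &
                         predictions$lineage == combos$lineage[i], ]
    naive <- sub[sub$phenotype == "naive", ]
    act <- sub[sub$phenotype == "activated", ]
    .stop_if(!setequal(naive$donor, act$donor) ||
               anyDuplicated(naive$donor) || anyDuplicated(act$donor),
             sprintf("broken pairing for %s / %s: each donor needs exactly one naive and one activated sample",
                     combos$clock[i], combos$lineage[i]))
    delta <- act$predicted_age[match(naive$donor, act$donor)] - naive$predicted_age
    .stop_if(length(delta) < 2, "need >= 2 donors for a paired test")
    p <- if (stats::sd(delta) == 0) {
      if (all(delta == 0)) 1 else NA_real_  # constant nonzero differences: t undefined
    } else stats::t.test(delta)$p.value
    data.frame(clock = combos$clock[i], lineage = combos$lineage[i],
               median_delta = stats::median(delta), p = p,
               n_donors = length(delta),
               stars = if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delta_age_result", "data.frame")
  out
}
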