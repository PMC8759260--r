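#' Write all cohort artifacts to a directory
#'
#' Emits the beta matrix, count matrix and covariates as TSV (samples in
#' rows), CpG coordinates and gene annotation as TSV, the true clock in
#' the coefficient CSV dialect, and QTL truth tables when present. Every
#' file round-trips through the matching reader bit-exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param truth the matching `ground_truth` (optional; writes the true
#'   clock and cluster labels when given).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"), "sample")
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"), "sample")
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$cpg_coords, file.path(dir, "cpg_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$gene_coords, file.path(dir, "gene_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    write_clock_model(truth$true_clock, file.path(dir, "true_clock.csv"))
    labels <- data.frame(id = c(names(truth$cpg_cluster_labels),
                                names(truth$gene_cluster_labels)),
                         label = c(unname(truth$cpg_cluster_labels),
                                   unname(truth$gene_cluster_labels)),
                         stringsAsFactors = FALSE)
    utils::write.table(labels, file.path(dir, "cluster_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth$qtl_truth)) {
      write_qtl_table(truth$qtl_truth$cis_meqtl,
                      file.path(dir, "cis_meqtl.tsv"))
      write_qtl_table(truth$qtl_truth$trans_eqtl,
                      file.path(dir, "trans_eqtl.tsv"))
    }
  }
  invisible(dir)
}

#' Read cohort artifacts written by [write_cohort()]
#' @param dir directory holding the artifacts.
#' @return a `synthetic_cohort`-shaped list.
#' @export
read_cohort <- function(dir) {
  covariates <- utils::read.table(file.path(dir, "covariates.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  rownames(covariates) <- covariates$sample
  structure(list(
    beta = read_matrix_tsv(file.path(dir, "beta.tsv")),
    counts = read_matrix_tsv(file.path(dir, "counts.tsv")),
    covariates = covariates,
    cpg_coords = utils::read.table(file.path(dir, "cpg_coords.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE),
    gene_coords = utils::read.table(file.path(dir, "gene_annotation.tsv"),
                                    header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE),
    replicate_pairs = NULL, genotypes = NULL),
    class = "synthetic_cohort")
}

#' Write / read a sorted-cell reference panel
#'
#' TSV with columns `sample`, `donor`, `lineage`, `phenotype`, then one
#' column per CpG.
#'
#' @param ref a `sorted_cell_reference`.
#' @param path output TSV.
#' @export
write_sorted_reference <- function(ref, path) {
  df <- cbind(ref$samples,
              as.data.frame(apply(ref$beta, 2, .fmt_num),
                            stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sorted_reference
#' @export
read_sorted_reference <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample", "donor", "lineage", "phenotype")
  beta <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- df$sample
  structure(list(beta = beta, samples = df[, meta],
                 beta_medians = NULL, expr_medians = NULL),
            class = "sorted_cell_reference")
}

#' Write association results in long format
#'
#' One row per tested (non-excluded) CpG-gene pair: `cpg`, `gene`, `class`,
#' `t`, `t_corrected`, `p`, `p_corrected`.
#'
#' @param results an `assoc_results`.
#' @param path output TSV.
#' @export
write_association_tsv <- function(results, path) {
  keep <- results$mask != "excluded"
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(cpg = rownames(results$t)[idx[, 1]],
                   gene = colnames(results$t)[idx[, 2]],
                   class = results$mask[keep],
                   t = .fmt_num(results$t[keep]),
                   t_corrected = .fmt_num(results$t_corrected[keep]),
                   p = .fmt_num(results$p[keep]),
                   p_corrected = .fmt_num(results$p_corrected[keep]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
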