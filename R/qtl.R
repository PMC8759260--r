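#' Load a QTL catalog table
#'
#' Reads a TSV with header columns `snp` and `target` and tags every record
#' with the supplied measurement kind and cis/trans relation. Duplicate
#' (snp, target) rows are collapsed. The tables are taken as
#' already-thresholded catalogs; no significance filtering is applied here.
#'
#' @param path TSV file with columns `snp`, `target`.
#' @param kind `"methylation"` (meQTL) or `"expression"` (eQTL).
#' @param relation `"cis"` or `"trans"`.
#' @return data.frame with columns `snp`, `target`, `kind`, `relation`.
#' @export
load_qtl_table <- function(path, kind = c("methylation", "expression"),
                           relation = c("cis", "trans")) {
  kind <- match.arg(kind)
  relation <- match.arg(relation)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  .stop_if(!all(c("snp", "target") %in% names(df)),
           "QTL table must have columns 'snp' and 'target'")
  df <- unique(df[, c("snp", "target")])
  if (nrow(df) > 0) {
    .stop_if(any(df$snp == "" | df$target == ""), "empty SNP or target ID")
  }
  df$kind <- rep(kind, nrow(df))
  df$relation <- rep(relation, nrow(df))
  rownames(df) <- NULL
  df
}

#' Write a QTL truth/catalog table
#' @param records data.frame with columns `snp`, `target`.
#' @param path output TSV.
#' @export
write_qtl_table <- function(records, path) {
  utils::write.table(records[, c("snp", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-check trans associations against QTL catalogs
#'
#' A trans CpG-gene association could be genetically driven only if some
#' SNP is simultaneously a cis-QTL for one member of the pair and a
#' trans-QTL for the other. In `"cpg_first"` direction each CpG's
#' cis-meQTL SNPs are intersected with the trans-eQTL SNPs of its
#' associated genes; `"gene_first"` is the mirror (cis-eQTLs of the gene
#' against trans-meQTLs of the CpG). Matching is by SNP ID string.
#'
#' @param assoc_pairs data.frame with columns `cpg`, `gene` (e.g. the
#'   significant trans pairs of an `assoc_results`).
#' @param cis_qtls QTL records (see [load_qtl_table()]) with relation
#'   `"cis"`: meQTLs for `"cpg_first"`, eQTLs for `"gene_first"`.
#' @param trans_qtls QTL records with relation `"trans"`: eQTLs for
#'   `"cpg_first"`, meQTLs for `"gene_first"`.
#' @param direction `"cpg_first"` or `"gene_first"`.
#' @return a `crosscheck_result`: data.frame `flagged` (`cpg`, `gene`,
#'   `snps` comma-joined), plus counts of flagged CpGs/genes out of those
#'   appearing in `assoc_pairs`.
#' @export
qtl_crosscheck <- function(assoc_pairs, cis_qtls, trans_qtls,
                           direction = c("cpg_first", "gene_first")) {
  direction <- match.arg(direction)
  stopifnot(all(c("cpg", "gene") %in% names(assoc_pairs)))
  cis_by <- split(cis_qtls$snp, cis_qtls$target)
  trans_by <- split(trans_qtls$snp, trans_qtls$target)
  first <- if (direction == "cpg_first") assoc_pairs$cpg else assoc_pairs$gene
  second <- if (direction == "cpg_first") assoc_pairs$gene else assoc_pairs$cpg
  shared <- vapply(seq_len(nrow(assoc_pairs)), function(i) {
    s <- intersect(cis_by[[first[i]]], trans_by[[second[i]]])
    if (length(s) == 0) NA_character_ else paste(sort(s), collapse = ",")
  }, character(1))
  flagged <- data.frame(cpg = assoc_pairs$cpg, gene = assoc_pairs$gene,
                        snps = shared, stringsAsFactors = FALSE)
  flagged <- flagged[!is.na(flagged$snps), , drop = FALSE]
  rownames(flagged) <- NULL
  structure(list(flagged = flagged,
                 direction = direction,
                 n_cpgs_flagged = length(unique(flagged$cpg)),
                 n_cpgs_total = length(unique(assoc_pairs$cpg)),
                 n_genes_flagged = length(unique(flagged$gene)),
                 n_genes_total = length(unique(assoc_pairs$gene))),
            class = "crosscheck_result")
}

#' @export
print.crosscheck_result <- function(x, ...) {
  cat(sprintf("<crosscheck_result> (%s) %d flagged pairs; %d/%d CpGs and %d/%d genes share >= 1 SNP\n",
              x$direction, nrow(x$flagged),
              x$n_cpgs_flagged, x$n_cpgs_total,
              x$n_genes_flagged, x$n_genes_total))
  invisible(x)
}
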