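#' Default pipeline configuration
#'
#' Collects every stage's tunables in one list. All defaults equal the
#' analysis constants used throughout the package: cis window 100 kb,
#' trans window 5 Mb, core-set fraction 0.05, minimum 10 trans-genes per
#' core CpG, extreme-deviation threshold 10 years, proxy thresholds
#' 0.5/0.7/0.9, 5 latent factors, Bonferroni family of 9 for
#' genomic-feature enrichment. A single global seed feeds per-stage
#' derived seeds (see [derive_seed()]) so stages can be rerun
#' independently yet reproducibly.
#'
#' @param seed global seed.
#' @param simulation a [simulation_config()] (its own seed is overridden
#'   by the derived stage seed).
#' @param n_perm permutations for the trans null (default 100, a scaled
#'   version of the full 1000-permutation test).
#' @param cis_bp,trans_bp,core_fraction,min_trans_genes,extreme_threshold,
#'   proxy_thresholds,k_latent,enrichment_m,alpha analysis constants.
#' @param n_donors donors in the sorted-cell panel.
#' @param activated_offset_years injected clock-age offset for the panel
#'   (NULL = use the actual compartment profiles).
#' @export
pipeline_config <- function(seed = 1,
                            simulation = simulation_config(),
                            n_perm = 100,
                            cis_bp = 1e5, trans_bp = 5e6,
                            core_fraction = 0.05, min_trans_genes = 10,
                            extreme_threshold = 10,
                            proxy_thresholds = c(0.5, 0.7, 0.9),
                            k_latent = 5, enrichment_m = 9, alpha = 0.05,
                            n_donors = 6, activated_offset_years = NULL) {
  cfg <- as.list(environment())
  cfg$simulation$seed <- derive_seed(seed, "simulate")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages, in dependency order: simulate the cohort; fit synthetic clocks
#' and predict age; clock similarity (overlap + proxies); preprocess
#' expression and run the cis/trans association analysis with latent
#' factors and per-CpG empirical-null correction; select and cluster the
#' core trans set; sorted-cell paired delta-age; permutation null
#' (optional); QTL crosscheck (when QTL effects were injected). Reruns
#' with an identical configuration reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, artifacts and a
#'   machine-readable `summary.json` are written there.
#' @param run_permutation run the permutation stage (slowest part).
#' @return a `pipeline_run` list with every stage's objects plus a
#'   `summary` list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         run_permutation = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))

  # -- simulate ---------------------------------------------------------
  sim <- simulate_cohort(config$simulation)
  cohort <- sim$cohort
  truth <- sim$truth
  base_ids <- rownames(truth$cell_fractions)
  beta <- cohort$beta[base_ids, , drop = FALSE]
  counts <- cohort$counts[base_ids, , drop = FALSE]
  covariates <- cohort$covariates[base_ids, , drop = FALSE]

  # -- clocks -----------------------------------------------------------
  set.seed(derive_seed(config$seed, "clocks"))
  half <- sample(colnames(beta)[truth$cpg_cluster_labels != "neutral"])
  clocks <- list(
    true = truth$true_clock,
    refit = make_synthetic_clock(truth, cohort, "identity"),
    horvath_like = make_synthetic_clock(truth, cohort, "horvath"),
    subset_a = make_synthetic_clock(truth, cohort, "identity",
                                    cpgs = half[seq_len(floor(length(half) / 2))]),
    subset_b = make_synthetic_clock(truth, cohort, "identity",
                                    cpgs = half[seq(floor(length(half) / 4) + 1,
                                                    length(half))]))
  age <- covariates$age
  summaries <- lapply(clocks, function(cl) {
    prediction_error_summary(predict_age(cl, beta), age)
  })
  concordance <- clock_concordance(summaries)
  extremes <- extreme_deviation_overlap(lapply(summaries, `[[`, "error"),
                                        threshold = config$extreme_threshold)

  # -- similarity -------------------------------------------------------
  overlap <- cpg_overlap_matrix(clocks)
  proxies <- proxy_fraction(clocks$subset_a,
                            list(subset_b = names(clocks$subset_b$coefficients),
                                 within = names(clocks$subset_a$coefficients)),
                            beta, thresholds = config$proxy_thresholds)

  # -- associations -----------------------------------------------------
  expression <- preprocess_expression(counts, cohort$gene_coords)
  design <- association_design(covariates)
  assoc <- run_association(beta, expression, design, cohort$cpg_coords,
                           k_latent = config$k_latent,
                           cis_bp = config$cis_bp, trans_bp = config$trans_bp)
  membership <- list(
    refit = names(clocks$refit$coefficients),
    subset_a = names(clocks$subset_a$coefficients),
    subset_b = names(clocks$subset_b$coefficients))
  core <- select_core_set(assoc, membership,
                          fraction = config$core_fraction,
                          min_trans_genes = config$min_trans_genes,
                          alpha = config$alpha)

  # -- clustering + sorted cells ---------------------------------------
  tmat <- assoc$t_corrected[core$cpgs, core$genes, drop = FALSE]
  sig <- matrix(FALSE, nrow(tmat), ncol(tmat), dimnames = dimnames(tmat))
  st <- core$significant_trans
  st <- st[st$cpg %in% core$cpgs & st$gene %in% core$genes, ]
  sig[cbind(match(st$cpg, rownames(tmat)), match(st$gene, colnames(tmat)))] <- TRUE
  tmat[!sig] <- 0  # non-significant pairs rendered as absent
  heatmap <- cluster_core_set(tmat)

  set.seed(derive_seed(config$seed, "sorted"))
  sorted_ref <- emit_sorted_cell_reference(
    truth, n_donors = config$n_donors,
    activated_offset_years = config$activated_offset_years)
  delta <- paired_delta_age(
    predict_sorted_cell_ages(clocks[c("true", "refit")], sorted_ref))

  # -- permutation (optional, slow) ------------------------------------
  perm <- NULL
  if (run_permutation) {
    perm <- permutation_test(beta, expression, design, cohort$cpg_coords,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "permutation"),
                             alpha = config$alpha,
                             k_latent = config$k_latent,
                             cis_bp = config$cis_bp,
                             trans_bp = config$trans_bp)
  }

  # -- QTL crosscheck ---------------------------------------------------
  crosscheck <- NULL
  if (!is.null(truth$qtl_truth)) {
    crosscheck <- qtl_crosscheck(core$significant_trans,
                                 truth$qtl_truth$cis_meqtl,
                                 truth$qtl_truth$trans_eqtl, "cpg_first")
  }

  cpg_ari <- adjusted_rand_index(
    heatmap$row_clusters,
    truth$cpg_cluster_labels[rownames(tmat)])
  summary <- list(
    seed = config$seed,
    n_samples = length(base_ids),
    clock_mae = vapply(summaries, `[[`, numeric(1), "mae"),
    clock_r = vapply(summaries, `[[`, numeric(1), "pearson_r"),
    n_cis_significant = nrow(select_significant(assoc, "cis",
                                                alpha = config$alpha)),
    n_trans_significant = nrow(core$significant_trans),
    core_genes = length(core$genes),
    core_cpgs = length(core$cpgs),
    cpg_cluster_ari = cpg_ari,
    median_inflation = stats::median(assoc$inflation),
    delta_age = stats::setNames(delta$median_delta,
                                paste(delta$clock, delta$lineage, sep = ":")),
    permutation_p = if (is.null(perm)) NA else perm$p_empirical)

  run <- structure(list(config = config, cohort = cohort, truth = truth,
                        clocks = clocks, error_summaries = summaries,
                        concordance = concordance, extremes = extremes,
                        overlap = overlap, proxies = proxies,
                        expression = expression, assoc = assoc, core = core,
                        heatmap = heatmap, sorted_ref = sorted_ref,
                        delta_age = delta, permutation = perm,
                        crosscheck = crosscheck, summary = summary),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"), truth = truth)
    write_association_tsv(assoc, file.path(out_dir, "associations.tsv"))
    utils::write.table(
      data.frame(id = c(rownames(tmat), colnames(tmat)),
                 axis = c(rep("cpg", nrow(tmat)), rep("gene", ncol(tmat))),
                 cluster = c(heatmap$row_clusters, heatmap$col_clusters)),
      file.path(out_dir, "core_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(delta, file.path(out_dir, "delta_age.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_run> seed %d, n = %d\n", s$seed, s$n_samples))
  cat(sprintf("  clock MAE (y): %s\n",
              paste(sprintf("%s %.2f", names(s$clock_mae), s$clock_mae),
                    collapse = ", ")))
  cat(sprintf("  significant: %d cis, %d trans pairs; core set %d genes x %d CpGs (ARI vs truth %.2f)\n",
              s$n_cis_significant, s$n_trans_significant,
              s$core_genes, s$core_cpgs, s$cpg_cluster_ari))
  cat(sprintf("  median per-CpG inflation %.2f; permutation p %s\n",
              s$median_inflation,
              if (is.na(s$permutation_p)) "(not run)" else sprintf("%.4g", s$permutation_p)))
  invisible(x)
}
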