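#' Configuration for the synthetic whole-blood cohort generator
#'
#' The generator emulates a whole-blood methylome + transcriptome cohort in
#' which both clock-CpG methylation and marker-gene expression are driven
#' by latent naive/activated T- and NK-cell proportions that shift with
#' age, on top of broad cell-type composition, technical batches, a latent
#' confounder, and measurement noise. Defaults describe the stated
#' simulation world (see the methods vignette) and are not meant to be
#' tuned per analysis.
#'
#' @param n_samples cohort size.
#' @param age_range years, `c(low, high)`.
#' @param n_clock_cpgs total clock CpGs simulated.
#' @param cpg_split named counts for `cluster1` (naive-high methylation),
#'   `cluster2` (activated-high) and `neutral` CpGs; must sum to
#'   `n_clock_cpgs`.
#' @param n_genes total genes simulated.
#' @param gene_split named counts for `naive_marker`, `activated_marker`
#'   and `null` genes; must sum to `n_genes`.
#' @param n_noncoding number of `null` genes annotated as lincRNA (filtered
#'   out by [preprocess_expression()]).
#' @param beta_noise_sd measurement noise SD on beta values.
#' @param count_dispersion negative-binomial dispersion (0 = Poisson).
#' @param library_size `c(meanlog, sdlog)` of the log-normal per-sample
#'   library size.
#' @param batch_levels named level counts for the technical covariates.
#' @param n_cohorts number of biobank labels.
#' @param batch_sd_beta,batch_sd_expr SD of the additive per-level mean
#'   shifts on beta / log-expression.
#' @param activation_slope logit units per year: rate at which the
#'   activated share of T (and, at 0.8x, NK) cells rises with age.
#' @param activation_mid_age age (years) at which the activated share
#'   crosses 50%.
#' @param activation_logit_sd person-to-person SD of the activation logit
#'   (biological noise uncoupled from age).
#' @param age_deviation_sd SD (years) of the gap between chronological age
#'   and the methylome-encoded (true-clock) age. This is the generative
#'   counterpart of age-prediction deviations: a person's naive/activated
#'   balance can be atypical for their chronological age, so the clock
#'   score and chronological age disagree. With it at 0 (and all other
#'   noise off) the true clock reproduces chronological age exactly.
#' @param marker_effect log-expression units per unit compartment fraction
#'   for marker genes.
#' @param n_confounders number of latent expression-only confounders
#'   (unmodelled structured variation: cryptic batch, cell stress,
#'   RNA-quality axes). Together with the compositional axis that CPM
#'   normalization induces (the log library-composition denominator is a
#'   rank-1 equal-loading axis), they are what the regression's latent
#'   factors absorb; the default 4 + 1 compositional axis matches the 5
#'   factors, so the adjustment is essentially exact.
#' @param confounder_sd per-confounder loading SD (log-expression units;
#'   every gene loads on every confounder).
#' @param sex_effect_sd loading SD of the sex effect (random 10% of genes).
#' @param cellcount_noise_sd measurement SD (percentage points) of the
#'   recorded differential cell counts.
#' @param n_replicate_pairs technical replicate samples to append.
#' @param qtl_spec optional list of QTL effects, each a list with elements
#'   `snp`, `cpg`, `gene`, `af`, `beta_effect`, `expr_effect` (see
#'   [inject_qtl_effects()]).
#' @param seed integer RNG seed.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 500,
                              age_range = c(18, 87),
                              n_clock_cpgs = 200,
                              cpg_split = c(cluster1 = 60, cluster2 = 60,
                                            neutral = 80),
                              n_genes = 300,
                              gene_split = c(naive_marker = 50,
                                             activated_marker = 50,
                                             null = 200),
                              n_noncoding = 0,
                              beta_noise_sd = 0.01,
                              count_dispersion = 0.08,
                              library_size = c(meanlog = log(5e5), sdlog = 0.3),
                              batch_levels = c(bisulphite_plate = 4,
                                               sentrix_position = 6,
                                               flowcell = 3),
                              n_cohorts = 3,
                              batch_sd_beta = 0.01,
                              batch_sd_expr = 0.1,
                              activation_slope = 0.045,
                              activation_mid_age = 50,
                              activation_logit_sd = 0.5,
                              age_deviation_sd = 4,
                              marker_effect = 12,
                              n_confounders = 4,
                              confounder_sd = 0.45,
                              sex_effect_sd = 0.1,
                              cellcount_noise_sd = 0.5,
                              n_replicate_pairs = 0,
                              qtl_spec = NULL,
                              seed = 1) {
  cfg <- as.list(environment())
  .stop_if(n_samples < 2, "n_samples must be >= 2")
  .stop_if(age_range[1] >= age_range[2], "age_range low must be < high")
  .stop_if(any(c(n_clock_cpgs, n_genes, cpg_split, gene_split) <= 0),
           "all counts must be > 0")
  .stop_if(!setequal(names(cpg_split), c("cluster1", "cluster2", "neutral")),
           "cpg_split must name cluster1, cluster2, neutral")
  .stop_if(sum(cpg_split) != n_clock_cpgs,
           "cluster CpG counts must sum to n_clock_cpgs")
  .stop_if(!setequal(names(gene_split),
                     c("naive_marker", "activated_marker", "null")),
           "gene_split must name naive_marker, activated_marker, null")
  .stop_if(sum(gene_split) != n_genes, "gene counts must sum to n_genes")
  .stop_if(n_noncoding > gene_split[["null"]],
           "n_noncoding cannot exceed the null gene count")
  .stop_if(beta_noise_sd < 0 || count_dispersion < 0 ||
             batch_sd_beta < 0 || batch_sd_expr < 0 ||
             activation_logit_sd < 0 || cellcount_noise_sd < 0 ||
             age_deviation_sd < 0,
           "noise SDs and dispersion must be non-negative")
  .stop_if(!is.finite(activation_slope), "activation_slope must be finite")
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> n=%d, ages %g-%g, %d clock CpGs (%s), %d genes (%s), seed %d\n",
              x$n_samples, x$age_range[1], x$age_range[2], x$n_clock_cpgs,
              paste(sprintf("%s=%d", names(x$cpg_split), x$cpg_split), collapse = "/"),
              x$n_genes,
              paste(sprintf("%s=%d", names(x$gene_split), x$gene_split), collapse = "/"),
              x$seed))
  invisible(x)
}

.cell_types <- c("naive_T", "activated_T", "nk_canonical", "nk_adaptive",
                 "b_cell", "monocyte", "neutrophil", "eosinophil", "basophil")
.naive_side <- c("naive_T", "nk_canonical", "b_cell")
.activated_side <- c("activated_T", "nk_adaptive")

# Minimum-norm least squares via SVD pseudoinverse. The mixture betas are
# rank-deficient (rank <= number of cell types), and the min-norm solution
# spreads the clock weights over all cluster CpGs instead of piling them on
# a few pivot columns, which keeps noise amplification realistic.
.lstsq_minnorm <- function(x, y, tol = 1e-10) {
  sv <- svd(x)
  keep <- sv$d > tol * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              ncol = length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Draw per-sample blood cell-type fractions
#'
#' Nine compartments on the simplex. The expected activated share of T
#' cells is logistic in age with slope `activation_slope` (NK cells follow
#' at 0.8x the slope), emulating immuno-senescence; neutrophil and total
#' lymphocyte fractions are strongly anticorrelated because both are
#' carved from the same granulocyte/lymphoid balance. Uses the current RNG
#' stream (seed before calling for reproducibility).
#'
#' @param ages numeric vector of ages (years).
#' @param config a [simulation_config()].
#' @return samples x 9 matrix, rows on the simplex (sum 1 within 1e-12).
#' @export
simulate_cell_fractions <- function(ages, config) {
  n <- length(ages)
  .stop_if(n == 0, "empty age vector")
  mono <- stats::rbeta(n, 60, 690)    # ~8%
  eos <- stats::rbeta(n, 20, 780)     # ~2.5%
  baso <- stats::rbeta(n, 8, 992)     # ~0.8%
  rem <- 1 - (mono + eos + baso)
  q <- stats::rbeta(n, 12 * 0.40, 12 * 0.60)  # lymphoid share of the rest
  lymph <- rem * q
  neut <- rem * (1 - q)
  sp <- .rdirichlet(n, c(70, 15, 15) * 1.2)   # T / NK / B within lymphoid
  tfrac <- lymph * sp[, 1]
  nk <- lymph * sp[, 2]
  b <- lymph * sp[, 3]
  lt <- config$activation_slope * (ages - config$activation_mid_age)
  s_t <- stats::plogis(lt + stats::rnorm(n, 0, config$activation_logit_sd))
  s_nk <- stats::plogis(0.8 * lt + stats::rnorm(n, 0, config$activation_logit_sd))
  m <- cbind(naive_T = tfrac * (1 - s_t),
             activated_T = tfrac * s_t,
             nk_canonical = nk * (1 - s_nk),
             nk_adaptive = nk * s_nk,
             b_cell = b, monocyte = mono, neutrophil = neut,
             eosinophil = eos, basophil = baso)
  m / rowSums(m)
}

#' Build cell-type reference methylation and expression profiles
#'
#' Cluster-1 CpGs are highly methylated in naive compartments (naive T,
#' canonical NK, B) and lowly methylated in activated ones (activated T,
#' adaptive NK), with a mean gap of 0.6 (never below 0.4 after per-CpG
#' jitter); cluster-2 CpGs are reversed; neutral CpGs have identical means
#' in every compartment (they carry no composition signal). Naive-marker
#' genes are high in naive compartments, activated markers in activated
#' ones, null genes flat. Uses the current RNG stream.
#'
#' @param config a [simulation_config()].
#' @return list with `reference_beta` (cell type x CpG, in [0, 1]),
#'   `reference_expr` (cell type x gene, natural-log relative expression),
#'   `cpg_cluster_labels`, `gene_cluster_labels`.
#' @export
build_reference_profiles <- function(config) {
  sp <- config$cpg_split
  cpg_labels <- rep(c("cluster1", "cluster2", "neutral"),
                    times = sp[c("cluster1", "cluster2", "neutral")])
  cpgs <- sprintf("cg%05d", seq_len(config$n_clock_cpgs))
  names(cpg_labels) <- cpgs
  nt <- length(.cell_types)
  other <- setdiff(.cell_types, c(.naive_side, .activated_side))
  ref_beta <- matrix(0, nt, config$n_clock_cpgs,
                     dimnames = list(.cell_types, cpgs))
  for (j in seq_len(config$n_clock_cpgs)) {
    lab <- cpg_labels[j]
    if (lab == "neutral") {
      ref_beta[, j] <- stats::runif(1, 0.15, 0.85)
    } else {
      hi_side <- if (lab == "cluster1") .naive_side else .activated_side
      lo_side <- if (lab == "cluster1") .activated_side else .naive_side
      v <- stats::setNames(rep(0.55, nt), .cell_types)
      v[hi_side] <- 0.85
      v[lo_side] <- 0.25
      ref_beta[, j] <- pmin(0.98, pmax(0.02, v + stats::runif(nt, -0.06, 0.06)))
    }
  }
  gs <- config$gene_split
  gene_labels <- rep(c("naive_marker", "activated_marker", "null"),
                     times = gs[c("naive_marker", "activated_marker", "null")])
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  names(gene_labels) <- genes
  base <- stats::rnorm(config$n_genes, log(100), 0.8)
  # marker genes are subset-restricted transcripts: less abundant than the
  # bulk (which also keeps them a small share of the library, so CPM
  # normalization does not couple the whole transcriptome to their swings)
  # and with a tighter abundance spread, as for a curated marker panel
  base[gene_labels != "null"] <- stats::rnorm(sum(gene_labels != "null"),
                                              log(100) - 2.5, 0.4)
  ref_expr <- matrix(rep(base, each = nt), nt, config$n_genes,
                     dimnames = list(.cell_types, genes))
  shift <- 1.5
  naive_g <- gene_labels == "naive_marker"
  act_g <- gene_labels == "activated_marker"
  ref_expr[.naive_side, naive_g] <- ref_expr[.naive_side, naive_g] + shift
  ref_expr[.activated_side, naive_g] <- ref_expr[.activated_side, naive_g] - shift
  ref_expr[.activated_side, act_g] <- ref_expr[.activated_side, act_g] + shift
  ref_expr[.naive_side, act_g] <- ref_expr[.naive_side, act_g] - shift
  list(reference_beta = ref_beta, reference_expr = ref_expr,
       cpg_cluster_labels = cpg_labels, gene_cluster_labels = gene_labels)
}

# hg19-like autosome lengths (Mb-rounded) for coordinate placement
.chrom_lengths <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
                    134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51) * 1e6
names(.chrom_lengths) <- paste0("chr", 1:22)

#' Simulate a whole-blood cohort with known ground truth
#'
#' Generates methylation betas as a noisy mixture of cell-type reference
#' profiles weighted by age-dependent cell fractions, expression counts as
#' negative-binomial draws whose marker-gene log-means are affine in the
#' matching compartment fraction, plus batch shifts on both modalities.
#'
#' Chronological age is emitted by the cohort's *true clock*: a latent
#' target age drives the logistic activation trend, the true clock is the
#' naive-to-activated methylation contrast calibrated against that target,
#' and the recorded age is the clock's noise-free prediction plus an
#' `age_deviation_sd` gap (composition atypical for one's calendar age).
#' With every noise SD at 0 the recorded age is exactly linear in the
#' noise-free betas, so the true clock reproduces it to machine precision;
#' at the defaults the clock predicts age with a realistic few-year error
#' while the deviation keeps a naive/activated signal in the methylome
#' that chronological age does not explain.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (a `synthetic_cohort`: `beta`, `counts`,
#'   `covariates`, `cpg_coords`, `gene_coords`, `replicate_pairs`,
#'   `genotypes`) and `truth` (a `ground_truth`: `cell_fractions`,
#'   `cpg_cluster_labels`, `gene_cluster_labels`, `reference_beta`,
#'   `reference_expr`, `true_clock`, `target_age`, `latent_confounder`,
#'   `qtl_truth`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  refs <- build_reference_profiles(config)
  target_age <- stats::runif(n, config$age_range[1], config$age_range[2])
  frac <- simulate_cell_fractions(target_age, config)
  rownames(frac) <- ids
  beta0 <- frac %*% refs$reference_beta

  # True clock: the naive->activated methylation contrast direction over the
  # cluster CpGs, linearly calibrated to the target age. The 1-D calibration
  # avoids overfitting incidental composition directions, so the clock's
  # weights stay at a realistic scale; age is exactly linear in the
  # noise-free betas by construction.
  cl_cpgs <- names(refs$cpg_cluster_labels)[refs$cpg_cluster_labels != "neutral"]
  contrast <- colMeans(refs$reference_beta[.activated_side, cl_cpgs, drop = FALSE]) -
    colMeans(refs$reference_beta[.naive_side, cl_cpgs, drop = FALSE])
  score <- drop(beta0[, cl_cpgs, drop = FALSE] %*% contrast)
  slope <- stats::cov(target_age, score) / stats::var(score)
  icept <- mean(target_age) - slope * mean(score)
  w <- slope * contrast
  # chronological age = methylome-encoded age + deviation: the composition
  # a person carries can be atypical for their calendar age. Clamped to a
  # plausible human range - noise tails must not produce impossible ages
  # (the log-linear clock transform is undefined below -1 year); the bounds
  # are generous enough that the zero-noise case never touches them.
  age <- icept + drop(beta0[, cl_cpgs, drop = FALSE] %*% w) +
    stats::rnorm(n, 0, config$age_deviation_sd)
  age <- pmin(pmax(age, 1), 110)
  true_clock <- clock_model("true_clock", intercept = icept,
                            coefficients = stats::setNames(w, cl_cpgs),
                            transform = "identity",
                            training_means = colMeans(beta0[, cl_cpgs, drop = FALSE]))

  # technical batches and biobank labels; additive per-level mean shifts
  lv <- config$batch_levels
  plate <- sample(paste0("P", seq_len(lv[["bisulphite_plate"]])), n, TRUE)
  sentrix <- sample(paste0("R", seq_len(lv[["sentrix_position"]])), n, TRUE)
  flowcell <- sample(paste0("FC", seq_len(lv[["flowcell"]])), n, TRUE)
  cohort_lab <- sample(paste0("C", seq_len(config$n_cohorts)), n, TRUE)
  shift <- function(levels, p, sd) {
    m <- matrix(stats::rnorm(length(levels) * p, 0, sd), length(levels), p,
                dimnames = list(levels, NULL))
    if (sd == 0) m[] <- 0
    m
  }
  sh_plate <- shift(unique(plate), config$n_clock_cpgs, config$batch_sd_beta)
  sh_sentrix <- shift(unique(sentrix), config$n_clock_cpgs, config$batch_sd_beta)
  sh_cob <- shift(unique(cohort_lab), config$n_clock_cpgs, config$batch_sd_beta)
  sh_flow <- shift(unique(flowcell), config$n_genes, config$batch_sd_expr)
  sh_coe <- shift(unique(cohort_lab), config$n_genes, config$batch_sd_expr)

  beta <- beta0 + sh_plate[plate, ] + sh_sentrix[sentrix, ] +
    sh_cob[cohort_lab, ] +
    matrix(stats::rnorm(n * config$n_clock_cpgs, 0, config$beta_noise_sd),
           n, config$n_clock_cpgs)
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- dimnames(beta0)

  # expression: marker log-means affine in the matching compartment fraction
  naive_frac <- frac[, "naive_T"] + frac[, "nk_canonical"]
  act_frac <- frac[, "activated_T"] + frac[, "nk_adaptive"]
  glab <- refs$gene_cluster_labels
  # monocytes carry no marker shift, so their row is each gene's baseline
  base <- refs$reference_expr["monocyte", ]
  logrel <- matrix(rep(base, each = n), n, config$n_genes,
                   dimnames = list(ids, names(glab)))
  # affine in the matching compartment fraction; centred so the marker
  # baseline abundance stays at its reference level
  logrel[, glab == "naive_marker"] <- logrel[, glab == "naive_marker"] +
    config$marker_effect * (naive_frac - mean(naive_frac))
  logrel[, glab == "activated_marker"] <- logrel[, glab == "activated_marker"] +
    config$marker_effect * (act_frac - mean(act_frac))
  confounder <- matrix(stats::rnorm(n * config$n_confounders), n,
                       config$n_confounders)
  conf_load <- matrix(stats::rnorm(config$n_confounders * config$n_genes,
                                   0, config$confounder_sd),
                      config$n_confounders, config$n_genes)
  sex <- sample(c("F", "M"), n, TRUE)
  sex_load <- numeric(config$n_genes)
  sex_genes <- sample.int(config$n_genes, max(1, floor(config$n_genes / 10)))
  sex_load[sex_genes] <- stats::rnorm(length(sex_genes), 0, config$sex_effect_sd)
  logrel <- logrel + confounder %*% conf_load +
    outer(as.numeric(sex == "M"), sex_load) +
    sh_flow[flowcell, ] + sh_coe[cohort_lab, ]

  lib <- stats::rlnorm(n, config$library_size[["meanlog"]],
                       config$library_size[["sdlog"]])
  pg <- exp(logrel)
  pg <- pg / rowSums(pg)
  mu <- pg * lib
  counts <- .draw_counts(mu, config$count_dispersion)
  dimnames(counts) <- dimnames(logrel)

  # measured differential (percentages, with measurement noise)
  meas <- function(x) pmax(0, 100 * x + stats::rnorm(n, 0, config$cellcount_noise_sd))
  covariates <- data.frame(
    sample = ids, age = age, sex = sex, cohort = cohort_lab,
    bisulphite_plate = plate, sentrix_position = sentrix, flowcell = flowcell,
    lymphocyte_pct = meas(frac[, "naive_T"] + frac[, "activated_T"] +
                            frac[, "nk_canonical"] + frac[, "nk_adaptive"] +
                            frac[, "b_cell"]),
    monocyte_pct = meas(frac[, "monocyte"]),
    neutrophil_pct = meas(frac[, "neutrophil"]),
    eosinophil_pct = meas(frac[, "eosinophil"]),
    basophil_pct = meas(frac[, "basophil"]),
    stringsAsFactors = FALSE)
  rownames(covariates) <- ids

  # coordinates; the first 5 neutral CpGs get a planted cis gene partner
  cpg_coords <- data.frame(
    cpg = colnames(beta),
    chrom = sample(names(.chrom_lengths), config$n_clock_cpgs, TRUE),
    pos = NA_real_, stringsAsFactors = FALSE)
  cpg_coords$pos <- floor(stats::runif(config$n_clock_cpgs, 1e6,
                                       .chrom_lengths[cpg_coords$chrom]))
  biotype <- rep("protein_coding", config$n_genes)
  if (config$n_noncoding > 0) {
    null_idx <- which(glab == "null")
    biotype[utils::tail(null_idx, config$n_noncoding)] <- "lincRNA"
  }
  gene_coords <- data.frame(
    gene = colnames(counts),
    chrom = sample(names(.chrom_lengths), config$n_genes, TRUE),
    start = NA_real_, end = NA_real_,
    strand = sample(c("+", "-"), config$n_genes, TRUE),
    biotype = biotype, stringsAsFactors = FALSE)
  width <- 5000 + stats::rpois(config$n_genes, 20000)
  gene_coords$start <- floor(stats::runif(config$n_genes, 1e6,
                                          .chrom_lengths[gene_coords$chrom] - max(width) - 1e5))
  gene_coords$end <- gene_coords$start + width
  neutral_cpgs <- which(refs$cpg_cluster_labels == "neutral")[1:5]
  null_genes <- which(glab == "null")[1:5]
  for (k in 1:5) {
    gene_coords$chrom[null_genes[k]] <- cpg_coords$chrom[neutral_cpgs[k]]
    gene_coords$start[null_genes[k]] <- cpg_coords$pos[neutral_cpgs[k]] + 20000
    gene_coords$end[null_genes[k]] <- gene_coords$start[null_genes[k]] + width[null_genes[k]]
  }

  replicate_pairs <- NULL
  if (config$n_replicate_pairs > 0) {
    k <- min(config$n_replicate_pairs, n)
    rep_ids <- paste0(ids[1:k], "_rep")
    rep_beta <- beta0[1:k, , drop = FALSE] + sh_plate[plate[1:k], ] +
      sh_sentrix[sentrix[1:k], ] + sh_cob[cohort_lab[1:k], ] +
      matrix(stats::rnorm(k * config$n_clock_cpgs, 0, config$beta_noise_sd),
             k, config$n_clock_cpgs)
    rep_beta <- pmin(pmax(rep_beta, 0), 1)
    rownames(rep_beta) <- rep_ids
    beta <- rbind(beta, rep_beta)
    rep_counts <- .draw_counts(mu[1:k, , drop = FALSE], config$count_dispersion)
    rownames(rep_counts) <- rep_ids
    counts <- rbind(counts, rep_counts)
    rep_cov <- covariates[1:k, ]
    rep_cov$sample <- rep_ids
    rownames(rep_cov) <- rep_ids
    covariates <- rbind(covariates, rep_cov)
    replicate_pairs <- data.frame(sample = ids[1:k], replicate = rep_ids,
                                  stringsAsFactors = FALSE)
  }

  cohort <- structure(list(beta = beta, counts = counts,
                           covariates = covariates,
                           cpg_coords = cpg_coords, gene_coords = gene_coords,
                           replicate_pairs = replicate_pairs,
                           genotypes = NULL),
                      class = "synthetic_cohort")
  truth <- structure(list(cell_fractions = frac,
                          cpg_cluster_labels = refs$cpg_cluster_labels,
                          gene_cluster_labels = refs$gene_cluster_labels,
                          reference_beta = refs$reference_beta,
                          reference_expr = refs$reference_expr,
                          true_clock = true_clock,
                          target_age = target_age,
                          latent_confounder = confounder,
                          qtl_truth = NULL),
                     class = "ground_truth")
  out <- list(cohort = cohort, truth = truth)
  if (!is.null(config$qtl_spec)) {
    out <- inject_qtl_effects(out$cohort, out$truth, config$qtl_spec)
  }
  out
}

.draw_counts <- function(mu, dispersion) {
  n <- nrow(mu); g <- ncol(mu)
  if (dispersion == 0) {
    matrix(stats::rpois(n * g, as.vector(mu)), n, g)
  } else {
    matrix(stats::rnbinom(n * g, mu = as.vector(mu), size = 1 / dispersion),
           n, g)
  }
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples x %d CpGs, %d genes; covariates: %s\n",
              nrow(x$beta), ncol(x$beta), ncol(x$counts),
              paste(setdiff(names(x$covariates), "sample"), collapse = ", ")))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d samples, CpG clusters %s; gene clusters %s\n",
              nrow(x$cell_fractions),
              paste(sprintf("%s=%d", names(table(x$cpg_cluster_labels)),
                            table(x$cpg_cluster_labels)), collapse = "/"),
              paste(sprintf("%s=%d", names(table(x$gene_cluster_labels)),
                            table(x$gene_cluster_labels)), collapse = "/")))
  invisible(x)
}

#' Inject genetic (QTL) effects into a simulated cohort
#'
#' Draws Hardy-Weinberg biallelic genotypes (0/1/2 at the stated allele
#' frequency) and shifts the target CpG's beta additively per allele
#' (cis-meQTL) and the target gene's log-expression per allele
#' (trans-eQTL). Emits the corresponding truth tables in the QTL catalog
#' dialect. Uses the current RNG stream.
#'
#' @param cohort a `synthetic_cohort`.
#' @param truth the matching `ground_truth`.
#' @param qtl_spec list of effects: each a list with `snp`, `cpg`, `gene`,
#'   `af` (allele frequency), `beta_effect` (beta units per allele),
#'   `expr_effect` (natural-log expression units per allele).
#' @return list with the modified `cohort` (gains a `genotypes` matrix) and
#'   `truth` whose `qtl_truth` holds `cis_meqtl` and `trans_eqtl` tables.
#' @export
inject_qtl_effects <- function(cohort, truth, qtl_spec) {
  n <- nrow(cohort$beta)
  geno <- matrix(0L, n, length(qtl_spec),
                 dimnames = list(rownames(cohort$beta),
                                 vapply(qtl_spec, `[[`, "", "snp")))
  meqtl <- eqtl <- list()
  for (i in seq_along(qtl_spec)) {
    q <- qtl_spec[[i]]
    .stop_if(!q$cpg %in% colnames(cohort$beta),
             paste0("unknown CpG ID: ", q$cpg))
    .stop_if(!q$gene %in% colnames(cohort$counts),
             paste0("unknown gene ID: ", q$gene))
    g <- stats::rbinom(n, 2, q$af)
    geno[, i] <- g
    newbeta <- cohort$beta[, q$cpg] + g * q$beta_effect
    if (any(newbeta < 0 | newbeta > 1)) {
      warning(sprintf("beta shift for %s pushes values outside [0, 1]; truncated",
                      q$cpg))
      newbeta <- pmin(pmax(newbeta, 0), 1)
    }
    cohort$beta[, q$cpg] <- newbeta
    cohort$counts[, q$gene] <- round(cohort$counts[, q$gene] * exp(g * q$expr_effect))
    meqtl[[i]] <- data.frame(snp = q$snp, target = q$cpg,
                             stringsAsFactors = FALSE)
    eqtl[[i]] <- data.frame(snp = q$snp, target = q$gene,
                            stringsAsFactors = FALSE)
  }
  cohort$genotypes <- geno
  truth$qtl_truth <- list(cis_meqtl = unique(do.call(rbind, meqtl)),
                          trans_eqtl = unique(do.call(rbind, eqtl)))
  list(cohort = cohort, truth = truth)
}

#' Fit a synthetic clock on a simulated cohort
#'
#' Least-squares fit of the (transformed) recorded age on the observed
#' beta values of a CpG subset (default: all cluster CpGs), emitted as a
#' [clock_model()] in the clock coefficient dialect with training means
#' for imputation. On a zero-noise cohort with the identity transform the
#' fit is exact because age is exactly linear in the noise-free betas.
#'
#' @param truth a `ground_truth`.
#' @param cohort the matching `synthetic_cohort`.
#' @param transform one of `"identity"`, `"horvath"`, `"zhang"`.
#' @param cpgs CpG subset (default: cluster1 + cluster2 CpGs).
#' @param adult_age horvath maturity constant.
#' @return a [clock_model()].
#' @export
make_synthetic_clock <- function(truth, cohort,
                                 transform = c("identity", "horvath", "zhang"),
                                 cpgs = NULL, adult_age = 20) {
  transform <- match.arg(transform)
  if (is.null(cpgs)) {
    cpgs <- names(truth$cpg_cluster_labels)[truth$cpg_cluster_labels != "neutral"]
  }
  samples <- rownames(truth$cell_fractions)
  beta <- cohort$beta[samples, , drop = FALSE]
  age <- cohort$covariates[samples, "age"]
  .stop_if(nrow(beta) < length(cpgs) + 1, "fewer samples than selected CpGs")
  x <- if (transform == "zhang") zhang_standardize(beta) else beta
  x <- x[, cpgs, drop = FALSE]
  y <- if (transform == "horvath") horvath_transform(age, adult_age) else age
  cf <- .lstsq_minnorm(cbind(1, x), y)
  clock_model(name = paste0("synthetic_", transform), intercept = cf[1],
              coefficients = stats::setNames(cf[-1], cpgs),
              transform = transform, adult_age = adult_age,
              training_means = colMeans(x))
}

#' Emit a paired sorted-cell reference panel
#'
#' For each donor and lineage (naive vs memory CD4 T, naive vs effector
#' CD8 T, canonical vs adaptive NK) draws one naive and one activated
#' methylation profile around the corresponding cell-type reference, with
#' a donor random effect shared within the pair plus measurement noise.
#' Optionally the activated profile is instead the naive profile shifted
#' along the true clock's coefficient direction so that its clock-predicted
#' age is exactly `activated_offset_years` higher - a controlled positive
#' for the paired delta-age analysis.
#'
#' @param truth a `ground_truth`.
#' @param n_donors number of donors (>= 2).
#' @param donor_sd SD of the per-donor random effect (beta units).
#' @param noise_sd measurement noise SD (beta units).
#' @param activated_offset_years optional injected clock-age offset.
#' @return a `sorted_cell_reference`: `beta` (sample x CpG), `samples`
#'   (data.frame `sample`, `donor`, `lineage`, `phenotype`),
#'   `beta_medians` (CpG x cell type), `expr_medians` (gene x cell type,
#'   natural-log scale).
#' @export
emit_sorted_cell_reference <- function(truth, n_donors = 6, donor_sd = 0.02,
                                       noise_sd = 0.01,
                                       activated_offset_years = NULL) {
  .stop_if(n_donors < 2, "n_donors must be >= 2")
  lineages <- list(CD4 = c(naive = "naive_T", activated = "activated_T"),
                   CD8 = c(naive = "naive_T", activated = "activated_T"),
                   NK = c(naive = "nk_canonical", activated = "nk_adaptive"))
  cpgs <- colnames(truth$reference_beta)
  rows <- list(); info <- list(); r <- 0
  for (ln in names(lineages)) {
    naive_prof <- truth$reference_beta[lineages[[ln]][["naive"]], ]
    act_prof <- truth$reference_beta[lineages[[ln]][["activated"]], ]
    if (!is.null(activated_offset_years)) {
      w <- truth$true_clock$coefficients
      d <- stats::setNames(numeric(length(cpgs)), cpgs)
      d[names(w)] <- activated_offset_years * w / sum(w^2)
      act_prof <- naive_prof + d
      if (any(act_prof < 0 | act_prof > 1)) {
        warning("injected clock offset pushes betas outside [0, 1]; truncated")
        act_prof <- pmin(pmax(act_prof, 0), 1)
      }
    }
    for (dn in seq_len(n_donors)) {
      donor_eff <- stats::rnorm(length(cpgs), 0, donor_sd)
      for (ph in c("naive", "activated")) {
        prof <- if (ph == "naive") naive_prof else act_prof
        r <- r + 1
        rows[[r]] <- pmin(pmax(prof + donor_eff +
                                 stats::rnorm(length(cpgs), 0, noise_sd), 0), 1)
        info[[r]] <- data.frame(sample = sprintf("%s_D%02d_%s", ln, dn, ph),
                                donor = sprintf("D%02d", dn),
                                lineage = ln, phenotype = ph,
                                stringsAsFactors = FALSE)
      }
    }
  }
  beta <- do.call(rbind, rows)
  samples <- do.call(rbind, info)
  rownames(beta) <- samples$sample
  colnames(beta) <- cpgs
  structure(list(beta = beta, samples = samples,
                 beta_medians = t(truth$reference_beta),
                 expr_medians = t(truth$reference_expr)),
            class = "sorted_cell_reference")
}

#' @export
print.sorted_cell_reference <- function(x, ...) {
  cat(sprintf("<sorted_cell_reference> %d samples (%d donors x %d lineages x 2 phenotypes), %d CpGs\n",
              nrow(x$beta), length(unique(x$samples$donor)),
              length(unique(x$samples$lineage)), ncol(x$beta)))
  invisible(x)
}
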