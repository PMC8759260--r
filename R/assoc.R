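#' Rank-inverse-normal transform
#'
#' Maps a vector onto normal quantiles via `qnorm((rank - 0.5) / n)`, with
#' average ranks for ties. The result has sample mean ~0 and a symmetric
#' distribution regardless of the input's shape.
#'
#' @param x numeric vector.
#' @export
rank_inverse_normal <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Filter and transform an RNA-seq count matrix for association testing
#'
#' Keeps protein-coding genes whose median raw count is strictly greater
#' than `min_median_count`, converts to log2 counts per million with a
#' small-count offset, `log2((count + 0.5) / (lib + 1) * 1e6)`, and applies
#' a per-gene rank-inverse-normal transform so each gene is normally
#' distributed.
#'
#' @param counts sample x gene matrix of non-negative integer counts.
#' @param gene_annotation data.frame with columns `gene` and `biotype`
#'   (plus coordinates, carried through).
#' @param min_median_count strict lower bound on the per-gene median count.
#' @param biotype biotype(s) retained.
#' @return a `preprocessed_expression` list: `expr` (sample x gene RIN
#'   matrix), `logcpm`, and the retained `genes` annotation.
#' @export
preprocess_expression <- function(counts, gene_annotation,
                                  min_median_count = 1,
                                  biotype = "protein_coding") {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(c("gene", "biotype") %in% names(gene_annotation)))
  lib <- rowSums(counts)
  .stop_if(any(lib == 0), "sample(s) with zero library size")
  ann <- gene_annotation[match(colnames(counts), gene_annotation$gene), ]
  keep <- ann$biotype %in% biotype &
    apply(counts, 2, stats::median) > min_median_count
  .stop_if(!any(keep), "all genes removed by filtering")
  counts <- counts[, keep, drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  logcpm <- log2((counts + 0.5) / (lib + 1) * 1e6)
  expr <- apply(logcpm, 2, rank_inverse_normal)
  rownames(expr) <- rownames(counts)
  structure(list(expr = expr, logcpm = logcpm, genes = ann),
            class = "preprocessed_expression")
}

#' @export
print.preprocessed_expression <- function(x, ...) {
  cat(sprintf("<preprocessed_expression> %d samples x %d genes (RIN log2-CPM)\n",
              nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' Build the association design matrix from per-sample covariates
#'
#' Encodes the regression covariates: cohort, age, sex, basophil /
#' eosinophil / lymphocyte / monocyte percentages, and the technical
#' batches (bisulphite plate, array position, flowcell). Neutrophil
#' percentage is never included: it is almost perfectly anticorrelated
#' with lymphocyte percentage and would make the design collinear.
#' Categorical covariates are dummy-coded against a reference level, with
#' levels rarer than `pool_min` pooled.
#'
#' @param covariates data.frame with (a subset of) columns `cohort`, `age`,
#'   `sex`, `basophil_pct`, `eosinophil_pct`, `lymphocyte_pct`,
#'   `monocyte_pct`, `bisulphite_plate`, `sentrix_position`, `flowcell`.
#' @param use_cellcounts set `FALSE` to drop the four cell percentages
#'   (sensitivity analysis without cell-composition adjustment).
#' @param pool_min categorical levels with fewer samples are pooled.
#' @return numeric design matrix including an intercept column.
#' @export
association_design <- function(covariates, use_cellcounts = TRUE,
                               pool_min = 5) {
  cells <- c("basophil_pct", "eosinophil_pct", "lymphocyte_pct", "monocyte_pct")
  numeric_cols <- intersect(c("age", if (use_cellcounts) cells), names(covariates))
  factor_cols <- intersect(c("cohort", "sex", "bisulphite_plate",
                             "sentrix_position", "flowcell"),
                           names(covariates))
  .stop_if("neutrophil_pct" %in% numeric_cols, "neutrophil_pct must not enter the design")
  df <- covariates[, c(numeric_cols, factor_cols), drop = FALSE]
  .stop_if(anyNA(df), "missing values in model covariates")
  for (fc in factor_cols) {
    f <- as.character(df[[fc]])
    tab <- table(f)
    rare <- names(tab)[tab < pool_min]
    if (length(rare) > 0 && length(tab) > length(rare)) f[f %in% rare] <- ".pooled"
    df[[fc]] <- factor(f)
    if (nlevels(df[[fc]]) < 2) df[[fc]] <- NULL  # constant after pooling
  }
  x <- stats::model.matrix(~ ., data = df)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop(paste0("design matrix is rank deficient; collinear column(s): ",
                paste(bad, collapse = ", ")), call. = FALSE)
  }
  rownames(x) <- rownames(covariates)
  x
}

#' Estimate latent expression factors by residual SVD
#'
#' Residualizes the expression matrix on the known covariates and takes the
#' top-k left singular vectors of the residual as latent factors capturing
#' unmodelled structured variation. Factors are orthonormal; the sign of
#' each factor is fixed so that its largest-magnitude gene loading is
#' positive, making the decomposition deterministic.
#'
#' A naive residual SVD would absorb any expression axis - including the
#' one shared with the methylation data, i.e. the signal the association
#' analysis is after. Robust latent-factor methods avoid contaminating the
#' factors with the effect of interest; here that protection is achieved
#' by additionally residualizing on the `protect` directions (typically
#' the leading principal components of the covariate-adjusted methylation
#' matrix) before the SVD, so the factors capture expression-only
#' structure (technical batches, unmodelled confounders) and never the
#' methylation-shared axis.
#'
#' @param expr sample x gene matrix (typically RIN-transformed).
#' @param design design matrix of known covariates.
#' @param k number of factors (default 5).
#' @param protect optional sample x d matrix of directions the factors
#'   must not absorb.
#' @return sample x k matrix of factors, columns `LF1..LFk`.
#' @export
estimate_latent_factors <- function(expr, design, k = 5, protect = NULL) {
  .stop_if(k <= 0, "k must be positive")
  n <- nrow(expr)
  r <- qr(design)$rank
  .stop_if(k >= n - r, "k must be smaller than the residual degrees of freedom")
  q <- qr.Q(qr(design))
  resid <- expr - q %*% crossprod(q, expr)
  if (!is.null(protect)) {
    pr <- protect - q %*% crossprod(q, protect)
    qp <- qr(pr)
    qp <- qr.Q(qp)[, seq_len(qp$rank), drop = FALSE]
    resid <- resid - qp %*% crossprod(qp, resid)
  }
  sv <- svd(resid, nu = k, nv = k)
  u <- sv$u
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) u[, j] <- -u[, j]
  }
  colnames(u) <- paste0("LF", seq_len(k))
  rownames(u) <- rownames(expr)
  u
}

# Residualized fast path shared by all association entry points.
# Returns the t-statistic matrix (CpGs x genes) for the methylation
# coefficient in per-gene OLS with `design` as nuisance covariates.
.assoc_t_matrix <- function(beta, expr, design) {
  n <- nrow(beta)
  stopifnot(nrow(expr) == n, nrow(design) == n)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    stop(paste0("design matrix is rank deficient; collinear column(s): ",
                paste(bad, collapse = ", ")), call. = FALSE)
  }
  q <- qr.Q(qd)
  br <- beta - q %*% crossprod(q, beta)
  er <- expr - q %*% crossprod(q, expr)
  bn <- sqrt(colSums(br^2)); bn[bn == 0] <- NA  # constant-after-adjustment CpG
  en <- sqrt(colSums(er^2)); en[en == 0] <- NA
  r <- crossprod(sweep(br, 2, bn, "/"), sweep(er, 2, en, "/"))
  df <- n - ncol(design) - 1
  .stop_if(df < 1, "not enough samples for the design")
  r[r > 1] <- 1; r[r < -1] <- -1
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  list(t = t, df = df)
}

#' Per-gene association of expression with one CpG's methylation
#'
#' Ordinary least squares of each gene's (transformed) expression on the
#' CpG's beta value plus the full covariate design (known covariates and
#' latent factors). Implemented through a single QR factorization of the
#' design shared across all genes. Returns the t statistic and two-sided p
#' value for the methylation coefficient; a perfect fit (zero residual
#' variance) is flagged rather than reported as a finite statistic.
#'
#' @param beta_cpg numeric vector, one CpG's beta across samples.
#' @param expr sample x gene expression matrix.
#' @param design covariate design matrix (with intercept; append latent
#'   factors before calling).
#' @return data.frame with `gene`, `t`, `p`, `df`, `perfect_fit`.
#' @export
fit_cpg_gene_models <- function(beta_cpg, expr, design) {
  res <- .assoc_t_matrix(matrix(beta_cpg, ncol = 1), expr, design)
  t <- drop(res$t)
  perfect <- is.finite(t) & abs(t) > 1 / sqrt(.Machine$double.eps)
  p <- 2 * stats::pt(-abs(t), df = res$df)
  data.frame(gene = colnames(expr) %||% seq_along(t),
             t = t, p = p, df = res$df, perfect_fit = perfect,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical-null correction of a set of test statistics
#'
#' Estimates the location (bias) and scale (inflation) of the empirical
#' null from the central mass of the z-converted statistics using a
#' three-component Gaussian mixture fitted by EM: one dominant central
#' (null) component and two flanking components that shield genuine signal
#' from distorting the null estimate. Two light regularizations keep the
#' fit honest at both extremes: a Dirichlet pseudo-count on the null
#' weight (so the flanks do not nibble the tails of a pure null), and
#' flank components constrained to be at least as wide as, and at least
#' 2.5 null SDs away from, the null component (so the flanks model diffuse
#' signal, never the null's shoulders). Corrected statistics are
#' `z' = (z - bias) / inflation`, with p values from the standard normal.
#' Following the genomic-control convention, an estimated inflation below
#' 1 (underdispersion, common in small statistic sets with correlated
#' tests) is reported but not used to scale statistics up - deflation is
#' never converted into significance.
#' If the EM does not converge to a credible null (weight >= 0.5), the
#' median/MAD fallback is used and flagged.
#'
#' @param t numeric statistics (t or z scale).
#' @param df residual degrees of freedom; `Inf` (default) treats `t` as z
#'   scores already.
#' @param min_stats minimum number of statistics required.
#' @param maxit,tol EM controls.
#' @return list with `z`, `z_corrected`, `p_corrected`, `bias`,
#'   `inflation`, `method` (`"em"` or `"mad"`), `converged`.
#' @export
empirical_null_correct <- function(t, df = Inf, min_stats = 100,
                                   maxit = 500, tol = 1e-8) {
  .stop_if(length(t) < min_stats,
           sprintf("need >= %d statistics for empirical-null estimation", min_stats))
  z <- if (is.infinite(df)) as.numeric(t) else .t_to_z(t, df)
  fit <- .empirical_null_rows(matrix(z, nrow = 1), maxit = maxit, tol = tol)
  zc <- (z - fit$bias[1]) / max(fit$inflation[1], 1)
  list(z = z, z_corrected = zc,
       p_corrected = 2 * stats::pnorm(-abs(zc)),
       bias = fit$bias[1], inflation = fit$inflation[1],
       method = fit$method[1], converged = fit$converged[1])
}

# Vectorized 3-component EM across the rows of a z matrix: one empirical
# null per row (CpG), all rows iterated together so a whole association run
# needs one EM instead of one per CpG. Parameters converged per row keep
# iterating at their fixed point (cheap, and keeps the code branch-free).
.empirical_null_rows <- function(z, maxit = 500, tol = 1e-8) {
  r <- nrow(z); m <- ncol(z)
  bad <- !is.finite(z)
  if (any(bad)) z[bad] <- stats::median(z[is.finite(z)])  # neutralize stray values
  med <- apply(z, 1, stats::median)
  s0 <- apply(z, 1, stats::mad)
  s0_alt <- apply(z, 1, stats::sd)
  s0[s0 == 0] <- s0_alt[s0 == 0]
  s0[s0 == 0 | !is.finite(s0)] <- 1
  mu <- cbind(med, med - 3 * s0, med + 3 * s0)
  sg <- cbind(s0, s0, s0)
  pw <- matrix(rep(c(0.9, 0.05, 0.05), each = r), r, 3)
  alpha <- c(1 + 0.02 * m, 1, 1)  # pseudo-counts favouring the null weight
  min_sep <- 2.5
  ll_old <- rep(-Inf, r)
  converged <- rep(FALSE, r)
  active <- seq_len(r)
  for (it in seq_len(maxit)) {
    za <- z[active, , drop = FALSE]
    d1 <- pw[active, 1] * stats::dnorm((za - mu[active, 1]) / sg[active, 1]) / sg[active, 1]
    d2 <- pw[active, 2] * stats::dnorm((za - mu[active, 2]) / sg[active, 2]) / sg[active, 2]
    d3 <- pw[active, 3] * stats::dnorm((za - mu[active, 3]) / sg[active, 3]) / sg[active, 3]
    tot <- d1 + d2 + d3
    tot[tot < 1e-300] <- 1e-300
    ll <- rowSums(log(tot))
    r1 <- d1 / tot; r2 <- d2 / tot; r3 <- d3 / tot
    nk <- cbind(rowSums(r1), rowSums(r2), rowSums(r3))
    pwa <- sweep(nk, 2, alpha - 1, "+")
    pw[active, ] <- pwa / rowSums(pwa)
    upd <- function(resp, k) {
      n_k <- nk[, k]
      ok <- n_k > 1e-8
      mu_k <- mu[active, k]
      mu_k[ok] <- rowSums(resp * za)[ok] / n_k[ok]
      sg_k <- sg[active, k]
      sg_k[ok] <- sqrt(rowSums(resp * (za - mu_k)^2)[ok] / n_k[ok])
      sg_k[!is.finite(sg_k) | sg_k < 1e-3] <- 1e-3
      mu[active, k] <<- mu_k
      sg[active, k] <<- sg_k
    }
    upd(r1, 1); upd(r2, 2); upd(r3, 3)
    # flanks model diffuse signal: at least as wide as the null and kept
    # min_sep null-SDs away, so they cannot nibble the null's shoulders
    sg[active, 2] <- pmax(sg[active, 2], sg[active, 1])
    sg[active, 3] <- pmax(sg[active, 3], sg[active, 1])
    mu[active, 2] <- pmin(mu[active, 2], mu[active, 1] - min_sep * sg[active, 1])
    mu[active, 3] <- pmax(mu[active, 3], mu[active, 1] + min_sep * sg[active, 1])
    done <- is.finite(ll) & abs(ll - ll_old[active]) < tol * (1 + abs(ll))
    converged[active[done]] <- TRUE
    ll_old[active] <- ll
    active <- active[!done]
    if (length(active) == 0) break
  }
  null_k <- max.col(pw)
  idx <- cbind(seq_len(r), null_k)
  credible <- converged & pw[idx] >= 0.5 & sg[idx] > 1e-3
  bias <- ifelse(credible, mu[idx], med)
  inflation <- ifelse(credible, sg[idx], s0)
  list(bias = bias, inflation = inflation,
       method = ifelse(credible, "em", "mad"), converged = converged)
}

.strip_chr <- function(x) sub("^chr", "", as.character(x))

.is_autosome <- function(chrom) .strip_chr(chrom) %in% as.character(1:22)

#' Classify a CpG-gene pair as cis, trans, or excluded
#'
#' The distance is 0 when the CpG lies inside the gene interval, otherwise
#' the base-pair gap to the nearest gene edge. Pairs within `cis_bp`
#' (default 100 kb) are cis; pairs more than `trans_bp` (default 5 Mb)
#' apart, or on different chromosomes, are trans; everything in between is
#' excluded from testing. All arguments are vectorized.
#'
#' @param cpg_chrom,cpg_pos CpG chromosome and 1-based position.
#' @param gene_chrom,gene_start,gene_end gene interval (1-based, closed).
#' @param cis_bp,trans_bp window sizes in bp.
#' @return character vector: `"cis"`, `"trans"`, or `"excluded"`.
#' @export
classify_cis_trans <- function(cpg_chrom, cpg_pos, gene_chrom,
                               gene_start, gene_end,
                               cis_bp = 1e5, trans_bp = 5e6) {
  same <- .strip_chr(cpg_chrom) == .strip_chr(gene_chrom)
  gap <- pmax(gene_start - cpg_pos, cpg_pos - gene_end, 0)
  ifelse(!same, "trans",
         ifelse(gap <= cis_bp, "cis",
                ifelse(gap > trans_bp, "trans", "excluded")))
}

#' Full CpG x gene cis/trans mask
#'
#' @param cpg_coords data.frame with `cpg`, `chrom`, `pos`.
#' @param gene_coords data.frame with `gene`, `chrom`, `start`, `end`.
#' @inheritParams classify_cis_trans
#' @return character matrix (CpGs x genes) partitioning every pair into
#'   exactly one of cis / trans / excluded.
#' @export
cis_trans_mask <- function(cpg_coords, gene_coords,
                           cis_bp = 1e5, trans_bp = 5e6) {
  nc <- nrow(cpg_coords); ng <- nrow(gene_coords)
  m <- matrix(classify_cis_trans(
    rep(cpg_coords$chrom, times = ng), rep(cpg_coords$pos, times = ng),
    rep(gene_coords$chrom, each = nc), rep(gene_coords$start, each = nc),
    rep(gene_coords$end, each = nc), cis_bp = cis_bp, trans_bp = trans_bp),
    nrow = nc, ncol = ng,
    dimnames = list(cpg_coords$cpg, gene_coords$gene))
  m
}

#' Run the full methylation-expression association analysis
#'
#' For each clock CpG, regresses every gene's RIN-transformed expression on
#' the CpG's beta value plus known covariates and latent factors, then
#' applies the per-CpG empirical-null correction to the resulting row of t
#' statistics. Non-autosomal CpGs and genes are dropped up front. Returns
#' the matrices of raw and corrected statistics together with the cis/trans
#' mask.
#'
#' @param beta sample x CpG matrix (clock CpGs).
#' @param expression a [preprocess_expression()] result or a plain sample x
#'   gene matrix.
#' @param design covariate design matrix from [association_design()].
#' @param cpg_coords,gene_coords coordinate data.frames (see
#'   [cis_trans_mask()]); `gene_coords` defaults to the annotation carried
#'   by `expression`.
#' @param k_latent number of latent factors appended to the design
#'   (default 5; 0 disables).
#' @param k_protect number of leading methylation principal components the
#'   latent factors are kept orthogonal to (see
#'   [estimate_latent_factors()]). Default 0 (off): the factors are then a
#'   function of expression alone, which keeps permutation tests clean -
#'   factors conditioned on both data sides induce collider-style partial
#'   correlations under label permutation. Turn it on only when the
#'   expression signal axis is so dominant that unprotected factors would
#'   swallow it, and interpret permutation results with care.
#' @param correct apply the per-CpG empirical-null correction.
#' @param cis_bp,trans_bp cis/trans window sizes.
#' @return an `assoc_results` object: matrices `t`, `p`, `t_corrected`
#'   (corrected z scale), `p_corrected`, character `mask`, per-CpG `bias`
#'   and `inflation`, `df`, and the latent factor matrix used.
#' @export
run_association <- function(beta, expression, design,
                            cpg_coords, gene_coords = NULL,
                            k_latent = 5, k_protect = 0, correct = TRUE,
                            cis_bp = 1e5, trans_bp = 5e6) {
  if (inherits(expression, "preprocessed_expression")) {
    if (is.null(gene_coords)) gene_coords <- expression$genes
    expr <- expression$expr
  } else expr <- expression
  .stop_if(is.null(gene_coords), "gene_coords required")
  cpg_coords <- cpg_coords[.is_autosome(cpg_coords$chrom), , drop = FALSE]
  gene_coords <- gene_coords[.is_autosome(gene_coords$chrom), , drop = FALSE]
  beta <- beta[, intersect(colnames(beta), cpg_coords$cpg), drop = FALSE]
  expr <- expr[, intersect(colnames(expr), gene_coords$gene), drop = FALSE]
  cpg_coords <- cpg_coords[match(colnames(beta), cpg_coords$cpg), ]
  gene_coords <- gene_coords[match(colnames(expr), gene_coords$gene), ]
  lf <- NULL
  if (k_latent > 0) {
    protect <- NULL
    if (k_protect > 0) {
      q <- qr.Q(qr(design))
      br <- beta - q %*% crossprod(q, beta)
      protect <- svd(br, nu = min(k_protect, ncol(br)), nv = 0)$u
    }
    lf <- estimate_latent_factors(expr, design, k = k_latent,
                                  protect = protect)
    design <- cbind(design, lf)
  }
  fit <- .assoc_t_matrix(beta, expr, design)
  tmat <- fit$t
  pmat <- 2 * stats::pt(-abs(tmat), df = fit$df)
  tcor <- tmat; pcor <- pmat
  bias <- rep(0, nrow(tmat)); inflation <- rep(1, nrow(tmat))
  method <- rep("none", nrow(tmat))
  if (correct) {
    zmat <- .t_to_z(tmat, fit$df)
    en <- .empirical_null_rows(zmat)
    tcor <- (zmat - en$bias) / pmax(en$inflation, 1)
    pcor <- 2 * stats::pnorm(-abs(tcor))
    bias <- en$bias
    inflation <- en$inflation
    method <- en$method
  }
  names(bias) <- names(inflation) <- names(method) <- rownames(tmat)
  mask <- cis_trans_mask(cpg_coords, gene_coords,
                         cis_bp = cis_bp, trans_bp = trans_bp)
  structure(list(t = tmat, p = pmat, t_corrected = tcor, p_corrected = pcor,
                 mask = mask, bias = bias, inflation = inflation,
                 correction = method, df = fit$df, latent_factors = lf,
                 cpg_coords = cpg_coords, gene_coords = gene_coords),
            class = "assoc_results")
}

#' @export
print.assoc_results <- function(x, ...) {
  cat(sprintf("<assoc_results> %d CpGs x %d genes; %d cis / %d trans / %d excluded pairs\n",
              nrow(x$t), ncol(x$t), sum(x$mask == "cis"),
              sum(x$mask == "trans"), sum(x$mask == "excluded")))
  if (any(x$correction != "none")) {
    cat(sprintf("  per-CpG empirical null: median inflation %.2f, median bias %.2f\n",
                stats::median(x$inflation), stats::median(x$bias)))
  }
  invisible(x)
}

#' @export
summary.assoc_results <- function(object, alpha = 0.05, ...) {
  cis <- select_significant(object, "cis", alpha = alpha)
  trans <- select_significant(object, "trans", alpha = alpha)
  out <- list(n_cis_pairs = sum(object$mask == "cis"),
              n_trans_pairs = sum(object$mask == "trans"),
              n_cis_significant = nrow(cis),
              n_trans_significant = nrow(trans),
              median_inflation = stats::median(object$inflation))
  class(out) <- "summary.assoc_results"
  out
}

#' @export
print.summary.assoc_results <- function(x, ...) {
  cat(sprintf(paste0("cis pairs tested: %d (significant: %d)\n",
                     "trans pairs tested: %d (significant: %d)\n",
                     "median per-CpG inflation: %.2f\n"),
              x$n_cis_pairs, x$n_cis_significant,
              x$n_trans_pairs, x$n_trans_significant, x$median_inflation))
  invisible(x)
}

#' Bonferroni-significant pairs within the cis or trans domain
#'
#' The Bonferroni family is the number of *tested* pairs in the requested
#' domain (cis and trans are corrected separately).
#'
#' @param results an `assoc_results`.
#' @param domain `"cis"` or `"trans"`.
#' @param alpha familywise level (default 0.05).
#' @param corrected use empirical-null-corrected p values (default TRUE).
#' @return data.frame `cpg`, `gene`, `t`, `p`, `p_bonf`, sorted by p.
#' @export
select_significant <- function(results, domain = c("cis", "trans"),
                               alpha = 0.05, corrected = TRUE) {
  domain <- match.arg(domain)
  sel <- results$mask == domain
  .stop_if(!any(sel), paste0("no ", domain, " pairs to test"))
  m <- sum(sel)
  p <- if (corrected) results$p_corrected else results$p
  t <- if (corrected) results$t_corrected else results$t
  p_bonf <- pmin(1, p * m)
  hit <- sel & p_bonf < alpha
  idx <- which(hit, arr.ind = TRUE)
  out <- data.frame(cpg = rownames(results$t)[idx[, 1]],
                    gene = colnames(results$t)[idx[, 2]],
                    t = t[hit], p = p[hit], p_bonf = p_bonf[hit],
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Core-set thresholds: 5% of each clock, rounded up
#'
#' @param clock_sizes named integer vector of clock CpG counts.
#' @param fraction core-set fraction (default 0.05).
#' @export
core_set_thresholds <- function(clock_sizes, fraction = 0.05) {
  ceiling(fraction * clock_sizes)
}

#' Select the core trans-association set
#'
#' A gene enters the core set when, within at least one clock, it is
#' Bonferroni-significantly associated with at least `ceiling(fraction *
#' clock size)` of that clock's CpGs. A CpG enters when it is significantly
#' associated with at least `min_trans_genes` genes in trans. A CpG may
#' belong to several clocks and is counted within each.
#'
#' @param results an `assoc_results`.
#' @param clock_membership named list: clock name -> character vector of
#'   CpG IDs.
#' @param fraction per-clock core fraction (default 0.05).
#' @param min_trans_genes minimum trans-gene count per CpG (default 10).
#' @param alpha familywise level for [select_significant()].
#' @return a `core_set` list: `genes`, `cpgs`, `thresholds`,
#'   `gene_counts` (gene x clock significant-CpG counts), `cpg_counts`,
#'   and the significant trans pair table.
#' @export
select_core_set <- function(results, clock_membership, fraction = 0.05,
                            min_trans_genes = 10, alpha = 0.05) {
  sig <- select_significant(results, "trans", alpha = alpha)
  sizes <- vapply(clock_membership, length, integer(1))
  thresholds <- core_set_thresholds(sizes, fraction)
  genes <- colnames(results$t)
  gene_counts <- sapply(clock_membership, function(cpgs) {
    tab <- table(factor(sig$gene[sig$cpg %in% cpgs], levels = genes))
    as.integer(tab)
  })
  rownames(gene_counts) <- genes
  gene_in <- apply(sweep(gene_counts, 2, thresholds, ">="), 1, any)
  cpg_counts <- table(factor(sig$cpg, levels = rownames(results$t)))
  cpg_in <- cpg_counts >= min_trans_genes
  structure(list(genes = genes[gene_in],
                 cpgs = rownames(results$t)[cpg_in],
                 thresholds = thresholds,
                 gene_counts = gene_counts,
                 cpg_counts = as.integer(cpg_counts) |>
                   stats::setNames(rownames(results$t)),
                 significant_trans = sig),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %d genes, %d CpGs (thresholds: %s; min trans-genes per CpG: inferred from selection)\n",
              length(x$genes), length(x$cpgs),
              paste(sprintf("%s=%d", names(x$thresholds), x$thresholds),
                    collapse = ", ")))
  invisible(x)
}

#' Permutation test of the trans-association count
#'
#' Shuffles the sample identifiers of the methylation matrix (expression
#' and covariates stay linked), reruns the trans analysis, and counts
#' Bonferroni-significant trans associations per permutation. The empirical
#' p value uses +1 smoothing: `(1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param beta,expression,design,cpg_coords,gene_coords as in
#'   [run_association()].
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the permutation stream.
#' @param alpha familywise level.
#' @param k_latent,k_protect,correct,cis_bp,trans_bp forwarded to the analysis.
#' @return a `permutation_result`: `observed`, integer vector `perm_counts`,
#'   `p_empirical`.
#' @export
permutation_test <- function(beta, expression, design, cpg_coords,
                             gene_coords = NULL, n_perm = 1000, seed = 1,
                             alpha = 0.05, k_latent = 5, k_protect = 0,
                             correct = TRUE, cis_bp = 1e5, trans_bp = 5e6) {
  .stop_if(n_perm < 1, "n_perm must be >= 1")
  obs_res <- run_association(beta, expression, design, cpg_coords,
                             gene_coords, k_latent = k_latent,
                             k_protect = k_protect, correct = correct,
                             cis_bp = cis_bp, trans_bp = trans_bp)
  count_trans <- function(res) {
    sel <- res$mask == "trans"
    if (!any(sel)) return(0L)
    sum(pmin(1, res$p_corrected * sum(sel))[sel] < alpha)
  }
  observed <- count_trans(obs_res)
  set.seed(seed)
  perm_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(beta))
    bperm <- beta[perm, , drop = FALSE]
    rownames(bperm) <- rownames(beta)
    res <- run_association(bperm, expression, design, cpg_coords,
                           gene_coords, k_latent = k_latent,
                           k_protect = k_protect, correct = correct,
                           cis_bp = cis_bp, trans_bp = trans_bp)
    perm_counts[b] <- count_trans(res)
  }
  structure(list(observed = observed, perm_counts = perm_counts,
                 p_empirical = (1 + sum(perm_counts >= observed)) / (1 + n_perm),
                 n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %d significant trans associations; %d/%d permutations >= observed; empirical p = %.4g\n",
              x$observed, sum(x$perm_counts >= x$observed), x$n_perm,
              x$p_empirical))
  invisible(x)
}
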