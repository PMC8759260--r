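test_that("expression preprocessing filters, normalizes and RIN-transforms", {
  counts <- cbind(keep = c(5L, 8L, 3L, 9L), boundary = c(1L, 1L, 1L, 2L),
                  nc = c(50L, 60L, 70L, 80L))
  rownames(counts) <- paste0("s", 1:4)
  ann <- data.frame(gene = c("keep", "boundary", "nc"),
                    chrom = "chr1", start = 1, end = 10,
                    biotype = c("protein_coding", "protein_coding", "lincRNA"))
  pe <- preprocess_expression(counts, ann)
  expect_equal(colnames(pe$expr), "keep")  # median 1 removed (strict >), lincRNA removed
  expect_lt(abs(mean(pe$expr[, "keep"])), 1e-8)

  # RIN closed form on [5, 1, 9]
  expect_equal(rank_inverse_normal(c(5, 1, 9)),
               qnorm(c(3, 1, 5) / 6), tolerance = 1e-12)
  # zero library size
  counts0 <- counts; counts0[1, ] <- 0L
  expect_error(preprocess_expression(counts0, ann), "zero library")
  expect_error(preprocess_expression(counts * 0L, ann), "library|filtered")
})

test_that("association design encodes covariates and rejects collinearity", {
  set.seed(6)
  cov <- data.frame(
    cohort = rep(c("A", "B"), 10), age = rnorm(20, 50, 10),
    sex = sample(rep(c("F", "M"), each = 10)),
    basophil_pct = runif(20), eosinophil_pct = runif(20),
    lymphocyte_pct = runif(20, 20, 40), monocyte_pct = runif(20, 5, 10),
    neutrophil_pct = runif(20, 50, 70),
    bisulphite_plate = rep(c("P1", "P2"), each = 10))
  x <- association_design(cov)
  expect_false(any(grepl("neutrophil", colnames(x))))
  expect_true("age" %in% colnames(x))
  expect_true(any(grepl("cohort", colnames(x))))
  x2 <- association_design(cov, use_cellcounts = FALSE)
  expect_false(any(grepl("pct", colnames(x2))))
  # collinear numeric covariate
  cov$basophil_pct <- cov$age
  cov$eosinophil_pct <- cov$age
  expect_error(association_design(cov), "collinear")
  cov$basophil_pct <- NA
  expect_error(association_design(cov), "missing values")
})

test_that("per-gene OLS matches the normal-equations oracle and flags perfect fits", {
  set.seed(2)
  n <- 12
  covars <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  x <- runif(n)
  y <- 2 * x + covars %*% c(1, 0.5, -1) + rnorm(n, 0, 0.3)
  expr <- cbind(g1 = as.vector(y), g2 = rnorm(n))
  ft <- fit_cpg_gene_models(x, expr, covars)
  orc <- ols_t_oracle(expr[, "g1"], x, covars)
  expect_equal(ft$t[1], unname(orc["t"]), tolerance = 1e-8)
  expect_equal(ft$p[1], unname(orc["p"]), tolerance = 1e-8)
  orc2 <- ols_t_oracle(expr[, "g2"], x, covars)
  expect_equal(ft$t[2], unname(orc2["t"]), tolerance = 1e-8)

  # gene identical to the CpG column -> perfect fit flagged
  ft2 <- fit_cpg_gene_models(x, cbind(g = x), matrix(1, n, 1))
  expect_true(ft2$perfect_fit[1])

  # rank-deficient design names the collinear column
  bad <- cbind(a = covars[, 2], b = covars[, 2])
  expect_error(fit_cpg_gene_models(x, expr, cbind(1, bad)), "collinear")
})

test_that("raw p values are uniform under the global null", {
  set.seed(17)
  n <- 300
  expr <- matrix(rnorm(n * 2000), n, 2000,
                 dimnames = list(NULL, paste0("g", 1:2000)))
  design <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  ft <- fit_cpg_gene_models(rnorm(n), expr, design)
  ks <- suppressWarnings(ks.test(ft$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("latent factors are orthonormal, recover planted confounders, and vanish without residual structure", {
  set.seed(4)
  n <- 500; g <- 200
  design <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  u <- rnorm(n)
  load <- numeric(g); load[1:100] <- rnorm(100, 0, 1)
  expr <- design %*% matrix(rnorm(3 * g), 3, g) + u %o% load +
    matrix(rnorm(n * g, 0, 0.5), n, g)
  f <- estimate_latent_factors(expr, design, k = 3)
  expect_equal(crossprod(f), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(abs(cor(f[, 1], u)), 0.9)

  # expression exactly in the covariate span: factors explain ~no variance
  expr0 <- design %*% matrix(rnorm(3 * g), 3, g)
  f0 <- estimate_latent_factors(expr0, design, k = 2)
  resid0 <- expr0 - design %*% solve(crossprod(design), crossprod(design, expr0))
  expect_lt(sum((crossprod(f0, resid0))^2), 1e-12)
  expect_error(estimate_latent_factors(expr, design, k = 0), "positive")
  expect_error(estimate_latent_factors(expr[1:4, ], design[1:4, ], k = 3),
               "degrees of freedom")
})

test_that("the empirical null is recovered across regimes", {
  set.seed(31)
  # calibrated input: bias and inflation near (0, 1)
  c1 <- empirical_null_correct(rnorm(10000))
  expect_lt(abs(c1$bias), 0.03)
  expect_lt(abs(c1$inflation - 1), 0.03)
  # affine null: corrected z indistinguishable from N(0,1)
  c2 <- empirical_null_correct(rnorm(10000, 0.5, 2))
  expect_gt(suppressWarnings(ks.test(c2$z_corrected, "pnorm"))$p.value, 0.01)
  # contaminated null: the mixture shields the signal component
  c3 <- empirical_null_correct(c(rnorm(9500, 0, 2), rnorm(500, 4, 1)))
  expect_gt(c3$inflation, 1.8)
  expect_lt(c3$inflation, 2.2)
  expect_error(empirical_null_correct(rnorm(50)), ">= 100")
})

test_that("cis/trans classification follows the distance rules and partitions pairs", {
  expect_equal(classify_cis_trans("chr1", 1e6, "chr1", 1.05e6, 1.06e6), "cis")
  expect_equal(classify_cis_trans("chr1", 1e6, "chr2", 1, 10), "trans")
  # boundary conventions
  expect_equal(classify_cis_trans("chr1", 1e6, "chr1", 1.1e6, 1.2e6), "cis")      # gap exactly 100 kb
  expect_equal(classify_cis_trans("chr1", 1e6, "chr1", 4e6, 4.1e6), "excluded")   # 3 Mb
  expect_equal(classify_cis_trans("chr1", 1e6, "chr1", 6e6, 6.1e6), "excluded")   # gap exactly 5 Mb
  expect_equal(classify_cis_trans("chr1", 1e6, "chr1", 6000001, 6100000), "trans") # gap 5,000,001
  # inside the gene -> distance 0 -> cis
  expect_equal(classify_cis_trans("chr1", 5e6, "chr1", 4.9e6, 5.1e6), "cis")

  set.seed(8)
  cpgs <- data.frame(cpg = paste0("cg", 1:30),
                     chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     pos = sample.int(2e7, 30))
  genes <- data.frame(gene = paste0("g", 1:20),
                      chrom = sample(c("chr1", "chr2"), 20, TRUE),
                      start = sample.int(2e7, 20))
  genes$end <- genes$start + 1e4
  m <- cis_trans_mask(cpgs, genes)
  expect_true(all(m %in% c("cis", "trans", "excluded")))
  # matches the scalar rule applied pairwise
  for (i in c(1, 7, 20)) for (j in c(2, 9, 18)) {
    expect_equal(m[i, j],
                 classify_cis_trans(cpgs$chrom[i], cpgs$pos[i], genes$chrom[j],
                                    genes$start[j], genes$end[j]))
  }
})

test_that("Bonferroni selection uses the domain pair count and controls FWER", {
  # arithmetic: same raw p, different family sizes
  expect_equal(min(1, 0.0004 * 100), 0.04)
  expect_equal(min(1, 0.0004 * 1000), 0.4)
  set.seed(23)
  n <- 60
  cpgs <- data.frame(cpg = paste0("cg", 1:20), chrom = "chr1",
                     pos = sample.int(1e6, 20))
  genes <- data.frame(gene = paste0("g", 1:20), chrom = "chr2",
                      start = sample.int(1e6, 20), biotype = "protein_coding")
  genes$end <- genes$start + 100
  design <- cbind(1, rnorm(n))
  hits <- 0L
  for (rep in 1:200) {
    beta <- matrix(runif(n * 20), n, 20, dimnames = list(NULL, cpgs$cpg))
    expr <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, genes$gene))
    res <- run_association(beta, expr, design, cpgs, genes,
                           k_latent = 0, correct = FALSE)
    sig <- select_significant(res, "trans", corrected = FALSE)
    if (nrow(sig) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 15L)
})

test_that("core-set selection applies the per-clock 5% rule and the 10-gene rule", {
  expect_equal(unname(core_set_thresholds(c(71, 353, 391, 514))),
               c(4, 18, 20, 26))
  # construct results where counts are fully controlled
  ncpg <- 30; ng <- 15
  t <- matrix(0, ncpg, ng, dimnames = list(paste0("cg", 1:ncpg),
                                           paste0("g", 1:ng)))
  p <- matrix(1, ncpg, ng, dimnames = dimnames(t))
  mask <- matrix("trans", ncpg, ng, dimnames = dimnames(t))
  # g1: significant with cg1..cg3 (3 CpGs); g2: with cg1..cg17 (17)
  p[1:3, 1] <- 1e-10
  p[1:17, 2] <- 1e-10
  # cg1 associated with 10 genes; cg2 with 9 (g1 and g2 via the columns
  # above plus g4..g10)
  p[1, 1:10] <- 1e-10
  p[2, 4:10] <- 1e-10
  res <- structure(list(t = t, t_corrected = t, p = p, p_corrected = p,
                        mask = mask), class = "assoc_results")
  core <- select_core_set(res, list(a = paste0("cg", 1:30)),
                          fraction = 0.1, min_trans_genes = 10)
  # threshold ceil(0.1*30) = 3: g1 (3 CpGs) in, g2 (17) in
  expect_true(all(c("g1", "g2") %in% core$genes))
  core2 <- select_core_set(res, list(a = paste0("cg", 1:30)),
                           fraction = 0.14, min_trans_genes = 10)
  # threshold ceil(4.2) = 5: g1 (3) out, g2 (17) in
  expect_false("g1" %in% core2$genes)
  expect_true("g2" %in% core2$genes)
  expect_equal(core$cpgs, "cg1")  # 10 genes in, 9 genes out
  # a gene just below a 71-CpG clock's threshold (3 < ceil(0.05*71) = 4)
  core4 <- select_core_set(res, list(h1 = paste0("cg", 1:71)),
                           fraction = 0.05, min_trans_genes = 10)
  expect_false("g1" %in% core4$genes)
})

test_that("permutation test: trivial null, determinism", {
  set.seed(99)
  n <- 40
  cpgs <- data.frame(cpg = paste0("cg", 1:5), chrom = "chr1",
                     pos = sample.int(1e6, 5))
  genes <- data.frame(gene = paste0("g", 1:6), chrom = "chr2",
                      start = sample.int(1e6, 6), biotype = "protein_coding")
  genes$end <- genes$start + 100
  beta <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, cpgs$cpg))
  expr <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, genes$gene))
  design <- cbind(1, rnorm(n))
  pt <- permutation_test(beta, expr, design, cpgs, genes, n_perm = 20,
                         seed = 7, k_latent = 0, correct = FALSE)
  expect_equal(pt$observed, 0L)
  expect_equal(pt$p_empirical, 1)  # every permutation >= an observed count of 0
  pt2 <- permutation_test(beta, expr, design, cpgs, genes, n_perm = 20,
                          seed = 7, k_latent = 0, correct = FALSE)
  expect_identical(pt$perm_counts, pt2$perm_counts)
  expect_error(permutation_test(beta, expr, design, cpgs, genes, n_perm = 0),
               "n_perm")
})
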