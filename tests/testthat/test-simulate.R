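test_that("configuration validation rejects impossible worlds", {
  expect_error(simulation_config(n_samples = 1), "n_samples")
  expect_error(simulation_config(age_range = c(80, 20)), "age_range")
  expect_error(simulation_config(beta_noise_sd = -0.1), "non-negative")
  expect_error(simulation_config(cpg_split = c(cluster1 = 300, cluster2 = 60,
                                               neutral = 80)),
               "sum to n_clock_cpgs")
  expect_error(simulation_config(gene_split = c(naive_marker = 1,
                                                activated_marker = 1,
                                                null = 1)),
               "sum to n_genes")
})

test_that("cell fractions: simplex closure, age trends, anticorrelation", {
  cfg <- simulation_config()
  set.seed(1)
  ages <- runif(5000, 18, 87)
  f <- simulate_cell_fractions(ages, cfg)
  expect_true(all(abs(rowSums(f) - 1) < 1e-12))
  expect_true(all(f >= 0))
  # neutrophil / lymphocyte strongly anticorrelated
  lymph <- rowSums(f[, c("naive_T", "activated_T", "nk_canonical",
                         "nk_adaptive", "b_cell")])
  expect_lte(cor(f[, "neutrophil"], lymph), -0.9)
  # monotone trend: activated share increases with age
  expect_gt(coef(lm(f[, "activated_T"] ~ ages))[2], 0)
  # null slope: activation independent of age
  cfg0 <- simulation_config(activation_slope = 0)
  set.seed(2)
  f0 <- simulate_cell_fractions(ages, cfg0)
  expect_lt(abs(cor(ages, f0[, "activated_T"])), 0.05)
  expect_error(simulate_cell_fractions(numeric(0), cfg), "empty")
})

test_that("reference profiles have the stated cluster structure", {
  set.seed(3)
  refs <- build_reference_profiles(simulation_config())
  lab <- refs$cpg_cluster_labels
  rb <- refs$reference_beta
  cl1 <- names(lab)[lab == "cluster1"]
  cl2 <- names(lab)[lab == "cluster2"]
  neu <- names(lab)[lab == "neutral"]
  expect_true(all(rb["naive_T", cl1] - rb["activated_T", cl1] >= 0.4))
  expect_true(all(rb["activated_T", cl2] - rb["naive_T", cl2] >= 0.4))
  # neutral CpGs: identical across compartments by construction
  expect_true(all(apply(rb[, neu, drop = FALSE], 2,
                        function(x) diff(range(x))) == 0))
  expect_true(all(rb >= 0 & rb <= 1))
  # marker ordering in expression
  glab <- refs$gene_cluster_labels
  nm <- names(glab)[glab == "naive_marker"]
  expect_true(all(refs$reference_expr["naive_T", nm] >
                    refs$reference_expr["activated_T", nm]))
})

test_that("cohorts are deterministic and zero noise gives the exact mixture", {
  a <- simulate_cohort(simulation_config(n_samples = 50, seed = 7))
  b <- simulate_cohort(simulation_config(n_samples = 50, seed = 7))
  expect_identical(a$cohort$beta, b$cohort$beta)
  expect_identical(a$cohort$counts, b$cohort$counts)
  expect_identical(a$cohort$covariates, b$cohort$covariates)

  cfg0 <- simulation_config(n_samples = 60, seed = 8, beta_noise_sd = 0,
                            batch_sd_beta = 0, batch_sd_expr = 0,
                            cellcount_noise_sd = 0, age_deviation_sd = 0)
  sim <- simulate_cohort(cfg0)
  mixture <- sim$truth$cell_fractions %*% sim$truth$reference_beta
  expect_equal(sim$cohort$beta, mixture)
  # true clock reproduces chronological age exactly
  pr <- predict_age(sim$truth$true_clock, sim$cohort$beta)
  expect_lt(mean(abs(pr$predicted_age - sim$cohort$covariates$age)), 1e-8)
})

test_that("default cohort: age couples to activation and the true clock is accurate", {
  sim <- simulate_cohort(simulation_config(n_samples = 2000, seed = 13))
  f <- sim$truth$cell_fractions
  age <- sim$cohort$covariates$age
  expect_gt(cor(age, f[, "activated_T"]), 0)
  expect_lt(cor(age, f[, "naive_T"]), 0)
  s <- prediction_error_summary(predict_age(sim$truth$true_clock,
                                            sim$cohort$beta), age)
  # noise-implied bound: clock weights x (measurement + 3 batch layers of)
  # beta noise, plus the age-deviation gap the clock cannot see
  w <- sim$truth$true_clock$coefficients
  cfg <- simulation_config()
  sigma <- sqrt(sum(w^2) * (cfg$beta_noise_sd^2 + 3 * cfg$batch_sd_beta^2) +
                  cfg$age_deviation_sd^2)
  expect_lt(s$mae, 1.5 * sigma)
  expect_gt(s$pearson_r, 0.9)
  # counts are non-negative integers; betas in range; covariates complete
  expect_true(all(sim$cohort$counts >= 0))
  expect_true(all(sim$cohort$counts == round(sim$cohort$counts)))
  expect_true(all(sim$cohort$beta >= 0 & sim$cohort$beta <= 1))
  expect_false(anyNA(sim$cohort$covariates))
})

test_that("synthetic clocks fit exactly without noise and generalize with it", {
  cfg0 <- simulation_config(n_samples = 150, seed = 9, beta_noise_sd = 0,
                            batch_sd_beta = 0, batch_sd_expr = 0,
                            cellcount_noise_sd = 0, age_deviation_sd = 0)
  sim0 <- simulate_cohort(cfg0)
  ck0 <- make_synthetic_clock(sim0$truth, sim0$cohort, "identity")
  pr0 <- predict_age(ck0, sim0$cohort$beta)
  expect_lt(mean(abs(pr0$predicted_age - sim0$cohort$covariates$age)), 1e-6)

  # horvath transform round-trips through the inverse
  ages <- seq(1, 100, by = 0.5)
  expect_equal(horvath_inverse_transform(horvath_transform(ages)), ages,
               tolerance = 1e-9)

  # held-out accuracy at default noise
  sim <- simulate_cohort(simulation_config(seed = 15))
  co <- sim$cohort
  idx <- 1:400
  tr_truth <- sim$truth
  tr_truth$cell_fractions <- sim$truth$cell_fractions[idx, ]
  ck <- make_synthetic_clock(tr_truth,
                             list(beta = co$beta[idx, ],
                                  covariates = co$covariates[idx, ]),
                             "identity")
  held <- predict_age(ck, co$beta[-idx, ])
  expect_lt(mean(abs(held$predicted_age - co$covariates$age[-idx])), 6)

  # fewer samples than CpGs
  tiny <- sim$truth
  tiny$cell_fractions <- sim$truth$cell_fractions[1:10, ]
  expect_error(make_synthetic_clock(tiny,
                                    list(beta = co$beta[1:10, ],
                                         covariates = co$covariates[1:10, ]),
                                    "identity"),
               "fewer samples")
})

test_that("replicate pairs share the biological signal but not the noise", {
  sim <- simulate_cohort(simulation_config(n_samples = 60, seed = 30,
                                           n_replicate_pairs = 15))
  rp <- sim$cohort$replicate_pairs
  expect_equal(nrow(rp), 15)
  expect_true(all(rp$replicate %in% rownames(sim$cohort$beta)))
  first <- sim$cohort$beta[rp$sample, , drop = FALSE]
  second <- sim$cohort$beta[rp$replicate, , drop = FALSE]
  icc <- icc_absolute_agreement(first, second)
  # cluster CpGs vary biologically across samples -> high replicate ICC
  cl <- names(sim$truth$cpg_cluster_labels)[
    sim$truth$cpg_cluster_labels != "neutral"]
  expect_gt(median(icc[cl]), 0.5)
})

test_that("cohort artifacts round-trip through their writers bit-exactly", {
  sim <- simulate_cohort(simulation_config(n_samples = 30, seed = 19))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir, truth = sim$truth)
  back <- read_cohort(dir)
  expect_identical(back$beta, sim$cohort$beta)
  expect_identical(back$counts, sim$cohort$counts)
  expect_equal(back$cpg_coords, sim$cohort$cpg_coords)
  expect_equal(back$gene_coords, sim$cohort$gene_coords)
  ck <- read_clock_model(file.path(dir, "true_clock.csv"))
  expect_identical(unname(ck$coefficients),
                   unname(sim$truth$true_clock$coefficients))
  expect_identical(ck$intercept, sim$truth$true_clock$intercept)

  set.seed(2)
  sr <- emit_sorted_cell_reference(sim$truth, n_donors = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_sorted_reference(sr, p)
  back_sr <- read_sorted_reference(p)
  expect_identical(back_sr$beta, sr$beta)
  expect_equal(back_sr$samples, sr$samples)
})
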