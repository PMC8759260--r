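test_that("clock coefficient files round-trip and reject malformed input", {
  ck <- toy_clock(training_means = c(cg1 = 0.4, cg2 = 0.6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clock_model(ck, path)
  back <- read_clock_model(path)
  expect_equal(back$intercept, ck$intercept)
  expect_equal(back$coefficients, ck$coefficients)
  expect_equal(back$transform, "identity")
  expect_equal(back$training_means, ck$training_means)

  # three-row hand fixture
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#transform=identity", "id,coef",
               "(Intercept),10", "cg1,2.0", "cg2,-1.0"), p2)
  m <- read_clock_model(p2)
  expect_equal(length(m$coefficients), 2L)
  expect_equal(m$intercept, 10)

  # duplicate CpG is named in the error
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,coef", "(Intercept),1", "cg1,2", "cg1,3"), p3)
  expect_error(read_clock_model(p3), "cg1")
  # missing intercept
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,coef", "cg1,2"), p4)
  expect_error(read_clock_model(p4), "Intercept")
  # non-numeric weight names the row
  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,coef", "(Intercept),1", "cg1,abc"), p5)
  expect_error(read_clock_model(p5), "row 2")
})

test_that("zhang standardization yields per-sample mean 0 / SD 1 and is idempotent", {
  b <- matrix(c(0.2, 0.4, 0.6, 0.1, 0.8, 0.3), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("cg1", "cg2", "cg3")))
  z <- zhang_standardize(b)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_true(all(abs(sqrt(rowMeans(z^2)) - 1) < 1e-10))
  expect_equal(zhang_standardize(z), z, tolerance = 1e-10)
  b2 <- rbind(b, sflat = c(0.5, 0.5, 0.5))
  expect_error(zhang_standardize(b2), "sflat")
})

test_that("the piecewise age transform has the stated fixed points and inverts", {
  expect_equal(horvath_inverse_transform(0), 20)
  expect_equal(horvath_inverse_transform(1), 41)
  ages <- seq(0, 120, by = 0.5)
  expect_equal(horvath_inverse_transform(horvath_transform(ages)), ages,
               tolerance = 1e-9)
  # strictly increasing and continuous at the knee
  x <- seq(-2, 3, by = 0.01)
  y <- horvath_inverse_transform(x)
  expect_true(all(diff(y) > 0))
  expect_lt(abs(horvath_inverse_transform(1e-9) - horvath_inverse_transform(-1e-9)), 1e-6)
})

test_that("predict_age computes the linear score, transforms, and accounts for missing CpGs", {
  b <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("cg1", "cg2")))
  expect_equal(predict_age(toy_clock(), b)$predicted_age, 10.5)
  # horvath: score 0 -> adult_age years
  ckh <- clock_model("h", 0, c(cg1 = 2, cg2 = -1), "horvath")
  bh <- matrix(c(0.25, 0.5), 1, dimnames = list("s1", c("cg1", "cg2")))
  expect_equal(predict_age(ckh, bh)$predicted_age, 20)

  # absent column imputed from training means, counted per sample
  ck <- toy_clock(training_means = c(cg2 = 0.5))
  b1 <- matrix(0.5, 2, 1, dimnames = list(c("s1", "s2"), "cg1"))
  pr <- predict_age(ck, b1, max_missing_frac = 0.5)
  expect_equal(pr$predicted_age, c(10.5, 10.5))
  expect_equal(pr$n_missing_cpgs, c(1L, 1L))
  # absent column with no training mean errors
  expect_error(predict_age(toy_clock(), b1, max_missing_frac = 0.5), "cg2")
  # NA entries fall back to the cohort mean of that CpG
  b2 <- matrix(c(0.5, 0.5, NA, 0.3, 0.7, 0.5), 3, 2,
               dimnames = list(c("s1", "s2", "s3"), c("cg1", "cg2")))
  pr2 <- predict_age(toy_clock(), b2)
  expect_equal(pr2$n_missing_cpgs, c(0L, 0L, 1L))
  expect_equal(pr2$predicted_age[3], 10 + 2 * mean(c(0.5, 0.5)) - 1 * 0.5)
  # too many absent clock CpGs
  big <- clock_model("big", 0, setNames(rep(1, 10), paste0("cg", 1:10)))
  expect_error(predict_age(big, b1), "missing")
  expect_error(predict_age(big, matrix(1, 1, 1, dimnames = list("s", "x"))),
               "all clock CpGs")
})

test_that("identity clocks are linear and zhang clocks shift-invariant", {
  set.seed(1)
  b <- matrix(runif(30), 3, 10,
              dimnames = list(paste0("s", 1:3), paste0("cg", 1:10)))
  ck <- clock_model("lin", 2, setNames(rnorm(10), colnames(b)))
  a <- 0.3
  combo <- a * b[1, ] + (1 - a) * b[2, ]
  pc <- predict_age(ck, rbind(s = combo))$predicted_age
  p12 <- predict_age(ck, b)$predicted_age
  expect_equal(pc, a * p12[1] + (1 - a) * p12[2], tolerance = 1e-10)

  ckz <- clock_model("z", 2, setNames(rnorm(10), colnames(b)), "zhang")
  bshift <- b
  bshift[1, ] <- bshift[1, ] + 0.07
  expect_equal(predict_age(ckz, b)$predicted_age[1],
               predict_age(ckz, bshift)$predicted_age[1], tolerance = 1e-8)
})

test_that("error summaries, concordance, and extreme-deviation overlap", {
  s <- prediction_error_summary(c(30, 40), c(28, 44))
  expect_equal(s$mae, 3)
  s2 <- prediction_error_summary(c(30, 40, 50), c(30, 40, 50))
  expect_equal(s2$mae, 0)
  expect_equal(s2$pearson_r, 1)
  # constant vector: r flagged as NA, not silently wrong
  expect_true(is.na(prediction_error_summary(rep(5, 4), 1:4)$pearson_r))
  expect_error(prediction_error_summary(1:3, 1:4), "mismatch")

  err <- rnorm(20)
  sa <- list(a = list(error = err, mae = 0), b = list(error = err, mae = 0))
  cc <- clock_concordance(sa)
  expect_equal(cc["a", "b"], 1)
  expect_true(isSymmetric(cc))

  # identical -> 100; disjoint -> 0; NaN flag when no extremes
  e1 <- c(12, 15, 1, 2, 3)
  ov <- extreme_deviation_overlap(list(a = e1, b = e1))
  expect_true(all(ov == 100))
  e2 <- c(-1, -2, 12, 0, 1)
  ov2 <- extreme_deviation_overlap(list(a = e1, b = e2))
  expect_equal(ov2["a", "b"], 0)
  ov3 <- extreme_deviation_overlap(list(a = c(0, 1), b = c(12, 0)))
  expect_true(is.nan(ov3["a", "b"]))
  expect_error(extreme_deviation_overlap(list(a = e1, b = e2), threshold = -1),
               "positive")

  # enumeration oracle on a random 2-clock fixture
  set.seed(7)
  ea <- rnorm(200, 0, 8); eb <- 0.6 * ea + rnorm(200, 0, 6)
  ov4 <- extreme_deviation_overlap(list(a = ea, b = eb), threshold = 10)
  brute <- 100 * sum(ea >= 10 & eb >= 10) / sum(ea >= 10)
  expect_equal(ov4["a", "b"], brute)
})

test_that("ICC(2,k) matches the ANOVA oracle and behaves at the extremes", {
  # hand-sized 4x2 table against the independent aov() route
  m <- matrix(c(9, 2, 5, 8, 10, 4, 6, 7), 4, 2)
  got <- icc_absolute_agreement(m[, 1, drop = FALSE] |> `colnames<-`("cg1"),
                                m[, 2, drop = FALSE] |> `colnames<-`("cg1"))
  expect_equal(unname(got), icc2k_oracle(m), tolerance = 1e-12)

  # identical replicates with between-sample variance -> ICC 1
  x <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "cg"))
  expect_equal(unname(icc_absolute_agreement(x, x)), 1)

  # independent replicates -> ICC near 0
  set.seed(3)
  a <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "cg"))
  b <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "cg"))
  expect_lt(abs(icc_absolute_agreement(a, b)), 0.15)

  a[1] <- NA
  expect_error(icc_absolute_agreement(a, b), "incomplete")
})

test_that("PLS cell-count predictor recovers noiseless linear structure", {
  set.seed(11)
  n <- 120
  beta <- matrix(runif(n * 30), n, 30,
                 dimnames = list(paste0("s", 1:n), paste0("cg", 1:30)))
  w <- matrix(0, 30, 2)
  w[1:5, 1] <- c(3, -2, 1, 4, -1)
  w[1:5, 2] <- c(-1, 2, 2, 0, 1)
  counts <- beta %*% w + 50
  colnames(counts) <- c("lymphocyte_pct", "monocyte_pct")
  age <- runif(n, 20, 80); sex <- sample(c("F", "M"), n, TRUE)
  tr <- 1:80
  fit <- fit_cellcount_predictor(beta[tr, ], age[tr], sex[tr], counts[tr, ],
                                 max_ncomp = 10)
  pred <- predict(fit, beta[-tr, ], age[-tr], sex[-tr])
  r2 <- 1 - sum((pred - counts[-tr, ])^2) / sum(scale(counts[-tr, ], scale = FALSE)^2)
  expect_gt(r2, 0.99)
  # training residuals centred
  tr_pred <- predict(fit, beta[tr, ], age[tr], sex[tr])
  expect_lt(abs(mean(tr_pred - counts[tr, ])), 0.05)
  expect_error(fit_cellcount_predictor(beta[1:4, ], age[1:4], sex[1:4],
                                       counts[1:4, ], ncomp = 10),
               "fewer training samples")
})
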