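#' Construct a linear CpG clock
#'
#' An epigenetic clock is a linear predictor of chronological age from the
#' methylation beta values of a fixed CpG set, optionally followed by a
#' non-linear transform. Three transform kinds are supported:
#' `"identity"` (the linear score is the age in years), `"horvath"`
#' (the score is on the piecewise log-linear transformed-age scale and is
#' mapped back to years, see [horvath_inverse_transform()]), and `"zhang"`
#' (beta values are standardized per sample across all supplied CpGs before
#' the linear score, see [zhang_standardize()]).
#'
#' @param name clock label.
#' @param intercept intercept on the (transformed) age scale.
#' @param coefficients named numeric vector, CpG ID -> weight.
#' @param transform one of `"identity"`, `"horvath"`, `"zhang"`.
#' @param adult_age maturity constant (years) for the horvath transform.
#' @param training_means optional named numeric vector of training-set mean
#'   betas, used to impute CpGs missing from a query matrix.
#' @return an object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        transform = c("identity", "horvath", "zhang"),
                        adult_age = 20, training_means = NULL) {
  transform <- match.arg(transform)
  .stop_if(length(coefficients) == 0, "clock has no coefficients")
  .stop_if(is.null(names(coefficients)) || any(names(coefficients) == ""),
           "coefficients must be named by CpG ID")
  dup <- unique(names(coefficients)[duplicated(names(coefficients))])
  .stop_if(length(dup) > 0,
           paste0("duplicate CpG ID(s) in clock: ", paste(dup, collapse = ", ")))
  .stop_if(!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept),
           "intercept must be a single finite number")
  .stop_if(transform == "horvath" && adult_age <= 0,
           "adult_age must be > 0 for the horvath transform")
  if (!is.null(training_means)) {
    training_means <- training_means[names(training_means) %in% names(coefficients)]
  }
  structure(list(name = name, intercept = unname(intercept),
                 coefficients = coefficients, transform = transform,
                 adult_age = adult_age, training_means = training_means),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d CpGs, transform = %s, intercept = %.4g\n",
              x$name, length(x$coefficients), x$transform, x$intercept))
  invisible(x)
}

#' @export
coef.clock_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @rdname predict_age
#' @param object a `clock_model`.
#' @param newdata sample x CpG beta matrix.
#' @param ... passed to [predict_age()].
#' @export
predict.clock_model <- function(object, newdata, ...) {
  predict_age(object, newdata, ...)
}

#' Read a clock coefficient file
#'
#' The dialect is a CSV with header `id,coef` (optional third column `mean`
#' holding training-set mean betas) and a mandatory intercept row with ID
#' `(Intercept)`. Leading comment lines of the form `#key=value` carry the
#' clock metadata (`transform`, `name`, `adult_age`).
#'
#' @param path file path.
#' @return a [clock_model()].
#' @export
read_clock_model <- function(path) {
  .stop_if(!file.exists(path), paste0("no such clock file: ", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(transform = "identity", name = basename(path), adult_age = "20")
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  body <- lines[!grepl("^#", lines)]
  .stop_if(length(body) < 2, "clock file has no data rows")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, colClasses = "character")
  .stop_if(!all(c("id", "coef") %in% names(df)),
           "clock file must have header columns 'id' and 'coef'")
  coefs <- suppressWarnings(as.numeric(df$coef))
  bad <- which(is.na(coefs) & !is.na(df$coef))
  .stop_if(length(bad) > 0,
           paste0("non-numeric weight in clock file at data row ", bad[1],
                  " (id ", df$id[bad[1]], ")"))
  is_int <- df$id == "(Intercept)"
  .stop_if(sum(is_int) == 0, "clock file is missing the (Intercept) row")
  .stop_if(sum(is_int) > 1, "clock file has multiple (Intercept) rows")
  cg_ids <- df$id[!is_int]
  dup <- unique(cg_ids[duplicated(cg_ids)])
  .stop_if(length(dup) > 0,
           paste0("duplicate CpG ID(s) in clock file: ", paste(dup, collapse = ", ")))
  w <- stats::setNames(coefs[!is_int], cg_ids)
  means <- NULL
  if ("mean" %in% names(df)) {
    mv <- suppressWarnings(as.numeric(df$mean[!is_int]))
    if (any(!is.na(mv))) means <- stats::setNames(mv, cg_ids)[!is.na(mv)]
  }
  clock_model(name = meta$name, intercept = coefs[is_int], coefficients = w,
              transform = meta$transform,
              adult_age = as.numeric(meta$adult_age), training_means = means)
}

#' Write a clock coefficient file
#' @param model a [clock_model()].
#' @param path output path.
#' @export
write_clock_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#name=", model$name),
               paste0("#transform=", model$transform),
               paste0("#adult_age=", .fmt_num(model$adult_age))), con)
  has_means <- !is.null(model$training_means)
  writeLines(if (has_means) "id,coef,mean" else "id,coef", con)
  writeLines(paste0("(Intercept),", .fmt_num(model$intercept),
                    if (has_means) "," else ""), con)
  ids <- names(model$coefficients)
  if (has_means) {
    mv <- model$training_means[ids]
    writeLines(paste0(ids, ",", .fmt_num(model$coefficients), ",",
                      ifelse(is.na(mv), "", .fmt_num(mv))), con)
  } else {
    writeLines(paste0(ids, ",", .fmt_num(model$coefficients)), con)
  }
  invisible(path)
}

#' Per-sample standardization of beta values across all CpGs
#'
#' Each sample (row) is centred and scaled to mean 0 and standard deviation
#' 1 across *all* supplied CpGs, not only clock CpGs. The population SD
#' (divisor n) is used.
#'
#' @param beta sample x CpG numeric matrix.
#' @return matrix of the same shape.
#' @export
zhang_standardize <- function(beta) {
  .stop_if(!is.matrix(beta) || ncol(beta) < 2, "need a matrix with >= 2 CpGs")
  mu <- rowMeans(beta)
  centred <- beta - mu
  sdv <- sqrt(rowMeans(centred^2))
  bad <- which(sdv == 0 | !is.finite(sdv))
  .stop_if(length(bad) > 0,
           paste0("constant beta row(s), cannot standardize sample(s): ",
                  paste(rownames(beta)[bad] %||% bad, collapse = ", ")))
  centred / sdv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Piecewise log-linear age transform and its inverse
#'
#' The forward transform maps age to `log(age + 1) - log(adult_age + 1)` up
#' to `adult_age` and `(age - adult_age) / (adult_age + 1)` above it; it is
#' strictly increasing and continuous, with a fixed point at 0 for
#' `age = adult_age`. `horvath_inverse_transform()` maps a transformed score
#' back to years.
#'
#' @param age age in years (forward direction).
#' @param x transformed score (inverse direction).
#' @param adult_age maturity constant in years (default 20).
#' @export
horvath_transform <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname horvath_transform
#' @export
horvath_inverse_transform <- function(x, adult_age = 20) {
  ifelse(x <= 0,
         exp(x + log(adult_age + 1)) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Predict age with a clock
#'
#' Computes the clock's linear score per sample and maps it to years
#' according to the clock's transform. A clock CpG can be missing in two
#' ways: its column is absent from `beta`, or individual entries are `NA`
#' (e.g. probes failing QC in some samples). Missing values are imputed
#' from the clock's training means when the coefficient file carries them,
#' otherwise from the cohort mean of that CpG; a fully absent CpG with no
#' training mean is an error, as is a clock with more than
#' `max_missing_frac` of its CpGs absent. The number of imputed CpGs is
#' reported per sample so that degradation is never silent.
#'
#' @param model a [clock_model()].
#' @param beta sample x CpG beta matrix with CpG IDs as column names.
#' @param max_missing_frac maximum tolerated fraction of absent clock CpGs.
#' @return an `age_prediction` data.frame with columns `sample`,
#'   `predicted_age` (years), `n_missing_cpgs`.
#' @export
predict_age <- function(model, beta, max_missing_frac = 0.2) {
  stopifnot(inherits(model, "clock_model"), is.matrix(beta))
  ids <- names(model$coefficients)
  absent <- setdiff(ids, colnames(beta))
  .stop_if(length(absent) == length(ids), "all clock CpGs missing from beta matrix")
  .stop_if(length(absent) / length(ids) > max_missing_frac,
           sprintf("%d of %d clock CpGs missing (> %.0f%% allowed)",
                   length(absent), length(ids), 100 * max_missing_frac))
  x <- if (model$transform == "zhang") zhang_standardize(beta) else beta
  n <- nrow(x)
  # assemble the sample x clock-CpG matrix, NA where unavailable
  xc <- matrix(NA_real_, n, length(ids),
               dimnames = list(rownames(x), ids))
  present <- intersect(ids, colnames(x))
  xc[, present] <- x[, present]
  n_missing <- rowSums(is.na(xc))
  if (any(is.na(xc))) {
    for (j in which(colSums(is.na(xc)) > 0)) {
      id <- ids[j]
      has_tm <- !is.null(model$training_means) &&
        id %in% names(model$training_means) &&
        !is.na(model$training_means[[id]])
      fill <- if (has_tm) {
        model$training_means[[id]]  # on the clock's input scale
      } else if (any(!is.na(xc[, j]))) {
        mean(xc[, j], na.rm = TRUE)  # cohort mean fallback
      } else {
        stop(paste0("clock CpG '", id, "' absent from beta and training means"),
             call. = FALSE)
      }
      xc[is.na(xc[, j]), j] <- fill
    }
  }
  score <- model$intercept + as.vector(xc %*% model$coefficients[ids])
  years <- switch(model$transform,
                  identity = score,
                  zhang = score,
                  horvath = horvath_inverse_transform(score, model$adult_age))
  out <- data.frame(sample = rownames(beta) %||% as.character(seq_len(n)),
                    predicted_age = years,
                    n_missing_cpgs = as.integer(n_missing),
                    stringsAsFactors = FALSE)
  attr(out, "clock") <- model$name
  class(out) <- c("age_prediction", "data.frame")
  out
}

#' Summarize prediction error against chronological age
#'
#' @param pred an `age_prediction` (or numeric vector of predicted ages).
#' @param age chronological ages in years, aligned with `pred`.
#' @return a `prediction_error_summary` list with `mae` (years), `pearson_r`,
#'   and the per-sample signed `error` (predicted - chronological).
#' @export
prediction_error_summary <- function(pred, age) {
  p <- if (inherits(pred, "age_prediction")) pred$predicted_age else pred
  .stop_if(length(p) != length(age), "prediction/age length mismatch")
  err <- p - age
  r <- NA_real_
  if (length(p) >= 3) {
    if (stats::sd(p) == 0 || stats::sd(age) == 0) {
      r <- NA_real_  # flagged: undefined for constant vectors
    } else r <- stats::cor(p, age)
  }
  structure(list(mae = mean(abs(err)), pearson_r = r, error = err,
                 clock = attr(pred, "clock") %||% "clock"),
            class = "prediction_error_summary")
}

#' @export
print.prediction_error_summary <- function(x, ...) {
  cat(sprintf("<prediction_error_summary> %s: MAE = %.3f y, r = %s, n = %d\n",
              x$clock, x$mae,
              if (is.na(x$pearson_r)) "NA (constant input)" else sprintf("%.3f", x$pearson_r),
              length(x$error)))
  invisible(x)
}

#' Pairwise concordance of prediction errors across clocks
#'
#' @param summaries named list of [prediction_error_summary()] objects with
#'   aligned samples.
#' @return symmetric Pearson correlation matrix of the error vectors.
#' @export
clock_concordance <- function(summaries) {
  .stop_if(length(summaries) < 2, "need >= 2 clocks")
  errs <- sapply(summaries, function(s) s$error)
  .stop_if(nrow(errs) < 3, "need >= 3 samples for correlations")
  m <- stats::cor(errs)
  diag(m) <- 1
  m
}

#' Directed overlap of extreme age-prediction deviations
#'
#' Entry (A, B) is the percentage of samples whose error under clock A is at
#' least `threshold` years that also exceed the threshold under clock B.
#' Rows with no extreme sample under A are returned as `NaN` (flagged, not
#' silently zero).
#'
#' @param errors_by_clock named list (or matrix columns) of signed
#'   per-sample errors, aligned across clocks.
#' @param threshold years (default 10).
#' @param direction `"high"` (error >= threshold), `"low"`
#'   (error <= -threshold) or `"abs"`.
#' @return square percentage matrix, clocks x clocks.
#' @export
extreme_deviation_overlap <- function(errors_by_clock, threshold = 10,
                                      direction = c("high", "low", "abs")) {
  direction <- match.arg(direction)
  .stop_if(threshold <= 0, "threshold must be positive")
  e <- sapply(errors_by_clock, identity)
  .stop_if(ncol(e) < 2, "need >= 2 clocks")
  flag <- switch(direction,
                 high = e >= threshold,
                 low  = e <= -threshold,
                 abs  = abs(e) >= threshold)
  k <- ncol(e)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(e), colnames(e)))
  for (a in seq_len(k)) {
    na <- sum(flag[, a])
    out[a, ] <- if (na == 0) NaN else 100 * colSums(flag[flag[, a], , drop = FALSE]) / na
  }
  out
}
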