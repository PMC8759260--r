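#' Replicate reliability: ICC(2,k), absolute agreement
#'
#' Shrout-Fleiss intraclass correlation for a two-way random-effects model,
#' absolute agreement, mean of k ratings (here k = 2 technical replicates).
#' Computed per CpG from the classical ANOVA decomposition:
#' `ICC(2,k) = (BMS - EMS) / (BMS + (JMS - EMS) / n)`, with BMS the
#' between-subject, JMS the between-rating and EMS the residual mean square.
#'
#' @param x either an n x k matrix (one CpG) or a 3-d array / list of such
#'   matrices; the convenience interface takes `first` and `second` matrices
#'   of aligned samples x CpGs holding the two replicate measurements.
#' @param first,second sample x CpG matrices of paired replicate
#'   measurements (same dimnames).
#' @return numeric vector of per-CpG ICC values.
#' @export
icc_absolute_agreement <- function(first, second) {
  stopifnot(is.matrix(first), is.matrix(second),
            all(dim(first) == dim(second)))
  .stop_if(nrow(first) < 2, "need >= 2 replicate pairs")
  .stop_if(anyNA(first) || anyNA(second), "incomplete replicate pair(s)")
  vapply(seq_len(ncol(first)), function(j) {
    .icc2k(cbind(first[, j], second[, j]))
  }, numeric(1)) |> stats::setNames(colnames(first))
}

# One CpG: ratings matrix n subjects x k raters.
.icc2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  jms <- ss_cols / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (jms - ems) / n)
}

#' Fit a PLS predictor of blood cell percentages from methylation
#'
#' Multivariate partial-least-squares (SIMPLS) regression of measured white
#' blood cell percentages on the methylation beta matrix plus age and sex,
#' mirroring the standard workflow for imputing cell counts in cohorts where
#' only a subset of samples has a differential. All predictors are centred
#' and scaled; the number of components is selected by 5-fold
#' cross-validation over `1..max_ncomp` (minimum mean RMSEP across
#' responses).
#'
#' @param beta sample x CpG matrix.
#' @param age numeric vector (years).
#' @param sex factor/character vector.
#' @param counts sample x cell-type matrix of measured percentages.
#' @param max_ncomp largest number of latent components tried (default 20).
#' @param ncomp fixed number of components; overrides cross-validation.
#' @param nfold folds for cross-validation.
#' @return a `cellcount_predictor` with a [predict()] method.
#' @export
fit_cellcount_predictor <- function(beta, age, sex, counts,
                                    max_ncomp = 20, ncomp = NULL, nfold = 5) {
  stopifnot(is.matrix(beta), is.matrix(counts), nrow(beta) == nrow(counts))
  .stop_if(anyNA(counts), "training samples must have complete measured counts")
  x <- cbind(beta, age = age, sex = as.numeric(factor(sex)))
  n <- nrow(x)
  cap <- min(max_ncomp, n - ceiling(n / nfold) - 2, ncol(x))
  .stop_if(!is.null(ncomp) && ncomp > n - 2, "fewer training samples than components")
  if (is.null(ncomp)) {
    .stop_if(cap < 1, "too few samples for cross-validated component selection")
    folds <- rep(seq_len(nfold), length.out = n)[sample.int(n)]
    press <- matrix(0, nfold, cap)
    for (f in seq_len(nfold)) {
      tr <- folds != f
      fit <- .simpls(x[tr, , drop = FALSE], counts[tr, , drop = FALSE], cap)
      for (a in seq_len(cap)) {
        pr <- .simpls_predict(fit, x[!tr, , drop = FALSE], a)
        press[f, a] <- mean((pr - counts[!tr, , drop = FALSE])^2)
      }
    }
    ncomp <- which.min(colMeans(press))
  }
  fit <- .simpls(x, counts, ncomp)
  structure(list(fit = fit, ncomp = ncomp, cpgs = colnames(beta),
                 responses = colnames(counts)),
            class = "cellcount_predictor")
}

#' @export
print.cellcount_predictor <- function(x, ...) {
  cat(sprintf("<cellcount_predictor> PLS, %d components, %d CpG features, responses: %s\n",
              x$ncomp, length(x$cpgs), paste(x$responses, collapse = ", ")))
  invisible(x)
}

#' @rdname fit_cellcount_predictor
#' @param object fitted predictor.
#' @param ... unused.
#' @export
predict.cellcount_predictor <- function(object, beta, age, sex, ...) {
  x <- cbind(beta[, object$cpgs, drop = FALSE],
             age = age, sex = as.numeric(factor(sex)))
  out <- .simpls_predict(object$fit, x, object$ncomp)
  out[out < 0] <- 0  # percentages cannot be negative
  colnames(out) <- object$responses
  rownames(out) <- rownames(beta)
  out
}

# SIMPLS (de Jong 1993) with centred+scaled X, centred Y.
.simpls <- function(x, y, ncomp) {
  xm <- colMeans(x); ym <- colMeans(y)
  xs <- apply(x, 2, stats::sd); xs[xs == 0] <- 1
  X <- sweep(sweep(x, 2, xm), 2, xs, "/")
  Y <- sweep(y, 2, ym)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  S <- crossprod(X, Y)
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- svd(S, nu = 1, nv = 0)$u
    t_sc <- X %*% r
    t_sc <- t_sc - mean(t_sc)
    tnorm <- sqrt(sum(t_sc^2))
    if (tnorm < 1e-12) { ncomp <- a - 1; break }
    t_sc <- t_sc / tnorm; r <- r / tnorm
    p_l <- crossprod(X, t_sc)
    q_l <- crossprod(Y, t_sc)
    v <- p_l
    if (a > 1) {
      Vs <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vs %*% crossprod(Vs, p_l)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- p_l; Q[, a] <- q_l; V[, a] <- v
  }
  list(R = R[, seq_len(ncomp), drop = FALSE],
       Q = Q[, seq_len(ncomp), drop = FALSE],
       xm = xm, xs = xs, ym = ym, ncomp_fit = ncomp)
}

.simpls_predict <- function(fit, x, ncomp) {
  a <- min(ncomp, fit$ncomp_fit)
  B <- fit$R[, seq_len(a), drop = FALSE] %*% t(fit$Q[, seq_len(a), drop = FALSE])
  X <- sweep(sweep(x, 2, fit$xm), 2, fit$xs, "/")
  sweep(X %*% B, 2, fit$ym, "+")
}
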