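#' @keywords internal
"_PACKAGE"

# Numbers are written with 17 significant digits so that every matrix and
# table written by the package round-trips through its reader bit-exactly.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a numeric matrix as TSV (rows labelled in the first column)
#'
#' Values are serialized with enough digits to round-trip exactly through
#' [read_matrix_tsv()].
#'
#' @param x numeric matrix with row and column names.
#' @param path output file path.
#' @param row_label header for the row-name column (e.g. `"sample"`).
#' @export
write_matrix_tsv <- function(x, path, row_label = "sample") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(row_label, colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], .fmt_num(x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param path file path.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Derive a reproducible stage seed from a global seed
#'
#' Hashes the stage name into the global seed so pipeline stages draw from
#' independent but reproducible streams. The result is always a valid
#' 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 17) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted cluster structure; 1 means identical
#' partitions up to label permutation, 0 is chance agreement.
#'
#' @param a,b label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# t statistic -> z score preserving sign, numerically stable in the tails.
.t_to_z <- function(t, df) {
  lp <- stats::pt(-abs(t), df = df, log.p = TRUE)
  z <- -stats::qnorm(lp, log.p = TRUE)
  sign(t) * z
}

.stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
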