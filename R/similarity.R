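#' Pairwise CpG overlap between clocks
#'
#' Counts CpGs shared by each clock pair; the diagonal holds clock sizes.
#' The companion percentage matrix expresses each shared count relative to
#' the smaller clock of the pair, the convention used when visualizing
#' clock redundancy.
#'
#' @param clocks named list of [clock_model()] objects (>= 2).
#' @return an `overlap_matrix` list with integer `counts` and numeric
#'   `percent` matrices.
#' @export
cpg_overlap_matrix <- function(clocks) {
  .stop_if(length(clocks) < 2, "need >= 2 clocks")
  sets <- lapply(clocks, function(cl) names(cl$coefficients))
  nms <- names(clocks) %||% paste0("clock", seq_along(clocks))
  k <- length(sets)
  counts <- matrix(0L, k, k, dimnames = list(nms, nms))
  pct <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    counts[i, j] <- shared
    pct[i, j] <- 100 * shared / min(length(sets[[i]]), length(sets[[j]]))
  }
  structure(list(counts = counts, percent = pct,
                 sizes = vapply(sets, length, integer(1))),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> shared CpG counts (diagonal = clock size):\n")
  print(x$counts)
  invisible(x)
}

#' Fraction of clock CpGs with a correlated proxy
#'
#' For each reference CpG set and threshold, the percentage of the clock's
#' CpGs whose methylation has at least one proxy at `|r| >=` the threshold
#' among the reference set. In between-clock mode a CpG shared by both
#' clocks counts as a proxy with r = 1; in within-clock mode (reference set
#' equal to the clock itself, passed as `within = TRUE` entries or by name)
#' the self-correlation is excluded.
#'
#' @param clock a [clock_model()].
#' @param reference_sets named list of character vectors of CpG IDs; name an
#'   entry `"within"` (or pass the clock's own CpGs) to get the
#'   internal-redundancy mode.
#' @param beta sample x CpG matrix covering the CpGs (missing CpGs are
#'   dropped with a warning).
#' @param thresholds absolute-correlation thresholds.
#' @return a `proxy_summary` matrix, reference sets x thresholds, in
#'   percent.
#' @export
proxy_fraction <- function(clock, reference_sets, beta,
                           thresholds = c(0.5, 0.7, 0.9)) {
  .stop_if(nrow(beta) < 3, "need >= 3 samples for correlations")
  own <- names(clock$coefficients)
  avail <- intersect(own, colnames(beta))
  if (length(avail) < length(own)) {
    warning(sprintf("%d clock CpGs missing from beta matrix; dropped",
                    length(own) - length(avail)))
  }
  out <- matrix(NA_real_, length(reference_sets), length(thresholds),
                dimnames = list(names(reference_sets),
                                paste0("r", thresholds)))
  for (i in seq_along(reference_sets)) {
    ref <- reference_sets[[i]]
    within <- setequal(ref, own)
    ref_avail <- intersect(ref, colnames(beta))
    cm <- abs(stats::cor(beta[, avail, drop = FALSE],
                         beta[, ref_avail, drop = FALSE]))
    if (within) {
      # exclude each CpG's correlation with itself
      for (cg in intersect(avail, ref_avail)) cm[cg, cg] <- NA
    }
    best <- apply(cm, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    if (!within) {
      # a CpG present in both clocks is a perfect proxy by convention
      best[intersect(avail, ref)] <- 1
    }
    for (t in seq_along(thresholds)) {
      out[i, t] <- 100 * mean(best >= thresholds[t], na.rm = TRUE)
    }
  }
  class(out) <- c("proxy_summary", class(out))
  out
}

#' Read a BED track into GRanges
#'
#' Thin wrapper over [rtracklayer::import()]; BED intervals (0-based,
#' half-open) are converted to 1-based closed coordinates at this boundary
#' and nowhere else.
#'
#' @param path BED3/BED4 file.
#' @export
read_bed_track <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  .stop_if(any(GenomicRanges::width(gr) < 1), "malformed interval (start >= end)")
  gr
}

#' Annotate CpGs with CGI class, peak membership and chromatin state
#'
#' CpGs are 1-based points. A CpG inside a CpG island is class `"CGI"`;
#' within 2 kb of an island edge but outside it, `"shore"`; otherwise
#' `"non-CGI"` - the three classes are mutually exclusive and exhaustive.
#' Peak tracks give one logical column each; a chromatin-state track (BED4,
#' mutually exclusive labelled segments) gives a `state` column.
#'
#' @param cpg_coords data.frame with columns `cpg`, `chrom`, `pos`
#'   (1-based).
#' @param cgi_intervals GRanges of CpG islands.
#' @param peak_tracks named list of GRanges (may be empty).
#' @param state_track optional GRanges with a `name` column of state labels.
#' @param shore_width flank width in bp (default 2000).
#' @return data.frame, one row per CpG: `cpg`, `cgi_class`, one logical
#'   column per peak track, and `state` when a state track is given.
#' @export
annotate_cpgs <- function(cpg_coords, cgi_intervals, peak_tracks = list(),
                          state_track = NULL, shore_width = 2000) {
  stopifnot(all(c("cpg", "chrom", "pos") %in% names(cpg_coords)))
  pts <- GenomicRanges::GRanges(cpg_coords$chrom,
                                IRanges::IRanges(cpg_coords$pos, width = 1))
  in_cgi <- IRanges::overlapsAny(pts, cgi_intervals)
  shores <- c(GenomicRanges::flank(cgi_intervals, shore_width, start = TRUE),
              GenomicRanges::flank(cgi_intervals, shore_width, start = FALSE))
  shores <- GenomicRanges::trim(shores)
  in_shore <- IRanges::overlapsAny(pts, shores) & !in_cgi
  out <- data.frame(cpg = cpg_coords$cpg,
                    cgi_class = ifelse(in_cgi, "CGI",
                                       ifelse(in_shore, "shore", "non-CGI")),
                    stringsAsFactors = FALSE)
  for (nm in names(peak_tracks)) {
    out[[nm]] <- IRanges::overlapsAny(pts, peak_tracks[[nm]])
  }
  if (!is.null(state_track)) {
    hit <- GenomicRanges::findOverlaps(pts, state_track, select = "first")
    out$state <- ifelse(is.na(hit), NA_character_,
                        as.character(state_track$name[hit]))
  }
  out
}

#' Enrichment of clock CpGs in genomic features
#'
#' For every feature (the three CGI classes one-vs-rest, each peak track,
#' and each chromatin state one-vs-rest) a 2x2 table of clock versus
#' background CpGs is tested with Fisher's exact test (two-sided). The odds
#' ratio is computed from the table, with a Haldane-Anscombe 0.5 correction
#' (flagged) when any cell is zero; the p value stays exact. Bonferroni
#' correction uses `m` independent features (default 9: 3 CGI classes + 6
#' histone marks; chromatin states are derived from the marks and share the
#' family).
#'
#' @param clock_cpg_ids,background_cpg_ids character vectors; clock CpGs
#'   are removed from the background before testing.
#' @param annotation output of [annotate_cpgs()] covering both sets.
#' @param m Bonferroni family size (default 9).
#' @return data.frame with `feature`, `odds_ratio`, `p`, `p_bonf`,
#'   `haldane` (logical), `degenerate` (feature annotating nothing or
#'   everything; excluded from the family).
#' @export
feature_enrichment <- function(clock_cpg_ids, background_cpg_ids, annotation,
                               m = 9) {
  background_cpg_ids <- setdiff(background_cpg_ids, clock_cpg_ids)
  .stop_if(length(clock_cpg_ids) == 0 || length(background_cpg_ids) == 0,
           "empty clock or background set")
  ann <- annotation[match(c(clock_cpg_ids, background_cpg_ids), annotation$cpg), ]
  is_clock <- c(rep(TRUE, length(clock_cpg_ids)),
                rep(FALSE, length(background_cpg_ids)))
  feats <- list()
  for (cls in c("CGI", "shore", "non-CGI")) {
    feats[[cls]] <- ann$cgi_class == cls
  }
  for (nm in setdiff(names(ann), c("cpg", "cgi_class", "state"))) {
    feats[[nm]] <- ann[[nm]]
  }
  if ("state" %in% names(ann)) {
    for (st in sort(unique(stats::na.omit(ann$state)))) {
      feats[[paste0("state:", st)]] <- !is.na(ann$state) & ann$state == st
    }
  }
  rows <- lapply(names(feats), function(nm) {
    f <- feats[[nm]]
    a <- sum(is_clock & f);  b <- sum(is_clock & !f)
    c_ <- sum(!is_clock & f); d <- sum(!is_clock & !f)
    degenerate <- (a + c_ == 0) || (b + d == 0)
    if (degenerate) {
      return(data.frame(feature = nm, odds_ratio = NA_real_, p = NA_real_,
                        p_bonf = NA_real_, haldane = FALSE, degenerate = TRUE))
    }
    haldane <- any(c(a, b, c_, d) == 0)
    or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)) else (a * d) / (b * c_)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(feature = nm, odds_ratio = or, p = p,
               p_bonf = min(1, m * p), haldane = haldane, degenerate = FALSE)
  })
  do.call(rbind, rows)
}
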