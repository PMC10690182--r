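#' Per-category element counts across replicates
#'
#' Counts detected elements of one kind per six-way category in every
#' replicate's graph set and aggregates as mean ± standard error of the
#' mean (SEM = sample SD / sqrt(n); 0 with a single replicate).
#'
#' @param replicate_graphs List of replicates; each replicate is a list of
#'   \code{splice_graph}s (one per gene).
#' @param kind \code{"junction"} or \code{"retained_intron"}.
#' @return Data frame (category, and per-replicate counts, mean, sem).
#' @export
category_counts <- function(replicate_graphs, kind = c("junction", "retained_intron")) {
  kind <- match.arg(kind)
  per_rep <- vapply(replicate_graphs, function(graphs) {
    cats <- unlist(lapply(graphs, function(g) {
      e <- g$edges[g$edges$kind == kind, , drop = FALSE]
      cat6 <- six_category(e)
      cat6[cat6 != "NOT_DETECTED"]
    }))
    .category_table(cats)
  }, integer(length(SIX_CATEGORIES)))
  per_rep <- matrix(per_rep, nrow = length(SIX_CATEGORIES),
                    dimnames = list(SIX_CATEGORIES, NULL))
  n <- ncol(per_rep)
  mean_ <- rowMeans(per_rep)
  sem <- if (n > 1) apply(per_rep, 1, stats::sd) / sqrt(n) else rep(0, nrow(per_rep))
  out <- data.frame(category = SIX_CATEGORIES, mean = mean_, sem = sem,
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) out[[sprintf("rep%d", r)]] <- per_rep[, r]
  rownames(out) <- NULL
  out
}

#' Long-read detection of short-read junctions as a function of PSI
#'
#' Bins short-read-supported junctions by their (minimum) short-read PSI
#' and reports, per bin, the fraction also detected by long reads, plus
#' the cumulative distributions and the missed fraction above a PSI
#' threshold (conventionally 0.2).
#'
#' @param psi Numeric vector of per-junction minimum PSI values (NA =
#'   junction in no quantifiable LSV; excluded).
#' @param long_detected Logical vector, same length: junction also
#'   detected by long reads.
#' @param bin_width Histogram bin width over [0, 1] (default 0.05).
#' @param threshold PSI threshold for the missed fraction (default 0.2).
#' @return List with \code{table} (bin_lo, bin_hi, n_short,
#'   n_long_detected, fraction_detected), \code{cdf} (psi grid, cumulative
#'   fractions of all and of long-detected junctions) and
#'   \code{missed_fraction}: fraction of junctions with PSI >= threshold
#'   not detected by long reads.
#' @export
detection_vs_psi <- function(psi, long_detected, bin_width = 0.05,
                             threshold = 0.2) {
  keep <- !is.na(psi)
  psi <- psi[keep]; long_detected <- long_detected[keep]
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- cut(psi, breaks, include.lowest = TRUE, right = FALSE)
  n_short <- as.integer(table(bin))
  n_long <- as.integer(tapply(long_detected, bin, sum, default = 0))
  tab <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    n_short = n_short, n_long_detected = n_long,
                    fraction_detected = ifelse(n_short > 0, n_long / n_short, NA),
                    stringsAsFactors = FALSE)
  ord <- order(psi, method = "radix")
  cdf <- data.frame(psi = psi[ord],
                    cdf_all = seq_along(psi) / length(psi),
                    stringsAsFactors = FALSE)
  missed <- if (any(psi >= threshold)) mean(!long_detected[psi >= threshold]) else NA_real_
  list(table = tab, cdf = cdf, threshold = threshold, missed_fraction = missed)
}

#' Long-read detection of short-read junctions by coverage bin
#'
#' @param counts Short-read unique counts of short-supported junctions.
#' @param long_detected Logical: also detected by long reads.
#' @param breaks Coverage bin edges (default \code{c(0, 10, 20, 50, 100,
#'   Inf)}).
#' @return List with \code{table} (per coverage bin the detected fraction;
#'   bins with no junctions reported as NA) and overall
#'   \code{fraction_detected}.
#' @export
detection_vs_coverage <- function(counts, long_detected,
                                  breaks = c(0, 10, 20, 50, 100, Inf)) {
  bin <- cut(counts, breaks, right = FALSE)
  n <- as.integer(table(bin))
  nd <- as.integer(tapply(long_detected, bin, sum, default = 0))
  tab <- data.frame(bin = levels(bin), n_short = n, n_long_detected = nd,
                    fraction_detected = ifelse(n > 0, nd / n, NA),
                    stringsAsFactors = FALSE)
  list(table = tab,
       fraction_detected = if (length(counts)) mean(long_detected) else NA_real_)
}

#' Fraction of short-quantifiable LSVs non-quantifiable by long reads
#'
#' Among LSVs quantifiable from short reads, the fraction failing the
#' long-read quantifiability filter, binned either by short-read coverage
#' or by spliced distance from the transcript 3' end.
#'
#' @param lsv_table Data frame from \code{\link{quantify_lsvs}} (pooled
#'   over genes).
#' @param axis \code{"coverage"} or \code{"distance3p"}.
#' @param breaks Bin edges; defaults \code{c(10, 20, 50, 100, Inf)} for
#'   coverage and \code{c(0, 500, 1000, 2500, Inf)} for distance.
#' @return Data frame (bin, n, n_nonquantifiable, fraction).
#' @export
nonquantifiable_fractions <- function(lsv_table,
                                      axis = c("coverage", "distance3p"),
                                      breaks = NULL) {
  axis <- match.arg(axis)
  keep <- lsv_table$short_quantifiable
  if (axis == "coverage") {
    if (is.null(breaks)) breaks <- c(10, 20, 50, 100, Inf)
    x <- lsv_table$short_total[keep]
  } else {
    if (is.null(breaks)) breaks <- c(0, 500, 1000, 2500, Inf)
    x <- lsv_table$dist3p[keep]
  }
  nq <- !lsv_table$long_quantifiable[keep]
  ok <- !is.na(x)
  x <- x[ok]; nq <- nq[ok]
  bin <- cut(x, breaks, right = FALSE)
  n <- as.integer(table(bin))
  nn <- as.integer(tapply(nq, bin, sum, default = 0))
  data.frame(bin = levels(bin), n = n, n_nonquantifiable = nn,
             fraction = ifelse(n > 0, nn / n, NA), stringsAsFactors = FALSE)
}

#' Retained-intron comparison: categories, lengths, detection
#'
#' Tabulates detected retained-intron events by six-way category, gives a
#' five-number length summary per category (median, quartiles, whiskers at
#' 1.5 IQR), and bins long-read IR events by PSI and by long-read count
#' with the fraction also detected by short reads per bin.
#'
#' @param graphs List of \code{splice_graph}s.
#' @param lsvs_by_gene Optional named list (gene_id -> list of lsvs); when
#'   given, long-read IR PSI values use \code{\link{ir_psi}} with
#'   \code{min_reads}.
#' @param min_reads PSI filter for IR PSI binning (default 10).
#' @param psi_breaks,count_breaks Bin edges for the detection tables.
#' @return List with \code{categories}, \code{lengths},
#'   \code{detection_by_psi}, \code{detection_by_count} data frames.
#' @export
ir_comparison <- function(graphs, lsvs_by_gene = NULL, min_reads = 10,
                          psi_breaks = seq(0, 1, 0.2),
                          count_breaks = c(1, 5, 10, 50, Inf)) {
  rows <- list()
  for (g in graphs) {
    e <- g$edges
    iri <- which(e$kind == "retained_intron" & (e$short | e$long))
    if (length(iri) == 0) next
    cat6 <- six_category(e[iri, , drop = FALSE])
    psi_long <- rep(NA_real_, length(iri))
    if (!is.null(lsvs_by_gene) && g$gene_id %in% names(lsvs_by_gene)) {
      lsvs <- lsvs_by_gene[[g$gene_id]]
      psi_long <- vapply(iri, function(i)
        ir_psi(i, lsvs, "long", min_reads), numeric(1))
    }
    rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, start = e$start[iri], end = e$end[iri],
      length = e$end[iri] - e$start[iri] + 1L,
      category = cat6, short = e$short[iri], long = e$long[iri],
      long_count = e$long_count[iri], psi_long = psi_long,
      stringsAsFactors = FALSE)
  }
  ir <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), start = integer(), end = integer(),
               length = integer(), category = character(), short = logical(),
               long = logical(), long_count = numeric(), psi_long = numeric(),
               stringsAsFactors = FALSE)
  rownames(ir) <- NULL
  categories <- data.frame(category = SIX_CATEGORIES,
                           count = as.integer(.category_table(ir$category)),
                           stringsAsFactors = FALSE)
  lengths <- do.call(rbind, lapply(SIX_CATEGORIES, function(cc) {
    x <- ir$length[ir$category == cc]
    if (length(x) == 0)
      return(data.frame(category = cc, n = 0L, median = NA, q1 = NA, q3 = NA,
                        whisker_lo = NA, whisker_hi = NA, stringsAsFactors = FALSE))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr]); hi <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(category = cc, n = length(x), median = q[2], q1 = q[1],
               q3 = q[3], whisker_lo = lo, whisker_hi = hi,
               stringsAsFactors = FALSE)
  }))
  longir <- ir[ir$long, , drop = FALSE]
  det_psi <- {
    keep <- !is.na(longir$psi_long)
    bin <- cut(longir$psi_long[keep], psi_breaks, include.lowest = TRUE, right = FALSE)
    n <- as.integer(table(bin))
    nd <- as.integer(tapply(longir$short[keep], bin, sum, default = 0))
    data.frame(bin = levels(bin), n_long = n, n_short_detected = nd,
               fraction = ifelse(n > 0, nd / n, NA), stringsAsFactors = FALSE)
  }
  det_cnt <- {
    bin <- cut(longir$long_count, count_breaks, right = FALSE)
    n <- as.integer(table(bin))
    nd <- as.integer(tapply(longir$short, bin, sum, default = 0))
    data.frame(bin = levels(bin), n_long = n, n_short_detected = nd,
               fraction = ifelse(n > 0, nd / n, NA), stringsAsFactors = FALSE)
  }
  list(events = ir, categories = categories, lengths = lengths,
       detection_by_psi = det_psi, detection_by_count = det_cnt)
}

#' Empirical read-length distribution and threshold fractions
#'
#' @param lengths Numeric read lengths (nt).
#' @param thresholds Lengths of interest; default 3000 nt, roughly the
#'   median length of human transcripts.
#' @return List with \code{cdf} (sorted lengths, cumulative fraction) and
#'   \code{fractions}: per threshold, the fraction of reads at least that
#'   long.
#' @export
read_length_distribution <- function(lengths, thresholds = 3000) {
  stopifnot(length(lengths) > 0)
  ord <- sort(lengths, method = "radix")
  cdf <- data.frame(length = ord, cdf = seq_along(ord) / length(ord))
  fr <- vapply(thresholds, function(t) mean(lengths >= t), numeric(1))
  list(cdf = cdf,
       fractions = data.frame(threshold = thresholds, fraction_ge = fr,
                              stringsAsFactors = FALSE))
}

#' Average a numeric column of per-replicate tables sharing key columns
#'
#' Replicates are processed independently; aggregation happens only at the
#' level of the reported statistic.
#'
#' @param tables List of data frames with identical key columns.
#' @param value_cols Numeric columns to average.
#' @return One data frame with per-column means across replicates.
#' @export
average_tables <- function(tables, value_cols) {
  out <- tables[[1]]
  for (cc in value_cols) {
    m <- vapply(tables, function(t) as.numeric(t[[cc]]), numeric(nrow(out)))
    m <- matrix(m, nrow = nrow(out))
    out[[cc]] <- rowMeans(m, na.rm = TRUE)
  }
  out
}
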