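#' Define local splicing variations (LSVs) on a splice graph
#'
#' An LSV is a split in the splice graph at a reference exon: a source LSV
#' when two or more detected edges leave the exon's 3' side (strand-aware),
#' a target LSV when two or more detected edges enter its 5' side.
#' Retained-intron edges adjacent to the exon participate as elements.
#' Edges supported by annotation alone (NOT_DETECTED) are excluded. An
#' edge is attached to a merged exon when its exon-proximal boundary lies
#' within that exon, so alternative 5'/3' splice sites internal to a merged
#' exon join the same LSV.
#'
#' @param graph A \code{splice_graph}.
#' @return List of \code{lsv} objects; each holds \code{lsv_id},
#'   \code{gene_id}, \code{ref_exon} (start/end), \code{direction}
#'   (\code{"source"}/\code{"target"}), \code{edge_idx} (row indices into
#'   \code{graph$edges}, coordinate-ordered), \code{J}, and per-source
#'   count vectors \code{r_short}, \code{r_long}.
#' @export
define_lsvs <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) return(list())
  detected <- which(e$short | e$long)
  if (length(detected) < 2) return(list())
  out <- list()
  for (x in seq_len(nrow(graph$exons))) {
    E1 <- graph$exons[x, 1]; E2 <- graph$exons[x, 2]
    leave_right <- detected[e$start[detected] - 1L >= E1 &
                            e$start[detected] - 1L <= E2 &
                            e$end[detected] > E2]
    enter_left <- detected[e$end[detected] + 1L >= E1 &
                           e$end[detected] + 1L <= E2 &
                           e$start[detected] < E1]
    if (graph$strand == "+") {
      src <- leave_right; tgt <- enter_left
    } else {
      src <- enter_left; tgt <- leave_right
    }
    for (dir in c("source", "target")) {
      idx <- if (dir == "source") src else tgt
      if (length(idx) < 2) next
      idx <- idx[order(e$start[idx], e$end[idx], e$kind[idx], method = "radix")]
      lsv <- structure(list(
        lsv_id = sprintf("%s:%d-%d:%s", graph$gene_id, E1, E2,
                         if (dir == "source") "s" else "t"),
        gene_id = graph$gene_id,
        ref_exon = c(start = unname(E1), end = unname(E2)),
        direction = dir,
        edge_idx = idx,
        J = length(idx),
        r_short = e$short_count[idx],
        r_long = e$long_count[idx]
      ), class = "lsv")
      out[[lsv$lsv_id]] <- lsv
    }
  }
  out
}

#' @export
print.lsv <- function(x, ...) {
  cat(sprintf("lsv %s: %s LSV at exon [%d,%d], J = %d\n", x$lsv_id,
              x$direction, x$ref_exon[["start"]], x$ref_exon[["end"]], x$J))
  invisible(x)
}

#' Conjugate beta-binomial PSI posterior for one LSV
#'
#' Reads supporting element j of an LSV with J elements are modelled as
#' binomial draws with inclusion probability PSI_j. The prior on PSI_j is
#' Beta(1/J, 1 - 1/J), the J-way generalisation of the Jeffreys-type prior
#' favouring extreme inclusion values; being conjugate, the posterior is
#'
#'   PSI_j | r ~ Beta(1/J + r_j, 1 - 1/J + sum_{j' != j} r_{j'}),
#'
#' with posterior mean (1/J + r_j) / (1 + sum r), so the means sum to 1 in
#' closed form. With r = 0 the prior (mean 1/J) is returned.
#'
#' @param r Non-negative numeric vector of per-element read counts
#'   (length J >= 2).
#' @return A \code{psi_posterior}: data frame with columns \code{alpha},
#'   \code{beta}, \code{mean}, one row per element.
#' @examples
#' psi_posterior(c(7, 3))   # element 1: Beta(7.5, 3.5), mean 7.5/11
#' @export
psi_posterior <- function(r) {
  J <- length(r)
  if (J < 2) stop("an LSV needs J >= 2 elements")
  if (any(r < 0)) stop("negative read counts")
  alpha <- 1 / J + r
  beta <- 1 - 1 / J + (sum(r) - r)
  structure(data.frame(alpha = alpha, beta = beta,
                       mean = alpha / (alpha + beta)),
            class = c("psi_posterior", "data.frame"))
}

#' @export
print.psi_posterior <- function(x, ...) {
  cat(sprintf("psi_posterior: J = %d, E[PSI] = %s\n", nrow(x),
              paste(sprintf("%.4f", x$mean), collapse = ", ")))
  invisible(x)
}

#' Per-element PSI posterior of an LSV for one evidence source
#'
#' Applies the same conjugate beta-binomial machinery to the chosen
#' source's counts: long-read counts are per-element sums of the read
#' counts of transcripts containing the element; short-read counts are
#' unique junction-spanning reads. The point estimate is the posterior
#' mean; with zero total reads the prior means (1/J each) are returned.
#'
#' @param lsv An \code{lsv}.
#' @param source \code{"short"} or \code{"long"}.
#' @return A \code{psi_posterior}.
#' @export
lsv_psi <- function(lsv, source = c("short", "long")) {
  source <- match.arg(source)
  r <- if (source == "short") lsv$r_short else lsv$r_long
  psi_posterior(r)
}

#' Is an LSV quantifiable for a source?
#'
#' TRUE when the source's reads over the LSV's elements total at least
#' \code{min_reads} (default 10, the standard LSV quantifiability filter).
#'
#' @param lsv An \code{lsv}.
#' @param source \code{"short"} or \code{"long"}.
#' @param min_reads Threshold (default 10).
#' @return Logical flag.
#' @export
is_quantifiable <- function(lsv, source = c("short", "long"), min_reads = 10) {
  source <- match.arg(source)
  r <- if (source == "short") lsv$r_short else lsv$r_long
  sum(r) >= min_reads
}

#' Minimum PSI of a junction across its quantifiable LSVs
#'
#' A junction can belong to both a source and a target LSV; when it is
#' quantified in several, the lowest posterior-mean PSI is reported. If no
#' containing LSV is quantifiable for the source, \code{NA} is returned
#' (the junction is excluded from PSI-based summaries).
#'
#' @param edge_index Row index of the junction in the graph's edge table.
#' @param lsvs List of \code{lsv}s from \code{\link{define_lsvs}}.
#' @param source \code{"short"} or \code{"long"}.
#' @param min_reads Quantifiability threshold (default 10).
#' @return Numeric PSI in [0, 1], or \code{NA}.
#' @export
junction_min_psi <- function(edge_index, lsvs, source = c("short", "long"),
                             min_reads = 10) {
  source <- match.arg(source)
  best <- NA_real_
  for (lsv in lsvs) {
    pos <- match(edge_index, lsv$edge_idx)
    if (is.na(pos)) next
    if (!is_quantifiable(lsv, source, min_reads)) next
    m <- lsv_psi(lsv, source)$mean[pos]
    if (is.na(best) || m < best) best <- m
  }
  best
}

#' Spliced distance from an LSV's reference boundary to the transcript 3' end
#'
#' For every annotation transcript whose exons contain the LSV-side
#' boundary of the reference exon, the exonic (spliced) distance from that
#' boundary to the transcript's TES is the number of exonic bases strictly
#' 3' of the boundary. The minimum over containing transcripts is returned
#' — a conservative estimate when transcripts have multiple 3' ends.
#'
#' @param lsv An \code{lsv}.
#' @param graph The \code{splice_graph} the LSV came from (for strand).
#' @param annotation The \code{annotation_set}.
#' @return Distance in nt, or \code{NA} when no annotated transcript
#'   contains the boundary.
#' @export
distance_to_3prime <- function(lsv, graph, annotation) {
  strand <- graph$strand
  # boundary on the side of the exon the LSV's edges attach to
  b <- if ((lsv$direction == "source") == (strand == "+"))
    lsv$ref_exon[["end"]] else lsv$ref_exon[["start"]]
  tids <- annotation$tx$transcript_id[annotation$tx$gene_id == lsv$gene_id]
  best <- NA_real_
  for (tid in tids) {
    exo <- annotation$exons[[tid]]
    if (!any(exo[, 1] <= b & b <= exo[, 2])) next
    if (strand == "+") {
      d <- sum(pmax(0L, exo[, 2] - pmax(exo[, 1], b + 1L) + 1L))
    } else {
      d <- sum(pmax(0L, pmin(exo[, 2], b - 1L) - exo[, 1] + 1L))
    }
    if (is.na(best) || d < best) best <- d
  }
  best
}

#' PSI of a retained intron with the lowest-PSI / minimum-reads rules
#'
#' Reports the lowest posterior-mean PSI of the intron across the LSVs it
#' participates in, considering only LSVs whose total reads for the source
#' reach \code{min_reads}; returns \code{NA} (excluded) when none qualify.
#'
#' @param edge_index Row index of the retained-intron edge.
#' @param lsvs List of \code{lsv}s.
#' @param source \code{"short"} or \code{"long"}.
#' @param min_reads Threshold (default 10).
#' @return Numeric PSI or \code{NA}.
#' @export
ir_psi <- function(edge_index, lsvs, source = c("short", "long"),
                   min_reads = 10) {
  junction_min_psi(edge_index, lsvs, source, min_reads)
}

#' Per-LSV quantification table
#'
#' One row per LSV: per-source total counts, quantifiability flags,
#' posterior means (as comma-joined strings aligned with the LSV's
#' coordinate-ordered elements), and spliced distance to the 3' end.
#'
#' @param graph A \code{splice_graph}.
#' @param lsvs List of \code{lsv}s (default: computed from the graph).
#' @param annotation The \code{annotation_set} (for 3'-distances).
#' @param min_reads Quantifiability threshold.
#' @return Data frame.
#' @export
quantify_lsvs <- function(graph, lsvs = define_lsvs(graph), annotation,
                          min_reads = 10) {
  rows <- lapply(lsvs, function(lsv) {
    ps <- lsv_psi(lsv, "short")$mean
    pl <- lsv_psi(lsv, "long")$mean
    data.frame(
      gene_id = lsv$gene_id, lsv_id = lsv$lsv_id,
      ref_start = lsv$ref_exon[["start"]], ref_end = lsv$ref_exon[["end"]],
      direction = lsv$direction, J = lsv$J,
      short_total = sum(lsv$r_short), long_total = sum(lsv$r_long),
      short_quantifiable = is_quantifiable(lsv, "short", min_reads),
      long_quantifiable = is_quantifiable(lsv, "long", min_reads),
      short_counts = paste(lsv$r_short, collapse = ","),
      long_counts = paste(format(lsv$r_long, trim = TRUE, scientific = FALSE),
                          collapse = ","),
      psi_short = paste(sprintf("%.6f", ps), collapse = ","),
      psi_long = paste(sprintf("%.6f", pl), collapse = ","),
      dist3p = distance_to_3prime(lsv, graph, annotation),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), lsv_id = character(),
                      ref_start = integer(), ref_end = integer(),
                      direction = character(), J = integer(),
                      short_total = numeric(), long_total = numeric(),
                      short_quantifiable = logical(),
                      long_quantifiable = logical(),
                      short_counts = character(), long_counts = character(),
                      psi_short = character(), psi_long = character(),
                      dist3p = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export full Beta posteriors of an LSV as JSON (violin-plot data)
#'
#' @param lsv An \code{lsv}.
#' @param path Optional output path.
#' @return JSON string or path invisibly.
#' @export
lsv_posterior_json <- function(lsv, path = NULL) {
  doc <- list(lsv_id = lsv$lsv_id, gene_id = lsv$gene_id,
              direction = lsv$direction, J = lsv$J,
              short = as.list(psi_posterior(lsv$r_short)),
              long = as.list(psi_posterior(lsv$r_long)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
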