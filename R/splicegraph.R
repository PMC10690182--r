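#' Intron intervals of a transcript exon chain
#'
#' One interval per consecutive exon pair:
#' \code{[exon_i_end + 1, exon_{i+1}_start - 1]} (1-based inclusive).
#' A single-exon chain has no junctions.
#'
#' @param exons Two-column start/end matrix, coordinate-sorted, or a
#'   \code{transcript_set} exon entry.
#' @return Integer matrix with columns \code{start}, \code{end}; zero rows
#'   for a single-exon transcript.
#' @examples
#' junctions_of(cbind(start = c(101, 301), end = c(200, 400)))  # [201, 300]
#' @export
junctions_of <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = as.integer(exons[-n, 2] + 1L),
        end = as.integer(exons[-1, 1] - 1L))
}

#' Assign long-read transcripts to annotated genes by exonic overlap
#'
#' Replaces the caller-provided gene_id of every long-read transcript with
#' the annotated gene sharing the most exonic bases on the same chromosome
#' and strand; ties are broken toward the lexicographically smaller gene_id.
#' Transcripts overlapping no annotated gene keep their own gene_id and are
#' reported with a warning (they form long-read-only genes).
#'
#' @param long_ts A \code{transcript_set} of long-read transcripts.
#' @param annotation An \code{annotation_set}.
#' @return The \code{transcript_set} with reassigned \code{gene_id}s.
#' @export
assign_long_read_genes <- function(long_ts, annotation) {
  if (nrow(long_ts$tx) == 0) return(long_ts)
  gids <- annotation$genes$gene_id
  gene_exons <- lapply(gids, function(g) annotation$index[[g]]$exons)
  unassigned <- 0L
  for (i in seq_len(nrow(long_ts$tx))) {
    exo <- long_ts$exons[[long_ts$tx$transcript_id[i]]]
    ir_tx <- IRanges::IRanges(exo[, 1], exo[, 2])
    best <- NA_character_; best_ov <- 0L
    cand <- which(annotation$genes$chrom == long_ts$tx$chrom[i] &
                  annotation$genes$strand == long_ts$tx$strand[i] &
                  annotation$genes$start <= max(exo[, 2]) &
                  annotation$genes$end >= min(exo[, 1]))
    for (g in cand) {
      ge <- gene_exons[[g]]
      ov <- sum(IRanges::width(IRanges::intersect(
        IRanges::reduce(ir_tx), IRanges::reduce(IRanges::IRanges(ge[, 1], ge[, 2])))))
      if (ov > best_ov || (ov == best_ov && ov > 0 &&
                           !is.na(best) && gids[g] < best)) {
        best <- gids[g]; best_ov <- ov
      }
    }
    if (!is.na(best)) long_ts$tx$gene_id[i] <- best else unassigned <- unassigned + 1L
  }
  if (unassigned > 0)
    warning(sprintf("%d long-read transcript(s) overlap no annotated gene; kept under their own gene_id", unassigned))
  long_ts
}

.empty_edge_df <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             ann = logical(), short = logical(), long = logical(),
             short_count = integer(), long_count = numeric(),
             stringsAsFactors = FALSE)
}

#' Build a unified per-gene splice graph
#'
#' Merges three evidence sources into one graph: annotated junctions from
#' the reference annotation, short-read junctions (supporting an edge only
#' when their unique-read count reaches \code{short_min_reads}), and
#' junctions contained in surviving long-read transcripts (long-read count
#' of an edge = sum of the read counts of the transcripts containing it).
#' Retained introns enter as \code{retained_intron} edges from the
#' short-read IR table (any reported event counts as short support) and
#' from long reads whenever a transcript exon fully spans — both flanking
#' splice sites strictly inside the exon — an intron annotated or observed
#' by another source. Exons are merged across annotation and long-read
#' transcripts. Undetermined-strand short-read junctions are matched to the
#' gene by coordinates.
#'
#' @param gene_id Gene to build.
#' @param annotation \code{annotation_set} (may lack the gene if long-read
#'   transcripts were assigned to it).
#' @param short Optional \code{short_read_evidence}.
#' @param long_ts Optional \code{transcript_set} of (already gene-assigned,
#'   count-filtered) long-read transcripts.
#' @param short_min_reads Minimum unique short reads for a junction to count
#'   as short support (default 2: the minimal reading of requiring multiple
#'   supporting reads).
#' @param boundary_window Tolerance in nt when flagging pTSS/pTES on
#'   long-read transcripts (default 0, exact match).
#' @return A \code{splice_graph}: gene/chrom/strand, merged \code{exons}
#'   matrix, \code{edges} data frame (kind, interval, per-source support
#'   flags and counts), \code{transcripts} (annotation + long reads, with
#'   pTSS/pTES flags), \code{tx_exons}, and per-source TSS/TES sets.
#' @export
build_splice_graph <- function(gene_id, annotation, short = NULL,
                               long_ts = NULL, short_min_reads = 2,
                               boundary_window = 0) {
  ann_has <- gene_id %in% annotation$genes$gene_id
  ltx_idx <- if (!is.null(long_ts)) which(long_ts$tx$gene_id == gene_id) else integer()
  if (!ann_has && length(ltx_idx) == 0)
    stop("gene unknown to all sources: ", gene_id)

  if (ann_has) {
    gmeta <- annotation$genes[annotation$genes$gene_id == gene_id, ]
    chrom <- gmeta$chrom; strand <- gmeta$strand
    gidx <- annotation$index[[gene_id]]
  } else {
    chrom <- long_ts$tx$chrom[ltx_idx[1]]
    strand <- long_ts$tx$strand[ltx_idx[1]]
    gidx <- list(junctions = matrix(integer(), 0, 2), jkeys = character(),
                 start_sites = integer(), end_sites = integer(),
                 tss = integer(), tes = integer(),
                 exons = matrix(integer(), 0, 2))
  }
  if (length(ltx_idx) > 0) {
    lstr <- unique(long_ts$tx$strand[ltx_idx])
    lchr <- unique(long_ts$tx$chrom[ltx_idx])
    if (ann_has && (any(lstr != strand) || any(lchr != chrom)))
      stop(sprintf("gene %s: contradictory strand/chromosome between sources", gene_id))
  }

  ann_tids <- if (ann_has) annotation$tx$transcript_id[annotation$tx$gene_id == gene_id] else character()
  long_tids <- if (length(ltx_idx)) long_ts$tx$transcript_id[ltx_idx] else character()

  # gene span for coordinate-matching unstranded/short evidence
  all_ex <- gidx$exons
  for (tid in long_tids) all_ex <- rbind(all_ex, long_ts$exons[[tid]])
  span <- c(min(all_ex[, 1]), max(all_ex[, 2]))

  # --- junction evidence per source -------------------------------------
  ann_j <- gidx$junctions

  short_j <- .empty_intron_df()
  short_ir <- .empty_intron_df()
  if (!is.null(short)) {
    sj <- short$junctions
    keep <- sj$chrom == chrom & sj$start >= span[1] & sj$end <= span[2] &
      (sj$strand == strand | sj$strand == "*")
    short_j <- sj[keep, , drop = FALSE]
    si <- short$introns
    keep_i <- si$chrom == chrom & si$start >= span[1] & si$end <= span[2] &
      si$strand == strand
    short_ir <- si[keep_i, , drop = FALSE]
  }
  short_det <- short_j[short_j$count >= short_min_reads, , drop = FALSE]

  long_j_keys <- character()
  long_j_counts <- numeric()
  if (length(ltx_idx)) {
    for (i in ltx_idx) {
      jm <- junctions_of(long_ts$exons[[long_ts$tx$transcript_id[i]]])
      if (nrow(jm) == 0) next
      ks <- .ikey(jm)
      rc <- long_ts$tx$read_count[i]
      for (k in ks) {
        if (k %in% long_j_keys) {
          long_j_counts[match(k, long_j_keys)] <- long_j_counts[match(k, long_j_keys)] + rc
        } else {
          long_j_keys <- c(long_j_keys, k)
          long_j_counts <- c(long_j_counts, rc)
        }
      }
    }
  }

  jkeys <- unique(c(gidx$jkeys, .ikey(as.matrix(short_det[, c("start", "end")])),
                    long_j_keys))
  edges <- .empty_edge_df()
  if (length(jkeys) > 0) {
    jm <- .key_mat(jkeys)
    short_keys <- .ikey(as.matrix(short_det[, c("start", "end")]))
    edges <- data.frame(
      kind = "junction", start = jm[, 1], end = jm[, 2],
      ann = jkeys %in% gidx$jkeys,
      short = jkeys %in% short_keys,
      long = jkeys %in% long_j_keys,
      short_count = 0L, long_count = 0,
      stringsAsFactors = FALSE
    )
    m <- match(jkeys, short_keys)
    edges$short_count <- ifelse(is.na(m), 0L, short_det$count[m])
    m <- match(jkeys, long_j_keys)
    edges$long_count <- ifelse(is.na(m), 0, long_j_counts[m])
  }

  # --- retained-intron edges --------------------------------------------
  # comparison introns a long/annotation exon can retain: annotated
  # junctions, detected short junctions, and short IR intervals
  comp <- unique(rbind(ann_j,
                       as.matrix(short_det[, c("start", "end")]),
                       as.matrix(short_ir[, c("start", "end")])))
  ir_keys <- .ikey(as.matrix(short_ir[, c("start", "end")]))
  ir_short_counts <- stats::setNames(short_ir$count, ir_keys)
  ir_long_counts <- numeric()
  ir_long_keys <- character()
  if (length(ltx_idx) && nrow(comp) > 0) {
    for (i in ltx_idx) {
      exo <- long_ts$exons[[long_ts$tx$transcript_id[i]]]
      rc <- long_ts$tx$read_count[i]
      for (r in seq_len(nrow(exo))) {
        sp <- which(comp[, 1] > exo[r, 1] & comp[, 2] < exo[r, 2])
        for (ci in sp) {
          k <- sprintf("%d-%d", comp[ci, 1], comp[ci, 2])
          if (k %in% ir_long_keys) {
            ir_long_counts[match(k, ir_long_keys)] <- ir_long_counts[match(k, ir_long_keys)] + rc
          } else {
            ir_long_keys <- c(ir_long_keys, k)
            ir_long_counts <- c(ir_long_counts, rc)
          }
        }
      }
    }
  }
  # annotation IR support: an annotated transcript exon spanning the intron
  ann_ir_of <- function(keys) {
    if (length(keys) == 0) return(logical(0))
    km <- .key_mat(keys)
    vapply(seq_along(keys), function(i) {
      ae <- gidx$exons
      nrow(ae) > 0 && any(ae[, 1] < km[i, 1] & ae[, 2] > km[i, 2])
    }, logical(1))
  }
  # annotated retained introns (annotation exon spans an annotated junction)
  ann_ir_keys <- character()
  if (nrow(ann_j) > 0 && nrow(gidx$exons) > 0) {
    for (ci in seq_len(nrow(ann_j))) {
      if (any(gidx$exons[, 1] < ann_j[ci, 1] & gidx$exons[, 2] > ann_j[ci, 2]))
        ann_ir_keys <- c(ann_ir_keys, sprintf("%d-%d", ann_j[ci, 1], ann_j[ci, 2]))
    }
  }
  all_ir_keys <- unique(c(ir_keys, ir_long_keys, ann_ir_keys))
  if (length(all_ir_keys) > 0) {
    irm <- .key_mat(all_ir_keys)
    ir_edges <- data.frame(
      kind = "retained_intron", start = irm[, 1], end = irm[, 2],
      ann = ann_ir_of(all_ir_keys),
      short = all_ir_keys %in% ir_keys,
      long = all_ir_keys %in% ir_long_keys,
      short_count = 0L, long_count = 0,
      stringsAsFactors = FALSE
    )
    m <- match(all_ir_keys, ir_keys)
    ir_edges$short_count <- ifelse(is.na(m), 0L, short_ir$count[m])
    m <- match(all_ir_keys, ir_long_keys)
    ir_edges$long_count <- ifelse(is.na(m), 0, ir_long_counts[m])
    edges <- rbind(edges, ir_edges)
  }
  if (nrow(edges) > 0) {
    edges <- edges[order(edges$kind, edges$start, edges$end, method = "radix"), ]
    rownames(edges) <- NULL
    if (any(edges$end < edges$start))
      stop("edge interval with length < 1 in gene ", gene_id)
    if (any(!edges$ann & !edges$short & !edges$long))
      stop("edge without support in gene ", gene_id)
  }

  # --- merged exons, transcripts, TSS/TES -------------------------------
  # retained-intron interiors are intronic in the graph's exon set: an
  # exon spanning a retained intron contributes only its flanks, so the
  # IR edge and the competing junction attach to the same reference exons
  merged <- IRanges::reduce(IRanges::IRanges(all_ex[, 1], all_ex[, 2]))
  if (length(all_ir_keys) > 0) {
    irm_all <- .key_mat(all_ir_keys)
    merged <- IRanges::setdiff(merged, IRanges::IRanges(irm_all[, 1], irm_all[, 2]))
  }
  exons <- cbind(start = IRanges::start(merged), end = IRanges::end(merged))

  tx_rows <- list(); tx_exons <- list()
  for (tid in ann_tids) {
    tx_rows[[tid]] <- data.frame(transcript_id = tid, source = "annotation",
                                 read_count = NA_real_, ptss = FALSE,
                                 ptes = FALSE, stringsAsFactors = FALSE)
    tx_exons[[tid]] <- annotation$exons[[tid]]
  }
  long_tss <- integer(); long_tes <- integer()
  for (i in ltx_idx) {
    tid <- long_ts$tx$transcript_id[i]
    exo <- long_ts$exons[[tid]]
    fl <- detect_ptss_ptes(exo, strand, gidx$tss, gidx$tes,
                           boundary_window = boundary_window,
                           warn_no_annotation = FALSE)
    tx_rows[[tid]] <- data.frame(transcript_id = tid, source = "long_reads",
                                 read_count = long_ts$tx$read_count[i],
                                 ptss = fl[["ptss"]], ptes = fl[["ptes"]],
                                 stringsAsFactors = FALSE)
    tx_exons[[tid]] <- exo
    if (strand == "+") { long_tss <- c(long_tss, exo[1, 1]); long_tes <- c(long_tes, exo[nrow(exo), 2]) }
    else { long_tss <- c(long_tss, exo[nrow(exo), 2]); long_tes <- c(long_tes, exo[1, 1]) }
  }
  transcripts <- if (length(tx_rows)) do.call(rbind, tx_rows) else
    data.frame(transcript_id = character(), source = character(),
               read_count = numeric(), ptss = logical(), ptes = logical(),
               stringsAsFactors = FALSE)
  rownames(transcripts) <- NULL

  graph <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exons = exons, edges = edges, transcripts = transcripts,
    tx_exons = tx_exons,
    tss = list(annotation = gidx$tss, long = sort(unique(long_tss))),
    tes = list(annotation = gidx$tes, long = sort(unique(long_tes)))
  ), class = "splice_graph")
  validate_splice_graph(graph)
  graph
}

.key_mat <- function(keys) {
  parts <- strsplit(keys, "-", fixed = TRUE)
  cbind(start = as.integer(vapply(parts, `[`, "", 1)),
        end = as.integer(vapply(parts, `[`, "", 2)))
}

#' Validate splice-graph invariants
#'
#' Checks that every edge has nonempty support, intervals have length >= 1,
#' counts are zero for unsupporting sources, and the graph is acyclic under
#' genomic order (edges always run left to right, so ordering edges by
#' start coordinate is a topological order).
#'
#' @param graph A \code{splice_graph}.
#' @return \code{TRUE} invisibly; stops on violation.
#' @export
validate_splice_graph <- function(graph) {
  e <- graph$edges
  if (nrow(e) > 0) {
    stopifnot(all(e$ann | e$short | e$long),
              all(e$end >= e$start),
              all(e$short_count[!e$short] == 0),
              all(e$long_count[!e$long] == 0),
              all(e$short_count >= 0), all(e$long_count >= 0))
  }
  if (nrow(graph$exons) > 1) {
    stopifnot(all(graph$exons[-nrow(graph$exons), 2] < graph$exons[-1, 1]))
  }
  invisible(TRUE)
}

#' Flag putative transcript start/end sites (pTSS/pTES)
#'
#' A long-read transcript gets pTSS = TRUE when its strand-aware 5'-most
#' genomic endpoint matches no annotated TSS of the gene within
#' \code{boundary_window} nt (and pTES analogously for the 3' end). These
#' typically arise when a caller outputs only a partial terminal exon.
#' Internal splice sites do not affect the flags.
#'
#' @param exons Exon matrix of the transcript (start/end, sorted).
#' @param strand \code{"+"} or \code{"-"}.
#' @param ann_tss,ann_tes Annotated TSS/TES genomic positions of the gene.
#' @param boundary_window Match tolerance in nt (default 0 = exact).
#' @param warn_no_annotation Warn when the gene has no annotated
#'   transcripts (both flags are then TRUE).
#' @return Named logical vector \code{c(ptss = , ptes = )}.
#' @export
detect_ptss_ptes <- function(exons, strand, ann_tss, ann_tes,
                             boundary_window = 0, warn_no_annotation = TRUE) {
  if (length(ann_tss) == 0 && length(ann_tes) == 0) {
    if (warn_no_annotation)
      warning("gene has no annotated transcripts; pTSS/pTES both TRUE")
    return(c(ptss = TRUE, ptes = TRUE))
  }
  if (strand == "+") {
    p5 <- exons[1, 1]; p3 <- exons[nrow(exons), 2]
  } else {
    p5 <- exons[nrow(exons), 2]; p3 <- exons[1, 1]
  }
  ptss <- !(length(ann_tss) > 0 && any(abs(ann_tss - p5) <= boundary_window))
  ptes <- !(length(ann_tes) > 0 && any(abs(ann_tes - p3) <= boundary_window))
  c(ptss = ptss, ptes = ptes)
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph %s (%s%s): %d exon(s), %d edge(s) [%d junction, %d IR], %d transcript(s)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$edges),
              sum(x$edges$kind == "junction"),
              sum(x$edges$kind == "retained_intron"), nrow(x$transcripts)))
  invisible(x)
}
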