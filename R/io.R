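#' Read a reference annotation from a GTF file
#'
#' Parses exon features from a GENCODE-dialect GTF and assembles them into
#' transcripts grouped by gene, together with per-gene indices of annotated
#' splice sites, junctions (intron intervals), and transcript start/end sites
#' (TSS/TES). All coordinates are kept 1-based inclusive, the GTF native
#' convention; a junction is keyed by its intron interval
#' \code{[exon_i_end + 1, exon_{i+1}_start - 1]}.
#'
#' @param path Path to a GTF file. Only \code{exon} features are required;
#'   every exon line must carry \code{gene_id} and \code{transcript_id}
#'   attributes.
#' @return An object of class \code{annotation_set}: a list with elements
#'   \code{tx} (transcript metadata data frame), \code{exons} (named list of
#'   two-column start/end matrices, one per transcript, coordinate-sorted),
#'   \code{genes} (per-gene chromosome/strand/span data frame) and
#'   \code{index} (per-gene list of annotated junctions, donor/acceptor
#'   splice-site sets, TSS/TES sets and exon intervals).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
#'   'gene_id "G1"; transcript_id "T1";'), gtf)
#' ann <- read_annotation_gtf(gtf)
#' @export
read_annotation_gtf <- function(path) {
  ts <- .read_gtf_transcripts(path, source = "annotation")
  build_annotation_set(ts)
}

#' Read long-read transcript models from a GTF file
#'
#' Reads transcript models emitted by a long-read caller (the dialect shared
#' by FLAIR, ESPRESSO, IsoQuant and Bambu) together with per-transcript read
#' counts, then removes transcripts whose count falls below \code{min_count}.
#' Counts are taken from a numeric transcript attribute
#' (\code{count_attribute}, default \code{"read_count"}) or, if a sidecar
#' table is given, from a two-column TSV (transcript_id, count). A transcript
#' absent from the sidecar is treated as count 0 and filtered, with a warning.
#'
#' @param path GTF path with exon features carrying gene_id/transcript_id.
#' @param counts Optional sidecar TSV path (transcript_id, count; no header).
#' @param min_count Minimum read count to retain a transcript; transcripts
#'   with counts below it (e.g. unexpressed reference models reported by
#'   count-aware callers) are dropped. Default 1.
#' @param count_attribute Name of the GTF attribute holding the count.
#' @return A \code{transcript_set}: list with \code{tx} data frame
#'   (transcript_id, gene_id, chrom, strand, read_count, source =
#'   \code{"long_reads"}) and \code{exons} named list of start/end matrices.
#' @export
read_long_read_gtf <- function(path, counts = NULL, min_count = 1,
                               count_attribute = "read_count") {
  ts <- .read_gtf_transcripts(path, source = "long_reads",
                              count_attribute = count_attribute)
  if (!is.null(counts)) {
    sc <- utils::read.table(counts, sep = "\t", header = FALSE,
                            col.names = c("transcript_id", "count"),
                            colClasses = c("character", "numeric"))
    idx <- match(ts$tx$transcript_id, sc$transcript_id)
    if (anyNA(idx)) {
      missing <- ts$tx$transcript_id[is.na(idx)]
      warning(sprintf("%d transcript(s) absent from counts table (treated as count 0): %s",
                      length(missing), paste(utils::head(missing, 5), collapse = ", ")))
    }
    ts$tx$read_count <- ifelse(is.na(idx), 0, sc$count[idx])
  }
  if (anyNA(ts$tx$read_count)) {
    warning(sprintf("%d transcript(s) without a read count (treated as 0)",
                    sum(is.na(ts$tx$read_count))))
    ts$tx$read_count[is.na(ts$tx$read_count)] <- 0
  }
  drop <- ts$tx$read_count < min_count
  if (any(drop)) {
    message(sprintf("read_long_read_gtf: removed %d transcript(s) with read count < %g",
                    sum(drop), min_count))
  }
  ts$exons <- ts$exons[!drop]
  ts$tx <- ts$tx[!drop, , drop = FALSE]
  rownames(ts$tx) <- NULL
  ts
}

# Shared GTF -> transcript_set parser. Validates attribute fields (naming the
# offending line), single chromosome/strand per transcript, and the >= 1 nt
# intron invariant between consecutive exons.
.read_gtf_transcripts <- function(path, source, count_attribute = "read_count") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_idx <- grep("^[^#]", lines)
  if (length(data_idx) == 0) {
    warning("empty GTF: ", path)
    return(empty_transcript_set(source))
  }
  .validate_gtf_lines(lines, data_idx, path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) {
    warning("GTF contains no exon features: ", path)
    return(empty_transcript_set(source))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id),
    stringsAsFactors = FALSE
  )
  counts <- rep(NA_real_, length(ex))
  if (count_attribute %in% names(S4Vectors::mcols(ex))) {
    counts <- suppressWarnings(as.numeric(as.character(
      S4Vectors::mcols(ex)[[count_attribute]])))
  }
  # transcript-level features may also carry the count attribute
  tx_feat <- gr[gr$type == "transcript"]
  tx_counts <- NULL
  if (length(tx_feat) > 0 && count_attribute %in% names(S4Vectors::mcols(tx_feat))) {
    tx_counts <- stats::setNames(
      suppressWarnings(as.numeric(as.character(S4Vectors::mcols(tx_feat)[[count_attribute]]))),
      as.character(tx_feat$transcript_id))
  }
  ord <- order(df$transcript_id, df$start, method = "radix")
  df <- df[ord, ]
  counts <- counts[ord]
  sp <- split(seq_len(nrow(df)), df$transcript_id)
  tids <- names(sp)
  exons <- vector("list", length(sp))
  names(exons) <- tids
  meta <- data.frame(
    transcript_id = tids,
    gene_id = character(length(sp)),
    chrom = character(length(sp)),
    strand = character(length(sp)),
    read_count = NA_real_,
    source = source,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(sp)) {
    i <- sp[[k]]
    if (length(unique(df$chrom[i])) != 1L || length(unique(df$strand[i])) != 1L)
      stop(sprintf("transcript %s has exons on mixed chromosomes or strands", tids[k]))
    s <- df$start[i]; e <- df$end[i]
    if (any(e[-length(e)] >= s[-1] - 1L))
      stop(sprintf("transcript %s: exons overlap or leave no intron (need >= 1 nt)", tids[k]))
    exons[[k]] <- cbind(start = s, end = e)
    meta$gene_id[k] <- df$gene_id[i[1]]
    meta$chrom[k] <- df$chrom[i[1]]
    meta$strand[k] <- df$strand[i[1]]
    ct <- counts[i]
    ct <- ct[!is.na(ct)]
    if (length(ct) > 0) meta$read_count[k] <- ct[1]
    else if (!is.null(tx_counts) && tids[k] %in% names(tx_counts))
      meta$read_count[k] <- tx_counts[[tids[k]]]
  }
  structure(list(tx = meta, exons = exons), class = "transcript_set")
}

.validate_gtf_lines <- function(lines, data_idx, path) {
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop(sprintf("%s: line %d: expected 9 tab-separated GTF fields, found %d",
                   path, i, length(f)))
    if (f[3] == "exon" &&
        (!grepl("gene_id", f[9], fixed = TRUE) ||
         !grepl("transcript_id", f[9], fixed = TRUE)))
      stop(sprintf("%s: line %d: exon feature lacks gene_id/transcript_id attribute",
                   path, i))
  }
  invisible(TRUE)
}

empty_transcript_set <- function(source = "annotation") {
  structure(list(
    tx = data.frame(transcript_id = character(), gene_id = character(),
                    chrom = character(), strand = character(),
                    read_count = numeric(), source = character(),
                    stringsAsFactors = FALSE),
    exons = stats::setNames(list(), character())
  ), class = "transcript_set")
}

#' Assemble an annotation set (per-gene splice-site/junction/TSS/TES indices)
#'
#' @param ts A \code{transcript_set} (as from the internal GTF parser).
#' @return An \code{annotation_set}.
#' @export
build_annotation_set <- function(ts) {
  tx <- ts$tx
  if (nrow(tx) == 0) {
    return(structure(list(tx = tx, exons = ts$exons,
                          genes = data.frame(gene_id = character(),
                                             chrom = character(),
                                             strand = character(),
                                             start = integer(), end = integer(),
                                             stringsAsFactors = FALSE),
                          index = stats::setNames(list(), character())),
                     class = "annotation_set"))
  }
  gids <- sort(unique(tx$gene_id), method = "radix")
  genes <- data.frame(gene_id = gids, chrom = NA_character_,
                      strand = NA_character_, start = NA_integer_,
                      end = NA_integer_, stringsAsFactors = FALSE)
  index <- vector("list", length(gids))
  names(index) <- gids
  for (g in seq_along(gids)) {
    ti <- which(tx$gene_id == gids[g])
    chrom <- unique(tx$chrom[ti]); strand <- unique(tx$strand[ti])
    if (length(chrom) != 1L || length(strand) != 1L)
      stop(sprintf("gene %s has transcripts on mixed chromosomes or strands", gids[g]))
    jmat <- matrix(integer(), 0, 2)
    exmat <- matrix(integer(), 0, 2)
    tss <- integer(); tes <- integer()
    for (i in ti) {
      exo <- ts$exons[[tx$transcript_id[i]]]
      exmat <- rbind(exmat, exo)
      jmat <- rbind(jmat, junctions_of(exo))
      if (strand == "+") { tss <- c(tss, exo[1, 1]); tes <- c(tes, exo[nrow(exo), 2]) }
      else { tss <- c(tss, exo[nrow(exo), 2]); tes <- c(tes, exo[1, 1]) }
    }
    jmat <- unique(jmat)
    jmat <- jmat[order(jmat[, 1], jmat[, 2]), , drop = FALSE]
    genes$chrom[g] <- chrom
    genes$strand[g] <- strand
    genes$start[g] <- min(exmat[, 1])
    genes$end[g] <- max(exmat[, 2])
    index[[g]] <- list(
      junctions = jmat,
      jkeys = .ikey(jmat),
      # splice-site sets keyed by intron-boundary coordinate, per side
      start_sites = sort(unique(jmat[, 1])),
      end_sites = sort(unique(jmat[, 2])),
      tss = sort(unique(tss)),
      tes = sort(unique(tes)),
      exons = unique(exmat)
    )
  }
  structure(list(tx = tx, exons = ts$exons, genes = genes, index = index),
            class = "annotation_set")
}

.ikey <- function(mat) {
  if (nrow(mat) == 0) return(character())
  sprintf("%d-%d", mat[, 1], mat[, 2])
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d gene(s), %d transcript(s)\n",
              nrow(x$genes), nrow(x$tx)))
  invisible(x)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set (%s): %d transcript(s)\n",
              if (nrow(x$tx)) x$tx$source[1] else "empty", nrow(x$tx)))
  invisible(x)
}

#' Read short-read splice junction evidence (STAR SJ.out.tab format)
#'
#' Nine whitespace-separated columns: chromosome, intron start (1-based),
#' intron end (1-based), strand code (0 undetermined, 1 +, 2 -), intron
#' motif, annotated flag, unique-mapping read count, multi-mapping read
#' count, maximum spliced overhang. Only the unique-read column is used as
#' the junction count; multi-mapping reads are ignored. Undetermined-strand
#' rows are kept with strand \code{"*"} and resolved against stranded gene
#' models at splice-graph build time.
#'
#' @param path Path to an SJ.out.tab-format file.
#' @param sample Optional sample label.
#' @return A \code{short_read_evidence} object: list with \code{junctions}
#'   data frame (chrom, strand, start, end, count), \code{introns} (same
#'   shape, empty until \code{\link{read_ir_table}} fills it) and
#'   \code{sample}.
#' @export
read_star_sj <- function(path, sample = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(dat) != 9L)
    stop(sprintf("%s: expected 9 columns (STAR SJ.out.tab), found %d", path, ncol(dat)))
  names(dat) <- c("chrom", "start", "end", "strand_code", "motif",
                  "annotated", "unique_reads", "multi_reads", "overhang")
  if (any(dat$unique_reads < 0) || any(dat$multi_reads < 0))
    stop("negative read counts in ", path)
  if (any(dat$start > dat$end))
    stop("junction with start > end in ", path)
  if (!all(dat$strand_code %in% 0:2))
    stop("invalid strand code (must be 0/1/2) in ", path)
  j <- data.frame(
    chrom = as.character(dat$chrom),
    strand = c("*", "+", "-")[dat$strand_code + 1L],
    start = as.integer(dat$start),
    end = as.integer(dat$end),
    count = as.integer(dat$unique_reads),
    stringsAsFactors = FALSE
  )
  key <- paste(j$chrom, j$strand, j$start, j$end)
  if (anyDuplicated(key))
    stop("duplicate junction key(s) in ", path, ": ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  structure(list(junctions = j, introns = .empty_intron_df(), sample = sample),
            class = "short_read_evidence")
}

.empty_intron_df <- function() {
  data.frame(chrom = character(), strand = character(), start = integer(),
             end = integer(), count = integer(), stringsAsFactors = FALSE)
}

#' Read a retained-intron count table
#'
#' TSV with header columns chromosome, strand, intron_start, intron_end,
#' supporting_reads. Intron intervals are keyed identically to junctions
#' (1-based inclusive intronic interval).
#'
#' @param path Path to the IR TSV.
#' @param evidence Optional \code{short_read_evidence} to attach the introns
#'   to; if \code{NULL} a new evidence object with empty junctions is
#'   returned.
#' @return A \code{short_read_evidence} with the \code{introns} component
#'   filled.
#' @export
read_ir_table <- function(path, evidence = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(dat) != 5L)
    stop(sprintf("%s: expected 5 columns, found %d", path, ncol(dat)))
  names(dat) <- c("chrom", "strand", "start", "end", "count")
  if (nrow(dat) > 0) {
    if (any(dat$start > dat$end)) stop("intron with start > end in ", path)
    if (any(dat$count < 0)) stop("negative supporting read counts in ", path)
    key <- paste(dat$chrom, dat$strand, dat$start, dat$end)
    if (anyDuplicated(key)) stop("duplicate intron interval(s) in ", path)
  }
  ir <- data.frame(chrom = as.character(dat$chrom),
                   strand = as.character(dat$strand),
                   start = as.integer(dat$start), end = as.integer(dat$end),
                   count = as.integer(dat$count), stringsAsFactors = FALSE)
  if (is.null(evidence)) {
    evidence <- structure(list(junctions = .empty_intron_df(),
                               introns = ir, sample = basename(path)),
                          class = "short_read_evidence")
  } else {
    evidence$introns <- ir
  }
  evidence
}

#' @export
print.short_read_evidence <- function(x, ...) {
  cat(sprintf("short_read_evidence [%s]: %d junction(s), %d retained intron(s)\n",
              x$sample, nrow(x$junctions), nrow(x$introns)))
  invisible(x)
}

#' Write a reporting table as TSV
#'
#' Deterministic column order (as given), tab separation, header row, and
#' floating-point values at 6 significant digits.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_table_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         format(signif(out[[j]], 6), trim = TRUE,
                                scientific = FALSE, drop0trailing = TRUE))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Export a splice graph as a JSON document
#'
#' One document per gene: merged exons, edges with their support sets and
#' per-source read counts, and transcripts with their exon chains, read
#' counts and pTSS/pTES flags — the data model behind a unified
#' splice-graph visualisation.
#'
#' @param graph A \code{splice_graph}.
#' @param path Optional output path; if \code{NULL} the JSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
splice_graph_to_json <- function(graph, path = NULL) {
  doc <- list(
    gene_id = graph$gene_id,
    chrom = graph$chrom,
    strand = graph$strand,
    exons = apply(graph$exons, 1, function(r) list(start = r[[1]], end = r[[2]])),
    edges = lapply(seq_len(nrow(graph$edges)), function(i) {
      e <- graph$edges[i, ]
      list(kind = e$kind, start = e$start, end = e$end,
           support = .support_vec(e),
           short_count = e$short_count, long_count = e$long_count)
    }),
    tss = graph$tss,
    tes = graph$tes,
    transcripts = lapply(seq_len(nrow(graph$transcripts)), function(i) {
      t <- graph$transcripts[i, ]
      exo <- graph$tx_exons[[t$transcript_id]]
      list(transcript_id = t$transcript_id, source = t$source,
           read_count = t$read_count,
           ptss = t$ptss, ptes = t$ptes,
           exons = apply(exo, 1, function(r) list(start = r[[1]], end = r[[2]])))
    })
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a splice graph back from its JSON export
#'
#' @param path Path to a JSON document written by
#'   \code{\link{splice_graph_to_json}}.
#' @return A \code{splice_graph}.
#' @export
splice_graph_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  exons <- do.call(rbind, lapply(doc$exons, function(e)
    c(start = as.integer(e$start), end = as.integer(e$end))))
  edges <- do.call(rbind, lapply(doc$edges, function(e) {
    sup <- unlist(e$support)
    data.frame(kind = e$kind, start = as.integer(e$start),
               end = as.integer(e$end),
               ann = "annotation" %in% sup, short = "short" %in% sup,
               long = "long" %in% sup,
               short_count = as.integer(e$short_count),
               long_count = as.numeric(e$long_count),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- .empty_edge_df()
  tx <- do.call(rbind, lapply(doc$transcripts, function(t)
    data.frame(transcript_id = t$transcript_id, source = t$source,
               read_count = if (is.null(t$read_count)) NA_real_ else as.numeric(t$read_count),
               ptss = isTRUE(t$ptss), ptes = isTRUE(t$ptes),
               stringsAsFactors = FALSE)))
  if (is.null(tx)) tx <- data.frame(transcript_id = character(), source = character(),
                                    read_count = numeric(), ptss = logical(),
                                    ptes = logical(), stringsAsFactors = FALSE)
  tx_exons <- stats::setNames(lapply(doc$transcripts, function(t)
    do.call(rbind, lapply(t$exons, function(e)
      c(start = as.integer(e$start), end = as.integer(e$end))))),
    vapply(doc$transcripts, `[[`, "", "transcript_id"))
  structure(list(gene_id = doc$gene_id, chrom = doc$chrom, strand = doc$strand,
                 exons = exons, edges = edges, transcripts = tx,
                 tx_exons = tx_exons,
                 tss = lapply(doc$tss, unlist), tes = lapply(doc$tes, unlist)),
            class = "splice_graph")
}

.support_vec <- function(edge_row) {
  c("annotation", "short", "long")[c(edge_row$ann, edge_row$short, edge_row$long)]
}
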