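SIX_CATEGORIES <- c("ALL", "BOTH_DENOVO", "SHORT_ANNOT", "LONG_ANNOT",
                    "SHORT_ONLY", "LONG_ONLY")
CATEGORY_LEVELS <- c(SIX_CATEGORIES, "NOT_DETECTED")

#' Six-way source category of splice-graph edges
#'
#' Any detected element (junction or retained intron) falls into one of six
#' categories according to which subset of \{annotation, short reads, long
#' reads\} supports it: ALL, BOTH_DENOVO (short + long, unannotated),
#' SHORT_ANNOT, LONG_ANNOT, SHORT_ONLY, LONG_ONLY. Support by the
#' annotation alone means the element was not detected by any reads and is
#' returned as NOT_DETECTED (excluded from all detected-element counts).
#'
#' @param edges Edge data frame of a \code{splice_graph} (or a single row),
#'   with logical columns \code{ann}, \code{short}, \code{long}.
#' @return Character vector of categories, one per edge.
#' @export
six_category <- function(edges) {
  if (nrow(edges) == 0) return(character())
  if (any(!edges$ann & !edges$short & !edges$long))
    stop("edge with empty support set")
  ifelse(edges$ann & edges$short & edges$long, "ALL",
  ifelse(!edges$ann & edges$short & edges$long, "BOTH_DENOVO",
  ifelse(edges$ann & edges$short, "SHORT_ANNOT",
  ifelse(edges$ann & edges$long, "LONG_ANNOT",
  ifelse(edges$short, "SHORT_ONLY",
  ifelse(edges$long, "LONG_ONLY", "NOT_DETECTED"))))))
}

# strand-aware donor (5'SS) / acceptor (3'SS) coordinates of an intron
# interval: on + the donor is the intron start, on - the intron end.
.donor_acceptor <- function(start, end, strand) {
  if (strand == "+") c(donor = start, acceptor = end)
  else c(donor = end, acceptor = start)
}

.site_annotated <- function(coord, side, gidx) {
  if (side == "start") coord %in% gidx$start_sites else coord %in% gidx$end_sites
}

#' Classify a de novo junction: novel splice site vs. novel combination
#'
#' A detected junction absent from the annotation is a NOVEL_COMBINATION
#' when both of its splice sites (strand-aware donor and acceptor) are
#' individually annotated for the gene but the pair forms no annotated
#' junction; otherwise it is a NOVEL_SPLICE_SITE.
#'
#' @param start,end Intron interval of the junction (1-based inclusive).
#' @param strand Gene strand.
#' @param gene_index Per-gene annotation index
#'   (\code{annotation$index[[gene_id]]}).
#' @return \code{"NOVEL_COMBINATION"} or \code{"NOVEL_SPLICE_SITE"}.
#' @export
classify_denovo_junction <- function(start, end, strand, gene_index) {
  if (sprintf("%d-%d", start, end) %in% gene_index$jkeys)
    stop("junction is annotated; de novo classification does not apply")
  donor_side <- if (strand == "+") "start" else "end"
  donor_coord <- if (strand == "+") start else end
  acceptor_coord <- if (strand == "+") end else start
  donor_known <- .site_annotated(donor_coord, if (strand == "+") "start" else "end", gene_index)
  acceptor_known <- .site_annotated(acceptor_coord, if (strand == "+") "end" else "start", gene_index)
  if (donor_known && acceptor_known) "NOVEL_COMBINATION" else "NOVEL_SPLICE_SITE"
}

#' Type of a novel-splice-site variation introduced by long reads
#'
#' Long-read elements involving unannotated splice sites are typed as:
#' \itemize{
#'   \item \code{IR}: a retained intron (a transcript exon fully spans an
#'     annotated/observed intron);
#'   \item \code{NEW_EXON}: a transcript exon lying strictly inside an
#'     annotated intron with both of its boundaries unannotated;
#'   \item \code{ALT_5SS}/\code{ALT_3SS}: only the donor/only the acceptor
#'     is novel;
#'   \item \code{MIXED}: both sites novel, within annotated exonic context.
#' }
#' Precedence IR > NEW_EXON > ALT/MIXED keeps the outcomes disjoint.
#'
#' @param kind \code{"junction"} or \code{"retained_intron"}.
#' @param start,end Element interval.
#' @param strand Gene strand.
#' @param gene_index Per-gene annotation index.
#' @param tx_exon_list List of exon matrices of the long-read transcripts
#'   containing the element (context for the NEW_EXON geometry test).
#' @return One of \code{"ALT_5SS"}, \code{"ALT_3SS"}, \code{"MIXED"},
#'   \code{"IR"}, \code{"NEW_EXON"}.
#' @export
classify_novel_ss_type <- function(kind, start, end, strand, gene_index,
                                   tx_exon_list = list()) {
  if (kind == "retained_intron") return("IR")
  donor_coord <- if (strand == "+") start else end
  acceptor_coord <- if (strand == "+") end else start
  donor_novel <- !.site_annotated(donor_coord, if (strand == "+") "start" else "end", gene_index)
  acceptor_novel <- !.site_annotated(acceptor_coord, if (strand == "+") "end" else "start", gene_index)
  if (!donor_novel && !acceptor_novel)
    stop("element has no novel splice site")
  if (.flanks_new_exon(start, end, gene_index, tx_exon_list))
    return("NEW_EXON")
  if (donor_novel && acceptor_novel) return("MIXED")
  if (donor_novel) "ALT_5SS" else "ALT_3SS"
}

# TRUE when a flanking exon of the junction (in any containing transcript)
# lies strictly inside an annotated intron with both boundaries unannotated.
.flanks_new_exon <- function(start, end, gene_index, tx_exon_list) {
  annj <- gene_index$junctions
  if (nrow(annj) == 0) return(FALSE)
  for (exo in tx_exon_list) {
    jm <- junctions_of(exo)
    if (nrow(jm) == 0) next
    hit <- which(jm[, 1] == start & jm[, 2] == end)
    if (length(hit) == 0) next
    for (h in hit) {
      for (exi in c(h, h + 1L)) {  # upstream and downstream flanking exon
        a <- exo[exi, 1]; b <- exo[exi, 2]
        inside <- any(annj[, 1] <= a & b <= annj[, 2])
        if (!inside) next
        left_novel <- !((a - 1L) %in% gene_index$end_sites)
        right_novel <- !((b + 1L) %in% gene_index$start_sites)
        # terminal exons of the chain have one boundary that is a
        # transcript end, not a splice site; require both splice-side
        # boundaries novel for internal exons only
        if (exi > 1L && exi < nrow(exo) && left_novel && right_novel)
          return(TRUE)
      }
    }
  }
  FALSE
}

VENN_CLASSES <- c(I = "nc", II = "nss", III = "nc+nss", IV = "nc+pt",
                  V = "nss+pt", VI = "nc+nss+pt", VII = "pt")

.venn_of_features <- function(nc, nss, pt) {
  key <- paste(c("nc", "nss", "pt")[c(nc, nss, pt)], collapse = "+")
  if (key == "") return("NONE")
  names(VENN_CLASSES)[match(key, VENN_CLASSES)]
}

#' Venn class (I–VII) of a novel long-read transcript
#'
#' A long-read transcript is characterised by which of three features it
#' carries: at least one novel-combination junction, at least one
#' novel-splice-site junction, and pTSS/pTES (either flag). The seven
#' nonempty feature subsets map to classes I–VII; class VII (pTSS/pTES
#' only) is flagged as excluded from comparison, since short-read splicing
#' callers do not call transcript starts/ends. A fully annotated transcript
#' returns \code{"NONE"}.
#'
#' @param transcript_id Transcript to classify (must be a long-read
#'   transcript of the graph).
#' @param graph A \code{splice_graph} with pTSS/pTES flags computed.
#' @param gene_index Per-gene annotation index.
#' @return List with \code{class} (\code{"I"}..\code{"VII"} or
#'   \code{"NONE"}), \code{excluded} (TRUE for VII), and the three feature
#'   flags.
#' @export
classify_long_transcript <- function(transcript_id, graph, gene_index) {
  row <- graph$transcripts[graph$transcripts$transcript_id == transcript_id, ]
  if (nrow(row) != 1 || row$source != "long_reads")
    stop("not a long-read transcript of this graph: ", transcript_id)
  exo <- graph$tx_exons[[transcript_id]]
  jm <- junctions_of(exo)
  nc <- FALSE; nss <- FALSE
  if (nrow(jm) > 0) {
    for (r in seq_len(nrow(jm))) {
      if (sprintf("%d-%d", jm[r, 1], jm[r, 2]) %in% gene_index$jkeys) next
      cls <- classify_denovo_junction(jm[r, 1], jm[r, 2], graph$strand, gene_index)
      if (cls == "NOVEL_COMBINATION") nc <- TRUE else nss <- TRUE
    }
  }
  pt <- isTRUE(row$ptss) || isTRUE(row$ptes)
  cls <- .venn_of_features(nc, nss, pt)
  list(class = cls, excluded = identical(cls, "VII"),
       novel_combination = nc, novel_splice_site = nss, ptss_ptes = pt)
}

#' Classify every detected element and long-read transcript of a gene
#'
#' Produces the per-element table (six-way category; for detected elements
#' without annotation support also the de novo class, and for long-read
#' novel elements the novel-splice-site type) and the per-transcript table
#' (Venn class I–VII with pTSS/pTES flags). A junction shared by several
#' long-read transcripts is classified once, by coordinates.
#'
#' @param graph A \code{splice_graph}.
#' @param annotation The \code{annotation_set} used to build it.
#' @return List with data frames \code{elements} (gene_id, kind, start,
#'   end, six_category, denovo_class, novel_ss_type) and
#'   \code{transcripts} (gene_id, transcript_id, venn_class, excluded,
#'   ptss, ptes).
#' @export
classify_elements <- function(graph, annotation) {
  gidx <- .gene_index_of(graph$gene_id, annotation)
  e <- graph$edges
  cat6 <- six_category(e)
  denovo <- rep(NA_character_, nrow(e))
  nss_type <- rep(NA_character_, nrow(e))
  long_tids <- graph$transcripts$transcript_id[graph$transcripts$source == "long_reads"]
  long_exons <- graph$tx_exons[long_tids]
  for (i in seq_len(nrow(e))) {
    if (cat6[i] %in% c("NOT_DETECTED")) next
    if (e$ann[i]) next  # annotated elements carry no de novo class
    if (e$kind[i] == "junction") {
      denovo[i] <- classify_denovo_junction(e$start[i], e$end[i], graph$strand, gidx)
      if (e$long[i] && denovo[i] == "NOVEL_SPLICE_SITE") {
        ctx <- Filter(function(exo) {
          jm <- junctions_of(exo)
          nrow(jm) > 0 && any(jm[, 1] == e$start[i] & jm[, 2] == e$end[i])
        }, long_exons)
        nss_type[i] <- classify_novel_ss_type("junction", e$start[i], e$end[i],
                                              graph$strand, gidx, ctx)
      }
    } else if (e$long[i]) {
      nss_type[i] <- "IR"
    }
  }
  elements <- data.frame(gene_id = graph$gene_id, kind = e$kind,
                         start = e$start, end = e$end,
                         six_category = cat6, denovo_class = denovo,
                         novel_ss_type = nss_type, stringsAsFactors = FALSE)
  tx_rows <- lapply(long_tids, function(tid) {
    v <- classify_long_transcript(tid, graph, gidx)
    data.frame(gene_id = graph$gene_id, transcript_id = tid,
               venn_class = v$class, excluded = v$excluded,
               ptss = graph$transcripts$ptss[graph$transcripts$transcript_id == tid],
               ptes = graph$transcripts$ptes[graph$transcripts$transcript_id == tid],
               stringsAsFactors = FALSE)
  })
  transcripts <- if (length(tx_rows)) do.call(rbind, tx_rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               venn_class = character(), excluded = logical(),
               ptss = logical(), ptes = logical(), stringsAsFactors = FALSE)
  list(elements = elements, transcripts = transcripts)
}

.gene_index_of <- function(gene_id, annotation) {
  if (gene_id %in% names(annotation$index)) annotation$index[[gene_id]]
  else list(junctions = matrix(integer(), 0, 2), jkeys = character(),
            start_sites = integer(), end_sites = integer(),
            tss = integer(), tes = integer(), exons = matrix(integer(), 0, 2))
}
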