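#' Confusion tables between pipeline labels and simulation ground truth
#'
#' Joins the classification outputs with the generator's truth tables on
#' element (gene, kind, interval) and transcript keys and tabulates each
#' taxonomy (six-way category, de novo class, novel-splice-site type, Venn
#' class, pTSS/pTES flags) as a confusion matrix with its recovery rate
#' (trace / total).
#'
#' @param elements Classification element table (from
#'   \code{\link{classify_elements}}, pooled over genes), detected
#'   elements only.
#' @param transcripts Classification transcript table.
#' @param truth_elements,truth_transcripts Ground-truth tables from
#'   \code{\link{simulate_dataset}}.
#' @return List of per-taxonomy results: \code{confusion} (table),
#'   \code{recovery} (fraction of elements whose label matches), and
#'   \code{n}.
#' @export
truth_eval <- function(elements, transcripts, truth_elements, truth_transcripts) {
  pred <- elements[elements$six_category != "NOT_DETECTED", , drop = FALSE]
  key <- function(d) paste(d$gene_id, d$kind, d$start, d$end)
  kp <- key(pred); kt <- key(truth_elements)
  if (!setequal(kp, kt)) {
    miss <- utils::head(setdiff(kt, kp), 3)
    extra <- utils::head(setdiff(kp, kt), 3)
    stop(sprintf("element universes differ: %d truth-only (e.g. %s), %d prediction-only (e.g. %s)",
                 length(setdiff(kt, kp)), paste(miss, collapse = "; "),
                 length(setdiff(kp, kt)), paste(extra, collapse = "; ")))
  }
  m <- match(kt, kp)
  out <- list()
  cmp <- function(pv, tv, name) {
    pv <- ifelse(is.na(pv), "<NA>", pv)
    tv <- ifelse(is.na(tv), "<NA>", tv)
    conf <- table(truth = tv, predicted = pv)
    list(confusion = conf, recovery = mean(pv == tv), n = length(pv))
  }
  out$six_category <- cmp(pred$six_category[m], truth_elements$six_category)
  out$denovo_class <- cmp(pred$denovo_class[m], truth_elements$denovo_class)
  out$novel_ss_type <- cmp(pred$novel_ss_type[m], truth_elements$novel_ss_type)

  kp <- paste(transcripts$gene_id, transcripts$transcript_id)
  kt <- paste(truth_transcripts$gene_id, truth_transcripts$transcript_id)
  if (!setequal(kp, kt))
    stop("transcript universes differ between prediction and truth")
  m <- match(kt, kp)
  out$venn_class <- cmp(transcripts$venn_class[m], truth_transcripts$venn_class)
  out$ptss <- cmp(as.character(transcripts$ptss[m]),
                  as.character(truth_transcripts$ptss))
  out$ptes <- cmp(as.character(transcripts$ptes[m]),
                  as.character(truth_transcripts$ptes))
  out
}

#' Brute-force six-way category from raw per-source membership
#'
#' Independent subset-test reference for the category assignment: given
#' raw evidence sets (annotated junction keys, short-read counts, long
#' read-supported keys), recomputes each element's category by direct
#' subset membership. Used as an oracle against graph-derived categories.
#'
#' @param keys Character element keys (\code{"start-end"}).
#' @param ann_keys Annotated element keys.
#' @param short_counts Named integer vector of short-read counts.
#' @param long_keys Keys supported by long reads.
#' @param short_min_reads Detection threshold for short support.
#' @return Character vector of categories (including NOT_DETECTED).
#' @export
brute_force_category <- function(keys, ann_keys, short_counts, long_keys,
                                 short_min_reads = 2) {
  vapply(keys, function(k) {
    a <- k %in% ann_keys
    s <- !is.na(short_counts[k]) && short_counts[k] >= short_min_reads
    l <- k %in% long_keys
    if (a && s && l) "ALL"
    else if (s && l) "BOTH_DENOVO"
    else if (a && s) "SHORT_ANNOT"
    else if (a && l) "LONG_ANNOT"
    else if (s) "SHORT_ONLY"
    else if (l) "LONG_ONLY"
    else if (a) "NOT_DETECTED"
    else stop("element with no evidence at all: ", k)
  }, character(1), USE.NAMES = FALSE)
}
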