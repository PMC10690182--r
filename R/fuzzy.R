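#' Fuzzy splice-site matching of long-read sites at one window size
#'
#' Long-read splice sites that do not exactly match a short-read site are
#' matched against short-read sites within \code{±window} nt; a site still
#' unmatched (and not itself annotated) is then compared to annotated
#' sites within the same window. Matching is per-site (intron start-side
#' and end-side coordinates handled independently), greedy nearest-first,
#' ties broken toward the smaller genomic coordinate, and many long-read
#' sites may snap to one target. Matched long-read coordinates are snapped
#' to the target site; edges that come to share an interval are merged
#' (support sets unioned, long-read counts summed) and annotation support
#' is re-evaluated against the annotated junction set (never removed).
#' Six-way categories are then recomputed. Only long-read sites move;
#' short-read and annotated sites are the trusted reference sets.
#'
#' @param graph A \code{splice_graph}.
#' @param window Non-negative window size in nt (0 = exact matching).
#' @param annotation The \code{annotation_set} (annotated site/junction
#'   sets of the gene).
#' @return A \code{fuzzy_match} object: \code{window},
#'   \code{counts_before}/\code{counts_after} (per-category counts over
#'   the original detected junction elements, so totals are conserved),
#'   \code{reassigned} data frame (old/new interval, old/new category,
#'   per-side shifts), and \code{graph_after} with the merged edge set.
#' @export
fuzzy_match <- function(graph, window, annotation) {
  if (window < 0) stop("window must be non-negative")
  gidx <- .gene_index_of(graph$gene_id, annotation)
  e <- graph$edges
  jidx <- which(e$kind == "junction")
  det <- jidx[e$short[jidx] | e$long[jidx]]
  cats_before <- six_category(e[det, , drop = FALSE])

  short_start <- sort(unique(e$start[jidx][e$short[jidx]]))
  short_end <- sort(unique(e$end[jidx][e$short[jidx]]))
  # annotation fallback targets are restricted to annotated sites that are
  # themselves stable (no short-read site within the window), which makes
  # matching idempotent: every snapped coordinate is a fixed point
  ann_start <- gidx$start_sites[vapply(gidx$start_sites, function(s)
    (s %in% short_start) || is.na(.nearest_within(s, short_start, window)),
    logical(1))]
  ann_end <- gidx$end_sites[vapply(gidx$end_sites, function(s)
    (s %in% short_end) || is.na(.nearest_within(s, short_end, window)),
    logical(1))]

  snap_site <- function(coord, short_sites, ann_sites) {
    if (coord %in% short_sites) return(coord)
    m <- .nearest_within(coord, short_sites, window)
    if (!is.na(m)) return(m)
    if (coord %in% ann_sites) return(coord)
    m <- .nearest_within(coord, ann_sites, window)
    if (!is.na(m)) return(m)
    coord
  }

  new_start <- e$start
  new_end <- e$end
  for (i in jidx) {
    if (!e$long[i]) next
    new_start[i] <- snap_site(e$start[i], short_start, ann_start)
    new_end[i] <- snap_site(e$end[i], short_end, ann_end)
  }

  # merge edges sharing (kind, snapped interval); annotation support is
  # kept and may be gained when the snapped interval is annotated
  key <- paste(e$kind, new_start, new_end)
  grp <- match(key, key)
  merged_rows <- sort(unique(grp))
  merged <- do.call(rbind, lapply(merged_rows, function(g) {
    idx <- which(grp == g)
    kind <- e$kind[idx[1]]
    ann <- any(e$ann[idx]) ||
      (kind == "junction" &&
       sprintf("%d-%d", new_start[idx[1]], new_end[idx[1]]) %in% gidx$jkeys)
    data.frame(kind = kind, start = new_start[idx[1]], end = new_end[idx[1]],
               ann = ann, short = any(e$short[idx]), long = any(e$long[idx]),
               short_count = max(e$short_count[idx]),
               long_count = sum(e$long_count[idx]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(merged)) merged <- .empty_edge_df()
  merged_cat <- six_category(merged)
  cats_after <- merged_cat[match(grp[det], merged_rows)]

  moved <- det[new_start[det] != e$start[det] | new_end[det] != e$end[det] |
               cats_after != cats_before]
  reassigned <- data.frame(
    gene_id = rep(graph$gene_id, length(moved)),
    old_start = e$start[moved], old_end = e$end[moved],
    new_start = new_start[moved], new_end = new_end[moved],
    shift_start = new_start[moved] - e$start[moved],
    shift_end = new_end[moved] - e$end[moved],
    old_category = cats_before[match(moved, det)],
    new_category = cats_after[match(moved, det)],
    stringsAsFactors = FALSE
  )

  graph_after <- graph
  ord <- order(merged$kind, merged$start, merged$end, method = "radix")
  graph_after$edges <- merged[ord, , drop = FALSE]
  rownames(graph_after$edges) <- NULL

  structure(list(
    window = window,
    counts_before = .category_table(cats_before),
    counts_after = .category_table(cats_after),
    reassigned = reassigned,
    graph_after = graph_after
  ), class = "fuzzy_match")
}

.nearest_within <- function(coord, sites, window) {
  if (length(sites) == 0 || window == 0) return(NA_integer_)
  d <- abs(sites - coord)
  ok <- which(d <= window)
  if (length(ok) == 0) return(NA_integer_)
  best <- ok[order(d[ok], sites[ok])][1]  # nearest; tie -> smaller coordinate
  sites[best]
}

.category_table <- function(cats) {
  tab <- table(factor(cats, levels = SIX_CATEGORIES))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.fuzzy_match <- function(x, ...) {
  cat(sprintf("fuzzy_match (window %d): %d element(s) reassigned\n",
              x$window, nrow(x$reassigned)))
  invisible(x)
}

#' Fuzzy-matching sweep over window sizes
#'
#' Runs \code{\link{fuzzy_match}} independently (not cumulatively) at each
#' window size and tabulates per-window category counts.
#'
#' @param graph A \code{splice_graph}.
#' @param windows Ascending integer vector of window sizes (the
#'   conventional sweep is 3–8 nt; 0 reproduces exact matching).
#' @param annotation The \code{annotation_set}.
#' @return List with \code{results} (list of \code{fuzzy_match}) and
#'   \code{table}: data frame (window, category, count, n_reassigned).
#' @export
fuzzy_sweep <- function(graph, windows, annotation) {
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  results <- lapply(windows, function(w) fuzzy_match(graph, w, annotation))
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(window = r$window, category = names(r$counts_after),
               count = as.integer(r$counts_after),
               n_reassigned = nrow(r$reassigned),
               stringsAsFactors = FALSE)
  }))
  list(results = results, table = tab)
}

#' Pool fuzzy sweeps over many genes into one category-count table
#'
#' @param graphs List of \code{splice_graph}s.
#' @param windows Window sizes.
#' @param annotation The \code{annotation_set}.
#' @return Data frame (window, category, count, n_reassigned) summed over
#'   genes.
#' @export
fuzzy_sweep_genes <- function(graphs, windows, annotation) {
  pieces <- lapply(graphs, function(g) fuzzy_sweep(g, windows, annotation)$table)
  tab <- do.call(rbind, pieces)
  agg <- stats::aggregate(cbind(count, n_reassigned) ~ window + category,
                          data = tab, FUN = sum)
  agg <- agg[order(agg$window, match(agg$category, SIX_CATEGORIES)), ]
  rownames(agg) <- NULL
  agg
}
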