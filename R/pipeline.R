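#' End-to-end comparison run
#'
#' Orchestrates the full pipeline: read the three evidence sources, build
#' per-gene unified splice graphs (one set per short-read replicate),
#' classify elements and transcripts, define and quantify LSVs, run the
#' fuzzy-matching sweep, and write every report table plus per-gene JSON
#' splice graphs and a run manifest. Outputs are a deterministic function
#' of the inputs and configuration.
#'
#' @param annotation_gtf Path to the reference annotation GTF.
#' @param long_gtf Path to the long-read transcript GTF.
#' @param sj_paths Character vector of SJ.out.tab paths (>= 1 replicate).
#' @param ir_paths Optional IR TSV paths, parallel to \code{sj_paths}
#'   (NULL or missing entries allowed: IR reports are then empty).
#' @param out_dir Output directory.
#' @param long_counts Optional sidecar counts TSV for the long-read GTF.
#' @param read_lengths_path Optional text file of long-read lengths (one
#'   per line) for the read-length report.
#' @param short_min_reads,long_min_count,lsv_min_reads Thresholds:
#'   short-read junction detection (default 2), long-read transcript
#'   count filter (default 1), LSV quantifiability (default 10).
#' @param fuzzy_windows Window sizes for the fuzzy sweep (default 0 and
#'   3–8 nt).
#' @param boundary_window pTSS/pTES matching tolerance (default 0).
#' @param write_graph_json Write one JSON splice-graph document per gene
#'   (default TRUE).
#' @return Invisibly, a list with the per-replicate graphs, pooled
#'   tables, and the manifest.
#' @export
run_compare <- function(annotation_gtf, long_gtf, sj_paths, ir_paths = NULL,
                        out_dir, long_counts = NULL, read_lengths_path = NULL,
                        short_min_reads = 2, long_min_count = 1,
                        lsv_min_reads = 10, fuzzy_windows = c(0, 3:8),
                        boundary_window = 0, write_graph_json = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "lsvcompare",
                   version = as.character(utils::packageVersion("lsvcompare")),
                   config = list(annotation_gtf = annotation_gtf,
                                 long_gtf = long_gtf,
                                 sj_paths = sj_paths,
                                 ir_paths = ir_paths,
                                 long_counts = long_counts,
                                 short_min_reads = short_min_reads,
                                 long_min_count = long_min_count,
                                 lsv_min_reads = lsv_min_reads,
                                 fuzzy_windows = fuzzy_windows,
                                 boundary_window = boundary_window),
                   stages = list())
  write_manifest <- function(status, stage = NULL) {
    manifest$status <- status
    if (!is.null(stage)) manifest$failed_stage <- stage
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, na = "null"),
               file.path(out_dir, "manifest.json"))
  }
  stage <- "read_inputs"
  res <- tryCatch({
    annotation <- read_annotation_gtf(annotation_gtf)
    long_ts <- read_long_read_gtf(long_gtf, counts = long_counts,
                                  min_count = long_min_count)
    long_ts <- assign_long_read_genes(long_ts, annotation)
    n_rep <- length(sj_paths)
    evidence <- lapply(seq_len(n_rep), function(r) {
      ev <- read_star_sj(sj_paths[r])
      if (!is.null(ir_paths) && length(ir_paths) >= r && !is.na(ir_paths[r]) &&
          nzchar(ir_paths[r])) {
        ev <- read_ir_table(ir_paths[r], ev)
      } else {
        warning("no IR table for replicate ", r, "; IR reports will be empty")
      }
      ev
    })
    manifest$stages$read_inputs <- list(
      n_genes_annotated = nrow(annotation$genes),
      n_long_transcripts = nrow(long_ts$tx),
      n_replicates = n_rep)

    stage <- "build_graphs"
    genes <- sort(unique(c(annotation$genes$gene_id, long_ts$tx$gene_id)),
                  method = "radix")
    rep_graphs <- lapply(seq_len(n_rep), function(r) {
      gl <- lapply(genes, function(g)
        build_splice_graph(g, annotation, evidence[[r]], long_ts,
                           short_min_reads = short_min_reads,
                           boundary_window = boundary_window))
      names(gl) <- genes
      gl
    })
    manifest$stages$build_graphs <- list(
      n_genes = length(genes),
      n_edges_rep1 = sum(vapply(rep_graphs[[1]], function(g) nrow(g$edges), integer(1))))

    stage <- "classify"
    cls <- lapply(rep_graphs[[1]], classify_elements, annotation = annotation)
    elements <- do.call(rbind, lapply(cls, `[[`, "elements"))
    transcripts <- do.call(rbind, lapply(cls, `[[`, "transcripts"))
    rownames(elements) <- rownames(transcripts) <- NULL
    write_table_tsv(elements, file.path(out_dir, "elements.tsv"))
    write_table_tsv(transcripts, file.path(out_dir, "transcripts.tsv"))
    manifest$stages$classify <- list(
      n_detected = sum(elements$six_category != "NOT_DETECTED"),
      n_transcripts = nrow(transcripts))

    stage <- "quantify"
    lsvs_by_gene <- lapply(rep_graphs[[1]], define_lsvs)
    lsv_tabs <- lapply(names(lsvs_by_gene), function(g)
      quantify_lsvs(rep_graphs[[1]][[g]], lsvs_by_gene[[g]], annotation,
                    min_reads = lsv_min_reads))
    lsv_table <- do.call(rbind, lsv_tabs)
    rownames(lsv_table) <- NULL
    write_table_tsv(lsv_table, file.path(out_dir, "lsvs.tsv"))
    manifest$stages$quantify <- list(n_lsvs = nrow(lsv_table))

    stage <- "fuzzy"
    fz <- fuzzy_sweep_genes(rep_graphs[[1]], fuzzy_windows, annotation)
    write_table_tsv(fz, file.path(out_dir, "fuzzy_sweep.tsv"))
    reassigned <- do.call(rbind, lapply(rep_graphs[[1]], function(g) {
      r <- fuzzy_match(g, max(fuzzy_windows), annotation)$reassigned
      r
    }))
    rownames(reassigned) <- NULL
    write_table_tsv(reassigned, file.path(out_dir, "fuzzy_reassigned.tsv"))
    manifest$stages$fuzzy <- list(n_reassigned_max_window = nrow(reassigned))

    stage <- "report"
    cats_j <- category_counts(rep_graphs, "junction")
    cats_ir <- category_counts(rep_graphs, "retained_intron")
    write_table_tsv(cats_j, file.path(out_dir, "category_counts_junctions.tsv"))
    write_table_tsv(cats_ir, file.path(out_dir, "category_counts_introns.tsv"))

    g1 <- rep_graphs[[1]]
    short_j <- lapply(g1, function(g) {
      e <- g$edges
      idx <- which(e$kind == "junction" & e$short)
      if (length(idx) == 0) return(NULL)
      lsvs <- lsvs_by_gene[[g$gene_id]]
      data.frame(
        psi = vapply(idx, function(i)
          junction_min_psi(i, lsvs, "short", lsv_min_reads), numeric(1)),
        count = e$short_count[idx],
        long_detected = e$long[idx])
    })
    short_j <- do.call(rbind, short_j)
    if (!is.null(short_j) && nrow(short_j) > 0) {
      dvp <- detection_vs_psi(short_j$psi, short_j$long_detected)
      write_table_tsv(dvp$table, file.path(out_dir, "detection_vs_psi.tsv"))
      dvc <- detection_vs_coverage(short_j$count, short_j$long_detected)
      write_table_tsv(dvc$table, file.path(out_dir, "detection_vs_coverage.tsv"))
      manifest$stages$report <- list(
        n_short_junctions = nrow(short_j),
        missed_fraction_psi20 = dvp$missed_fraction,
        long_detected_fraction = dvc$fraction_detected)
    }
    nq_cov <- nonquantifiable_fractions(lsv_table, "coverage")
    nq_dist <- nonquantifiable_fractions(lsv_table, "distance3p")
    write_table_tsv(nq_cov, file.path(out_dir, "nonquantifiable_coverage.tsv"))
    write_table_tsv(nq_dist, file.path(out_dir, "nonquantifiable_distance.tsv"))
    irc <- ir_comparison(g1, lsvs_by_gene, min_reads = lsv_min_reads)
    write_table_tsv(irc$categories, file.path(out_dir, "ir_categories.tsv"))
    write_table_tsv(irc$lengths, file.path(out_dir, "ir_lengths.tsv"))
    write_table_tsv(irc$detection_by_psi, file.path(out_dir, "ir_detection_by_psi.tsv"))
    write_table_tsv(irc$detection_by_count, file.path(out_dir, "ir_detection_by_count.tsv"))
    if (!is.null(read_lengths_path) && file.exists(read_lengths_path)) {
      lens <- as.numeric(readLines(read_lengths_path))
      rld <- read_length_distribution(lens)
      write_table_tsv(rld$fractions, file.path(out_dir, "read_length_fractions.tsv"))
    }

    if (write_graph_json) {
      gj <- file.path(out_dir, "splicegraphs")
      if (!dir.exists(gj)) dir.create(gj)
      for (g in g1) splice_graph_to_json(g, file.path(gj, paste0(g$gene_id, ".json")))
    }

    list(graphs = rep_graphs, elements = elements, transcripts = transcripts,
         lsv_table = lsv_table, lsvs_by_gene = lsvs_by_gene,
         fuzzy_table = fz, category_counts = list(junction = cats_j,
                                                  retained_intron = cats_ir),
         annotation = annotation, manifest = manifest)
  }, error = function(e) {
    write_manifest("failed", stage)
    stop("stage ", stage, " failed: ", conditionMessage(e))
  })
  manifest <- res$manifest
  write_manifest("ok")
  res$manifest$status <- "ok"
  invisible(res)
}

#' Generate a synthetic fixture directory
#'
#' Thin wrapper over \code{\link{simulate_dataset}} for scripted use.
#'
#' @param out_dir Output directory.
#' @param config A \code{sim_config}.
#' @return The \code{simulate_dataset} result, invisibly.
#' @export
run_simulate <- function(out_dir, config = sim_config()) {
  res <- simulate_dataset(config, out_dir)
  invisible(res)
}

#' Evaluate a comparison run against simulation ground truth
#'
#' @param run_dir Directory written by \code{\link{run_compare}}.
#' @param truth_dir Directory written by \code{\link{run_simulate}}.
#' @return \code{\link{truth_eval}} result; also writes
#'   \code{recovery.tsv} into \code{run_dir}.
#' @export
run_evaluate <- function(run_dir, truth_dir) {
  read_tsv <- function(p) {
    if (!file.exists(p)) stop("missing file: ", p)
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  elements <- read_tsv(file.path(run_dir, "elements.tsv"))
  transcripts <- read_tsv(file.path(run_dir, "transcripts.tsv"))
  truth_el <- read_tsv(file.path(truth_dir, "truth_elements.tsv"))
  truth_tx <- read_tsv(file.path(truth_dir, "truth_transcripts.tsv"))
  ev <- truth_eval(elements, transcripts, truth_el, truth_tx)
  rec <- data.frame(taxonomy = names(ev),
                    recovery = vapply(ev, `[[`, numeric(1), "recovery"),
                    n = vapply(ev, `[[`, numeric(1), "n"),
                    stringsAsFactors = FALSE)
  write_table_tsv(rec, file.path(run_dir, "recovery.tsv"))
  ev
}
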