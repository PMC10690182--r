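# Shared fixtures, built in code once per test run.

.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

gtf_line <- function(chrom, start, end, strand, gene, tx, count = NULL) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  if (!is.null(count)) attrs <- sprintf('%s read_count "%s";', attrs, count)
  sprintf("%s\tt\texon\t%d\t%d\t.\t%s\t.\t%s", chrom, start, end, strand, attrs)
}

# a small hand-built gene on chr1 (+): two annotated isoforms (exon-2 skip),
# long-read transcripts with an IR exon and a pTSS start, matched SJ rows
# and an IR table row
toy_gene <- function() fixture("toy_gene", function() {
  ann <- write_lines_tmp(c(
    gtf_line("chr1", 101, 200, "+", "G1", "T1"),
    gtf_line("chr1", 301, 400, "+", "G1", "T1"),
    gtf_line("chr1", 501, 600, "+", "G1", "T1"),
    gtf_line("chr1", 701, 800, "+", "G1", "T1"),
    gtf_line("chr1", 101, 200, "+", "G1", "T2"),
    gtf_line("chr1", 501, 600, "+", "G1", "T2"),
    gtf_line("chr1", 701, 800, "+", "G1", "T2")
  ), ".gtf")
  long <- write_lines_tmp(c(
    gtf_line("chr1", 101, 200, "+", "G1", "L1", 4),
    gtf_line("chr1", 301, 400, "+", "G1", "L1", 4),
    gtf_line("chr1", 501, 600, "+", "G1", "L1", 4),
    gtf_line("chr1", 701, 800, "+", "G1", "L1", 4),
    gtf_line("chr1", 101, 200, "+", "G1", "L2", 3),
    gtf_line("chr1", 301, 600, "+", "G1", "L2", 3),
    gtf_line("chr1", 701, 800, "+", "G1", "L2", 3),
    gtf_line("chr1", 150, 200, "+", "G1", "L3", 2),
    gtf_line("chr1", 301, 400, "+", "G1", "L3", 2),
    gtf_line("chr1", 501, 600, "+", "G1", "L3", 2),
    gtf_line("chr1", 701, 800, "+", "G1", "L3", 2)
  ), ".gtf")
  sj <- write_lines_tmp(c(
    "chr1\t201\t300\t1\t1\t1\t15\t3\t40",
    "chr1\t401\t500\t1\t1\t1\t12\t0\t40",
    "chr1\t201\t500\t1\t1\t1\t8\t0\t40",
    "chr1\t601\t700\t1\t1\t1\t20\t1\t40"
  ), ".tab")
  ir <- write_lines_tmp(c(
    "chromosome\tstrand\tintron_start\tintron_end\tsupporting_reads",
    "chr1\t+\t401\t500\t5"
  ), ".tsv")
  annotation <- read_annotation_gtf(ann)
  long_ts <- suppressMessages(read_long_read_gtf(long))
  evidence <- read_ir_table(ir, read_star_sj(sj))
  graph <- build_splice_graph("G1", annotation, evidence, long_ts)
  list(paths = list(ann = ann, long = long, sj = sj, ir = ir),
       annotation = annotation, long_ts = long_ts, evidence = evidence,
       graph = graph)
})

# default-condition synthetic fixture (seed 1) with graphs and LSVs
sim_default <- function() fixture("sim_default", function() {
  dir <- file.path(tempdir(), "lsvcompare_sim_default")
  sim <- simulate_dataset(sim_config(n_genes = 200, seed = 1), dir)
  annotation <- read_annotation_gtf(sim$paths$annotation)
  long_ts <- suppressMessages(read_long_read_gtf(sim$paths$long_gtf))
  long_ts <- assign_long_read_genes(long_ts, annotation)
  evidence <- read_ir_table(sim$paths$ir, read_star_sj(sim$paths$sj))
  genes <- sort(unique(c(annotation$genes$gene_id, long_ts$tx$gene_id)),
                method = "radix")
  graphs <- lapply(genes, function(g)
    suppressWarnings(build_splice_graph(g, annotation, evidence, long_ts)))
  names(graphs) <- genes
  lsvs_by_gene <- lapply(graphs, define_lsvs)
  lsv_table <- do.call(rbind, lapply(genes, function(g)
    quantify_lsvs(graphs[[g]], lsvs_by_gene[[g]], annotation)))
  rownames(lsv_table) <- NULL
  list(sim = sim, annotation = annotation, long_ts = long_ts,
       evidence = evidence, genes = genes, graphs = graphs,
       lsvs_by_gene = lsvs_by_gene, lsv_table = lsv_table)
})

# brute-force spliced 3'-distance by enumerating exonic base positions
brute_force_dist3p <- function(boundary, exons, strand) {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq(exons[i, 1], exons[i, 2])))
  if (!(boundary %in% pos)) return(NA_real_)
  if (strand == "+") sum(pos > boundary) else sum(pos < boundary)
}
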