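test_that("exon chains yield intron intervals", {
  expect_equal(junctions_of(cbind(c(101, 301, 501), c(200, 400, 600))),
               cbind(start = c(201L, 401L), end = c(300L, 500L)))
  expect_equal(nrow(junctions_of(cbind(101, 600))), 0)
  # 1-base intron boundary case
  expect_equal(junctions_of(cbind(c(101, 202), c(200, 300))),
               cbind(start = 201L, end = 201L))
})

test_that("unified graph merges tri-source support with counts", {
  g <- toy_gene()$graph
  e <- g$edges
  j1 <- e[e$kind == "junction" & e$start == 201 & e$end == 300, ]
  expect_true(j1$ann && j1$short && j1$long)  # annotation + SJ + L1/L3
  expect_equal(j1$short_count, 15L)
  expect_equal(j1$long_count, 4 + 3 + 2)      # L1, L2 and L3 contain it

  # IR edge on intron [401,500]: short IR table + spanning exon of L2
  ir <- e[e$kind == "retained_intron", ]
  expect_equal(nrow(ir), 1)
  expect_equal(c(ir$start, ir$end), c(401, 500))
  expect_false(ir$ann)
  expect_true(ir$short && ir$long)
  expect_equal(ir$short_count, 5L)
  expect_equal(ir$long_count, 3)

  # pTSS flag: L3 starts at 150 inside the annotated first exon
  tx <- g$transcripts
  expect_true(tx$ptss[tx$transcript_id == "L3"])
  expect_false(tx$ptes[tx$transcript_id == "L3"])
  expect_false(tx$ptss[tx$transcript_id == "L1"])
})

test_that("short junctions below the read threshold do not give support", {
  tg <- toy_gene()
  g5 <- build_splice_graph("G1", tg$annotation, tg$evidence, tg$long_ts,
                           short_min_reads = 10)
  e <- g5$edges
  # the [201,500] skip junction has 8 short reads: below 10, annotated only
  skip <- e[e$kind == "junction" & e$start == 201 & e$end == 500, ]
  expect_false(skip$short)
  expect_equal(skip$short_count, 0L)
})

test_that("graph construction enforces gene/strand contracts", {
  tg <- toy_gene()
  expect_error(build_splice_graph("NOPE", tg$annotation, tg$evidence, tg$long_ts),
               "unknown")
  bad_long <- tg$long_ts
  bad_long$tx$strand[] <- "-"
  expect_error(build_splice_graph("G1", tg$annotation, tg$evidence, bad_long),
               "contradictory")
})

test_that("pTSS/pTES windows are strand-aware and exact by default", {
  # start inside annotated first exon: putative start
  expect_equal(detect_ptss_ptes(cbind(c(150, 301), c(200, 400)), "+",
                                ann_tss = 101, ann_tes = 400),
               c(ptss = TRUE, ptes = FALSE))
  # exact endpoints
  expect_equal(detect_ptss_ptes(cbind(c(101, 301), c(200, 400)), "+",
                                ann_tss = 101, ann_tes = 400),
               c(ptss = FALSE, ptes = FALSE))
  # window semantics
  expect_equal(detect_ptss_ptes(cbind(c(103, 301), c(200, 400)), "+",
                                ann_tss = 101, ann_tes = 400,
                                boundary_window = 5)[["ptss"]], FALSE)
  # minus strand: 5' end is the highest coordinate
  expect_equal(detect_ptss_ptes(cbind(c(101, 301), c(200, 380)), "-",
                                ann_tss = 400, ann_tes = 101),
               c(ptss = TRUE, ptes = FALSE))
  expect_warning(f <- detect_ptss_ptes(cbind(101, 200), "+", integer(), integer()),
                 "no annotated")
  expect_true(all(f))
})

test_that("undetermined-strand SJ rows resolve by coordinates at build", {
  tg <- toy_gene()
  sj0 <- write_lines_tmp(c(
    "chr1\t201\t300\t0\t1\t1\t15\t3\t40",
    "chr1\t401\t500\t0\t1\t1\t12\t0\t40"
  ), ".tab")
  ev <- read_star_sj(sj0)
  g <- build_splice_graph("G1", tg$annotation, ev, NULL)
  e <- g$edges
  expect_true(e$short[e$start == 201 & e$end == 300 & e$kind == "junction"])
})

test_that("adding a source only adds edges or enlarges support", {
  tg <- toy_gene()
  g_as <- build_splice_graph("G1", tg$annotation, tg$evidence, NULL)
  g_all <- build_splice_graph("G1", tg$annotation, tg$evidence, tg$long_ts)
  key <- function(g) paste(g$edges$kind, g$edges$start, g$edges$end)
  expect_true(all(key(g_as) %in% key(g_all)))
  m <- match(key(g_as), key(g_all))
  for (col in c("ann", "short", "long"))
    expect_true(all(g_all$edges[[col]][m] >= g_as$edges[[col]]))
})

test_that("edge support equals brute-force recomputation from raw inputs on synthetic genes", {
  fx <- sim_default()
  sj <- fx$evidence$junctions
  sj_counts <- stats::setNames(sj$count, sprintf("%d-%d", sj$start, sj$end))
  for (g in fx$genes[seq(1, length(fx$genes), by = 7)]) {
    graph <- fx$graphs[[g]]
    e <- graph$edges[fx$graphs[[g]]$edges$kind == "junction", , drop = FALSE]
    ann_keys <- fx$annotation$index[[g]]$jkeys
    tids <- fx$long_ts$tx$transcript_id[fx$long_ts$tx$gene_id == g]
    long_keys <- unique(unlist(lapply(tids, function(t)
      sprintf("%d-%d", junctions_of(fx$long_ts$exons[[t]])[, 1],
              junctions_of(fx$long_ts$exons[[t]])[, 2]))))
    keys <- paste(e$start, e$end, sep = "-")
    expect_equal(six_category(e),
                 brute_force_category(keys, ann_keys, sj_counts, long_keys))
  }
})

test_that("gene assignment picks the maximal-overlap same-strand gene", {
  ann <- read_annotation_gtf(write_lines_tmp(c(
    gtf_line("chr1", 100, 200, "+", "GB", "TB1"),
    gtf_line("chr1", 400, 500, "+", "GB", "TB1"),
    gtf_line("chr1", 450, 520, "+", "GC", "TC1"),
    gtf_line("chr1", 800, 900, "+", "GC", "TC1")
  ), ".gtf"))
  long <- suppressMessages(read_long_read_gtf(write_lines_tmp(c(
    gtf_line("chr1", 100, 200, "+", "GX", "LX", 3),
    gtf_line("chr1", 400, 500, "+", "GX", "LX", 3)
  ), ".gtf")))
  out <- assign_long_read_genes(long, ann)
  expect_equal(out$tx$gene_id, "GB")
})
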