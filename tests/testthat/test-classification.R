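test_that("six-way categories follow the support subset", {
  mk <- function(a, s, l) data.frame(ann = a, short = s, long = l)
  expect_equal(six_category(mk(TRUE, TRUE, TRUE)), "ALL")
  expect_equal(six_category(mk(FALSE, TRUE, TRUE)), "BOTH_DENOVO")
  expect_equal(six_category(mk(TRUE, TRUE, FALSE)), "SHORT_ANNOT")
  expect_equal(six_category(mk(TRUE, FALSE, TRUE)), "LONG_ANNOT")
  expect_equal(six_category(mk(FALSE, TRUE, FALSE)), "SHORT_ONLY")
  expect_equal(six_category(mk(FALSE, FALSE, TRUE)), "LONG_ONLY")
  expect_equal(six_category(mk(TRUE, FALSE, FALSE)), "NOT_DETECTED")
  expect_error(six_category(mk(FALSE, FALSE, FALSE)), "empty support")
})

test_that("de novo junctions split into novel splice site vs novel combination", {
  idx <- toy_gene()$annotation$index[["G1"]]
  # donor of exon 1 with acceptor of exon 4: both annotated, pair is not
  expect_equal(classify_denovo_junction(201, 700, "+", idx), "NOVEL_COMBINATION")
  # unannotated acceptor position
  expect_equal(classify_denovo_junction(201, 310, "+", idx), "NOVEL_SPLICE_SITE")
  # both sites unannotated
  expect_equal(classify_denovo_junction(211, 310, "+", idx), "NOVEL_SPLICE_SITE")
  # calling it on an annotated junction is a caller bug
  expect_error(classify_denovo_junction(201, 300, "+", idx), "annotated")
})

test_that("novel-splice-site elements are typed by geometry with IR > NEW_EXON precedence", {
  idx <- toy_gene()$annotation$index[["G1"]]
  # donor shifted +12 into exon 1 (novel), acceptor annotated
  expect_equal(classify_novel_ss_type("junction", 189, 300, "+", idx), "ALT_5SS")
  # acceptor shifted, donor annotated
  expect_equal(classify_novel_ss_type("junction", 201, 312, "+", idx), "ALT_3SS")
  # both novel, exonic context
  expect_equal(classify_novel_ss_type("junction", 189, 312, "+", idx), "MIXED")
  # retained introns are IR regardless of context
  expect_equal(classify_novel_ss_type("retained_intron", 401, 500, "+", idx), "IR")
  # exon strictly inside annotated intron [601,700], both boundaries novel:
  # both flanking junctions are NEW_EXON (context transcript supplied)
  ctx <- list(cbind(c(101, 301, 501, 630, 701), c(200, 400, 600, 660, 800)))
  expect_equal(classify_novel_ss_type("junction", 601, 629, "+", idx, ctx),
               "NEW_EXON")
  expect_equal(classify_novel_ss_type("junction", 661, 700, "+", idx, ctx),
               "NEW_EXON")
  expect_error(classify_novel_ss_type("junction", 201, 300, "+", idx),
               "no novel")
})

test_that("strand flips which side is the donor", {
  ann <- read_annotation_gtf(write_lines_tmp(c(
    gtf_line("chr1", 101, 200, "-", "GM", "TM"),
    gtf_line("chr1", 301, 400, "-", "GM", "TM"),
    gtf_line("chr1", 501, 600, "-", "GM", "TM")
  ), ".gtf"))
  idx <- ann$index[["GM"]]
  # on minus strand the donor is the intron end; shifting it gives ALT_5SS
  expect_equal(classify_novel_ss_type("junction", 201, 290, "-", idx), "ALT_5SS")
  expect_equal(classify_novel_ss_type("junction", 211, 300, "-", idx), "ALT_3SS")
})

test_that("long-read transcripts map to Venn classes with VII excluded", {
  tg <- toy_gene()
  idx <- tg$annotation$index[["G1"]]
  g <- tg$graph
  # L1 matches annotation exactly: not a novel transcript
  expect_equal(classify_long_transcript("L1", g, idx)$class, "NONE")
  # L3's only novelty is a truncated first exon: class VII, excluded
  v3 <- classify_long_transcript("L3", g, idx)
  expect_equal(v3$class, "VII")
  expect_true(v3$excluded)
  expect_error(classify_long_transcript("T1", g, idx), "not a long-read")
})

test_that("novel junction plus pTSS lands in a combined Venn class", {
  ann <- read_annotation_gtf(write_lines_tmp(c(
    gtf_line("chr1", 101, 200, "+", "GV", "TV"),
    gtf_line("chr1", 301, 400, "+", "GV", "TV"),
    gtf_line("chr1", 501, 600, "+", "GV", "TV")
  ), ".gtf"))
  long <- suppressMessages(read_long_read_gtf(write_lines_tmp(c(
    gtf_line("chr1", 150, 200, "+", "GV", "LV", 3),
    gtf_line("chr1", 301, 390, "+", "GV", "LV", 3),   # novel donor at 391
    gtf_line("chr1", 501, 600, "+", "GV", "LV", 3)
  ), ".gtf")))
  g <- build_splice_graph("GV", ann, NULL, long)
  v <- classify_long_transcript("LV", g, ann$index[["GV"]])
  expect_true(v$novel_splice_site && v$ptss_ptes && !v$novel_combination)
  expect_equal(v$class, "V")
  expect_false(v$excluded)
})

test_that("six categories plus NOT_DETECTED partition random edge sets and match the oracle", {
  set.seed(99)
  n <- 1500
  subset_id <- sample(1:7, n, replace = TRUE)  # the 7 nonempty subsets
  sup <- cbind(bitwAnd(subset_id, 1L) > 0, bitwAnd(subset_id, 2L) > 0,
               bitwAnd(subset_id, 4L) > 0)
  edges <- data.frame(ann = sup[, 1], short = sup[, 2], long = sup[, 3])
  keys <- sprintf("%d-%d", seq_len(n) * 10L, seq_len(n) * 10L + 5L)
  ann_keys <- keys[edges$ann]
  short_counts <- stats::setNames(
    ifelse(edges$short, 2L + stats::rpois(n, 20), sample(0:1, n, replace = TRUE)),
    keys)
  long_keys <- keys[edges$long]
  got <- six_category(edges)
  oracle <- brute_force_category(keys, ann_keys, short_counts, long_keys,
                                 short_min_reads = 2)
  expect_equal(got, oracle)
  # partition: every edge has exactly one category; totals add up
  tab <- table(factor(got, levels = c("ALL", "BOTH_DENOVO", "SHORT_ANNOT",
                                      "LONG_ANNOT", "SHORT_ONLY", "LONG_ONLY",
                                      "NOT_DETECTED")))
  expect_equal(sum(tab), n)
})

test_that("no element carries both de novo classes", {
  fx <- sim_default()
  els <- do.call(rbind, lapply(fx$graphs, function(g)
    classify_elements(g, fx$annotation)$elements))
  dn <- els$denovo_class[!is.na(els$denovo_class)]
  expect_true(all(dn %in% c("NOVEL_COMBINATION", "NOVEL_SPLICE_SITE")))
  # annotated elements never carry a de novo class
  ann_sup <- els$six_category %in% c("ALL", "SHORT_ANNOT", "LONG_ANNOT", "NOT_DETECTED")
  expect_true(all(is.na(els$denovo_class[ann_sup])))
})
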