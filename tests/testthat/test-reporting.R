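test_that("category counts aggregate replicates with SEM", {
  g <- toy_gene()$graph
  one <- category_counts(list(list(g)), "junction")
  expect_true(all(one$sem == 0))
  expect_equal(sum(one$mean), sum(g$edges$kind == "junction" &
                                    (g$edges$short | g$edges$long)))
  # identical replicates: SEM 0, mean equals the count
  three <- category_counts(list(list(g), list(g), list(g)), "junction")
  expect_true(all(three$sem == 0))
  expect_equal(three$mean, one$mean)
  expect_equal(three$rep2, as.integer(one$mean))
})

test_that("detection-vs-PSI histograms, CDF and missed fraction behave at the limits", {
  psi <- c(0.05, 0.15, 0.25, 0.5, 0.9, NA)
  all_det <- detection_vs_psi(psi, rep(TRUE, 6))
  expect_equal(all_det$missed_fraction, 0)
  none_det <- detection_vs_psi(psi, rep(FALSE, 6))
  expect_equal(none_det$missed_fraction, 1)
  expect_true(all(diff(none_det$cdf$cdf_all) >= 0))
  expect_equal(max(none_det$cdf$cdf_all), 1)
  expect_equal(sum(all_det$table$n_short), 5)  # NA excluded
})

test_that("a configured fraction of hidden high-PSI junctions is recovered as missed", {
  cfg <- sim_config(n_genes = 150, seed = 11, trunc_scale = Inf,
                    full_length_prob = 1, long_depth = 20,
                    long_dropout_rate = 0.1, long_dropout_min_psi = 0.2,
                    p_short_novel = 0)
  s <- simulate_dataset(cfg, file.path(tempdir(), "sim_dropout"))
  ann <- read_annotation_gtf(s$paths$annotation)
  lt <- suppressMessages(read_long_read_gtf(s$paths$long_gtf))
  lt <- assign_long_read_genes(lt, ann)
  ev <- read_ir_table(s$paths$ir, read_star_sj(s$paths$sj))
  genes <- sort(unique(c(ann$genes$gene_id, lt$tx$gene_id)), method = "radix")
  rows <- lapply(genes, function(g) {
    gr <- suppressWarnings(build_splice_graph(g, ann, ev, lt))
    e <- gr$edges
    idx <- which(e$kind == "junction" & e$short)
    if (!length(idx)) return(NULL)
    lsvs <- define_lsvs(gr)
    data.frame(psi = vapply(idx, function(i)
      junction_min_psi(i, lsvs, "short"), numeric(1)),
      det = e$long[idx])
  })
  jj <- do.call(rbind, rows)
  dv <- detection_vs_psi(jj$psi, jj$det)
  expect_equal(dv$missed_fraction, 0.10, tolerance = 0.35)
  expect_gt(sum(!is.na(jj$psi) & jj$psi >= 0.2), 100)
})

test_that("coverage-binned detection fractions hit the limit cases", {
  counts <- c(5, 15, 30, 70, 200)
  same <- detection_vs_coverage(counts, rep(TRUE, 5))
  expect_true(all(same$table$fraction_detected[same$table$n_short > 0] == 1))
  # an empty bin is reported as missing
  few <- detection_vs_coverage(c(5, 15), c(TRUE, FALSE))
  expect_true(is.na(few$table$fraction_detected[few$table$bin == "[100,Inf)"]))
})

test_that("non-quantifiable fractions are 0 when long mirrors short and 1 when absent", {
  lt <- data.frame(short_total = c(15, 30, 60, 150),
                   long_total = c(15, 30, 60, 150),
                   short_quantifiable = TRUE,
                   long_quantifiable = TRUE,
                   dist3p = c(100, 700, 1500, 3000))
  f0 <- nonquantifiable_fractions(lt, "coverage")
  expect_true(all(f0$fraction[f0$n > 0] == 0))
  lt$long_quantifiable <- FALSE
  f1 <- nonquantifiable_fractions(lt, "distance3p")
  expect_true(all(f1$fraction[f1$n > 0] == 1))
})

test_that("IR comparison summarises categories, lengths and detection", {
  g <- toy_gene()$graph
  irc <- ir_comparison(list(g))
  expect_equal(sum(irc$categories$count), 1)
  expect_equal(irc$categories$count[irc$categories$category == "BOTH_DENOVO"], 1)
  # a single event: all quartiles equal its length
  len <- irc$lengths[irc$lengths$category == "BOTH_DENOVO", ]
  expect_equal(len$median, 100)
  expect_equal(len$q1, len$q3)
  # removing the short IR table leaves the event long-only
  tg <- toy_gene()
  ev2 <- tg$evidence
  ev2$introns <- ev2$introns[0, ]
  g2 <- build_splice_graph("G1", tg$annotation, ev2, tg$long_ts)
  irc2 <- ir_comparison(list(g2))
  expect_equal(irc2$categories$count[irc2$categories$category == "LONG_ONLY"], 1)
})

test_that("read-length distribution reports threshold fractions", {
  expect_equal(read_length_distribution(rep(100, 50))$fractions$fraction_ge, 0)
  expect_equal(read_length_distribution(c(2999, 3000, 3001))$fractions$fraction_ge,
               2 / 3)
  set.seed(5)
  x <- stats::rexp(20000, 1 / 1000)
  med <- stats::qexp(0.5, 1 / 1000)
  fr <- read_length_distribution(x, thresholds = med)$fractions$fraction_ge
  expect_equal(fr, 0.5, tolerance = 0.02)
  cdf <- read_length_distribution(x)$cdf
  expect_true(!is.unsorted(cdf$cdf))
})
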