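test_that("beta-binomial posterior matches the conjugate closed form", {
  p <- psi_posterior(c(7, 3))
  expect_equal(p$alpha, c(7.5, 3.5))
  expect_equal(p$beta, c(3.5, 7.5))
  expect_equal(p$mean[1], 7.5 / 11)

  # zero reads return the prior: Beta(1/J, 1 - 1/J), mean 1/J
  p0 <- psi_posterior(c(0, 0, 0))
  expect_equal(p0$alpha, rep(1 / 3, 3))
  expect_equal(p0$beta, rep(2 / 3, 3))
  expect_equal(p0$mean, rep(1 / 3, 3))

  # large-count limit: mean within 1e-3 of 1, and the closed-form mean
  # agrees with numerical integration of the Beta density
  pl <- psi_posterior(c(1000, 0))
  expect_lt(abs(pl$mean[1] - 1), 1e-3)
  num_mean <- stats::integrate(function(x)
    x * stats::dbeta(x, pl$alpha[1], pl$beta[1]), 0, 1)$value
  expect_equal(pl$mean[1], num_mean, tolerance = 1e-6)

  expect_error(psi_posterior(5), "J >= 2")
  expect_error(psi_posterior(c(-1, 3)), "negative")
})

test_that("posterior invariants: normalisation, prior recovery, monotonicity, consistency", {
  set.seed(7)
  for (rep in 1:50) {
    J <- sample(2:6, 1)
    r <- stats::rpois(J, sample(c(0, 3, 40), 1))
    p <- psi_posterior(r)
    expect_lt(abs(sum(p$mean) - 1), 1e-9)
    # raising one count strictly raises its mean
    j <- sample(J, 1)
    r2 <- r; r2[j] <- r2[j] + 5
    expect_gt(psi_posterior(r2)$mean[j], p$mean[j])
  }
  # posterior mean converges to r_j / sum(r)
  r <- c(7000, 3000)
  expect_lt(max(abs(psi_posterior(r)$mean - r / sum(r))), 1e-3)
})

test_that("short-read PSI uses the same posterior machinery", {
  toy <- toy_gene()
  lsvs <- define_lsvs(toy$graph)
  expect_equal(psi_posterior(c(30, 10))$mean, c(30.5 / 41, 10.5 / 41))
  expect_equal(psi_posterior(c(0, 0))$mean, c(0.5, 0.5))
  expect_equal(psi_posterior(c(10, 0, 0, 0))$mean[1], 10.25 / 11)
  # graph-backed short/long PSI agree with direct substitution
  l <- lsvs[[1]]
  expect_equal(lsv_psi(l, "short")$mean,
               psi_posterior(l$r_short)$mean)
})

test_that("LSV definition: splits at reference exons, IR elements included, linear genes empty", {
  g <- toy_gene()$graph
  lsvs <- define_lsvs(g)
  ids <- names(lsvs)
  # source LSV at exon 1 (two detected junctions leave it: skip + inclusion)
  src1 <- lsvs[[grep("101-200:s", ids)]]
  expect_equal(src1$J, 2)
  expect_equal(src1$direction, "source")
  # source LSV at exon 2 contains the junction [401,500] and the IR edge
  src2 <- lsvs[[grep("301-400:s", ids)]]
  expect_equal(src2$J, 2)
  expect_setequal(g$edges$kind[src2$edge_idx], c("junction", "retained_intron"))

  # a strictly linear gene has no LSVs
  ann <- read_annotation_gtf(write_lines_tmp(c(
    gtf_line("chr1", 101, 200, "+", "GL", "TL"),
    gtf_line("chr1", 301, 400, "+", "GL", "TL"),
    gtf_line("chr1", 501, 600, "+", "GL", "TL")
  ), ".gtf"))
  sj <- read_star_sj(write_lines_tmp(c(
    "chr1\t201\t300\t1\t1\t1\t30\t0\t40",
    "chr1\t401\t500\t1\t1\t1\t25\t0\t40"
  ), ".tab"))
  gl <- build_splice_graph("GL", ann, sj, NULL)
  expect_length(define_lsvs(gl), 0)
})

test_that("quantifiability boundary sits exactly at the read threshold", {
  mk_lsv <- function(r_short, r_long) structure(list(
    lsv_id = "x", gene_id = "g", ref_exon = c(start = 1, end = 2),
    direction = "source", edge_idx = seq_along(r_short),
    J = length(r_short), r_short = r_short, r_long = r_long), class = "lsv")
  expect_true(is_quantifiable(mk_lsv(c(5, 5), c(0, 0)), "short"))
  expect_false(is_quantifiable(mk_lsv(c(5, 4), c(0, 0)), "short"))
  expect_true(is_quantifiable(mk_lsv(c(0, 0), c(6, 4)), "long"))
  expect_false(is_quantifiable(mk_lsv(c(0, 0), c(5, 4)), "long"))
  expect_true(is_quantifiable(mk_lsv(c(0, 0), c(0, 0)), "short", min_reads = 0))
  expect_error(is_quantifiable(mk_lsv(c(5, 5), c(0, 0)), "neither"))
})

test_that("a junction in several quantifiable LSVs reports its lowest PSI", {
  g <- toy_gene()$graph
  lsvs <- define_lsvs(g)
  # junction [201,500] (skip) appears in a source LSV at exon 1 and a
  # target LSV at exon 3; minimum of the two short PSI means is reported
  eidx <- which(g$edges$kind == "junction" & g$edges$start == 201 &
                g$edges$end == 500)
  vals <- vapply(lsvs, function(l) {
    pos <- match(eidx, l$edge_idx)
    if (is.na(pos) || !is_quantifiable(l, "short")) NA_real_
    else lsv_psi(l, "short")$mean[pos]
  }, numeric(1))
  expect_equal(junction_min_psi(eidx, lsvs, "short"), min(vals, na.rm = TRUE))
  # an edge present in no LSV is excluded
  expect_true(is.na(junction_min_psi(999L, lsvs, "short")))
})

test_that("spliced 3' distance sums exon lengths and takes the transcript minimum", {
  # two-exon tail of lengths 120 + 80 after the reference exon
  ann <- read_annotation_gtf(write_lines_tmp(c(
    gtf_line("chr1", 101, 200, "+", "GD", "TD1"),
    gtf_line("chr1", 301, 420, "+", "GD", "TD1"),
    gtf_line("chr1", 521, 600, "+", "GD", "TD1"),
    # second transcript ends right after the reference exon
    gtf_line("chr1", 101, 200, "+", "GD", "TD2"),
    gtf_line("chr1", 301, 320, "+", "GD", "TD2")
  ), ".gtf"))
  mk <- function(dir) structure(list(
    lsv_id = "x", gene_id = "GD", ref_exon = c(start = 101, end = 200),
    direction = dir, edge_idx = 1:2, J = 2,
    r_short = c(1, 1), r_long = c(1, 1)), class = "lsv")
  graph <- list(strand = "+")
  # TD1 tail: 120 + 80 = 200; TD2 tail: 20; conservative minimum
  expect_equal(distance_to_3prime(mk("source"), graph, ann), 20)
  ann1 <- ann
  ann1$tx <- ann1$tx[ann1$tx$transcript_id == "TD1", ]
  expect_equal(distance_to_3prime(mk("source"), graph, ann1), 200)
  # LSV on the 3'-terminal exon: distance bounded by that exon's length
  mk3 <- structure(list(lsv_id = "x", gene_id = "GD",
                        ref_exon = c(start = 521, end = 600),
                        direction = "target", edge_idx = 1:2, J = 2,
                        r_short = c(1, 1), r_long = c(1, 1)), class = "lsv")
  expect_lte(distance_to_3prime(mk3, graph, ann1), 80)
})

test_that("spliced 3' distance equals brute-force position enumeration", {
  set.seed(11)
  for (rep in 1:100) {
    strand <- sample(c("+", "-"), 1)
    n <- sample(2:6, 1)
    w <- sample(15:40, n, replace = TRUE)
    gaps <- sample(10:60, n, replace = TRUE)
    start <- cumsum(gaps + c(0, w[-n] + 1)) + 100
    exo <- cbind(start = start, end = start + w - 1)
    # boundary at a random exon edge
    i <- sample(n, 1)
    b <- unname(if (sample(c(TRUE, FALSE), 1)) exo[i, 1] else exo[i, 2])
    ann <- list(tx = data.frame(transcript_id = "T", gene_id = "G"),
                exons = list(T = exo))
    lsv <- structure(list(gene_id = "G",
                          ref_exon = c(start = b, end = b),
                          direction = "source"), class = "lsv")
    graph <- list(strand = strand)
    lsv$direction <- if (strand == "+") "source" else "target"  # boundary = end = b
    lsv$ref_exon <- c(start = b, end = b)
    expect_equal(distance_to_3prime(lsv, graph, ann),
                 brute_force_dist3p(b, exo, strand))
  }
})

test_that("IR PSI applies the minimum-PSI and minimum-reads rules", {
  # intron with 12 long reads against a 4-read junction: mean 12.5/17
  expect_equal(psi_posterior(c(12, 4))$mean[1], 12.5 / 17)
  g <- toy_gene()$graph
  lsvs <- define_lsvs(g)
  ir_idx <- which(g$edges$kind == "retained_intron")
  # long counts on that LSV: junction 4 (L1) + ir 3 (L2) = 7 < 10: excluded
  expect_true(is.na(ir_psi(ir_idx, lsvs, "long")))
  # short counts 12 + 5 = 17 >= 10: reported
  short_val <- ir_psi(ir_idx, lsvs, "short")
  expect_false(is.na(short_val))
  expect_equal(short_val,
               min(vapply(lsvs, function(l) {
                 pos <- match(ir_idx, l$edge_idx)
                 if (is.na(pos) || sum(l$r_short) < 10) NA_real_
                 else lsv_psi(l, "short")$mean[pos]
               }, numeric(1)), na.rm = TRUE))
})
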