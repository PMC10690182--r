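#' Simulation configuration for matched annotation/short/long inputs
#'
#' Builds the configuration object for \code{\link{simulate_dataset}}. The
#' defaults describe a desk-scale transcriptome with the qualitative
#' structure of matched short/long-read data: log-normal isoform
#' expression, negative-binomial short-read junction counts scaled by true
#' inclusion, Poisson long-read counts, a 3'-anchored exponential
#' truncation model for long reads (junctions far from the TES in spliced
#' nt are covered less), and per-class novelty injection (alternative
#' 5'/3' splice sites, novel combinations, new exons, retained introns,
#' short-only de novo junctions, pTES-shifted transcripts).
#'
#' @param n_genes Number of genes (default 200).
#' @param seed Random seed; identical seeds give byte-identical outputs.
#' @param exons_per_gene,exon_len,intron_len Integer ranges (min, max).
#' @param expr_meanlog,expr_sdlog Log-normal isoform expression.
#' @param short_mu,short_size Negative-binomial short junction counts:
#'   mean \code{short_mu * inclusion}, dispersion \code{short_size}.
#' @param long_depth Long-read depth multiplier: isoform reads ~
#'   Poisson(\code{long_depth} * expression * weight).
#' @param full_length_prob Probability a long read is full length.
#' @param trunc_scale Exponential truncation scale in spliced nt measured
#'   from the 3' end; \code{Inf} disables truncation.
#' @param p_skip_isoform Probability of a second annotated (exon-skipping)
#'   isoform, the backbone of each gene's LSVs.
#' @param p_alt5,p_alt3,p_mixed,p_novel_comb_long,p_new_exon,p_ir_long
#'   Per-gene injection probabilities of long-read novelty classes.
#' @param p_ir_short,p_ir_annot Probabilities of a short-read IR event and
#'   of an annotated retained-intron isoform.
#' @param p_short_novel Probability of a short-only de novo junction;
#'   \code{short_novel_ss_frac} of these involve a novel splice site, the
#'   rest a novel combination.
#' @param p_short_sees_long_novel Probability a long-injected novel
#'   junction is also present in the short-read junction table.
#' @param p_ptes Probability an isoform's emitted transcripts carry a
#'   shifted 3' end (pTES).
#' @param novel_shift Range (min, max) of splice-site shifts in nt for
#'   alternative-splice-site novelties.
#' @param long_dropout_rate,long_dropout_min_psi Fraction of junctions
#'   with true inclusion above \code{long_dropout_min_psi} hidden from
#'   long reads (isoforms containing them emit no reads).
#' @param short_min_reads,long_min_count,lsv_min_reads Detection and
#'   quantifiability thresholds mirrored in the ground-truth labels.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 200, seed = 1,
                       exons_per_gene = c(6, 15),
                       exon_len = c(100, 400), intron_len = c(200, 2500),
                       expr_meanlog = log(12), expr_sdlog = 0.7,
                       short_mu = 40, short_size = 5,
                       long_depth = 1,
                       full_length_prob = 0.05, trunc_scale = 1000,
                       p_skip_isoform = 0.8,
                       p_alt5 = 0.08, p_alt3 = 0.08, p_mixed = 0.05,
                       p_novel_comb_long = 0.1, p_new_exon = 0.08,
                       p_ir_long = 0.5, p_ir_short = 0.1, p_ir_annot = 0.05,
                       p_short_novel = 0.25, short_novel_ss_frac = 0.9,
                       p_short_sees_long_novel = 0.4,
                       p_ptes = 0.08,
                       novel_shift = c(3, 10),
                       long_dropout_rate = 0, long_dropout_min_psi = 0,
                       short_min_reads = 2, long_min_count = 1,
                       lsv_min_reads = 10) {
  cfg <- as.list(environment())
  rates <- c(cfg$p_skip_isoform, cfg$p_alt5, cfg$p_alt3, cfg$p_mixed,
             cfg$p_novel_comb_long, cfg$p_new_exon, cfg$p_ir_long,
             cfg$p_ir_short, cfg$p_ir_annot, cfg$p_short_novel,
             cfg$short_novel_ss_frac, cfg$p_short_sees_long_novel,
             cfg$p_ptes, cfg$long_dropout_rate, cfg$full_length_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  if (cfg$trunc_scale <= 0) stop("trunc_scale must be positive (Inf disables)")
  if (cfg$exon_len[1] < 30) stop("exons must allow splice-site shifts (min length 30)")
  structure(cfg, class = "sim_config")
}

# transcription-ordered exon widths and per-junction spliced distance from
# the TES (exonic bases strictly 3' of the junction)
.spliced_layout <- function(exons, strand) {
  w <- exons[, 2] - exons[, 1] + 1L
  if (strand == "-") w <- rev(w)
  n <- length(w)
  S <- if (n > 1) rev(cumsum(rev(w)))[-1] else numeric(0)  # S_m = sum w[(m+1):n]
  list(w = w, L = sum(w), S = S)
}

# suffix chain covering the last k junctions (k+1 terminal exons in
# transcription direction), as a genomic-sorted exon matrix
.suffix_chain <- function(exons, strand, k) {
  n <- nrow(exons)
  take <- k + 1L
  if (strand == "+") exons[(n - take + 1L):n, , drop = FALSE]
  else exons[1:take, , drop = FALSE]
}

.chain_key <- function(exons) paste(exons[, 1], exons[, 2], sep = "-", collapse = ";")

# split an exon chain at hidden junctions into maximal fragments
.split_chain <- function(exons, hidden_keys) {
  n <- nrow(exons)
  if (length(hidden_keys) == 0 || n < 2) return(list(exons))
  jk <- .ikey(junctions_of(exons))
  brk <- which(jk %in% hidden_keys)
  if (length(brk) == 0) return(list(exons))
  bounds <- c(0L, brk, n)
  lapply(seq_len(length(bounds) - 1L), function(i)
    exons[(bounds[i] + 1L):bounds[i + 1L], , drop = FALSE])
}

#' Simulate a matched annotation / short-read / long-read dataset
#'
#' Generates the three input dialects (annotation GTF; long-read GTF with
#' read_count attributes plus a sidecar counts TSV; STAR-format SJ.out.tab
#' and an IR TSV) together with ground-truth labels for every detected
#' element (six-way category, de novo class, novel-splice-site type) and
#' every emitted long-read transcript (Venn class, pTSS/pTES), plus the
#' true PSI of each gene's exon-skipping event and the spliced lengths of
#' all simulated long reads. Ground-truth support labels are derived from
#' the realised draws with the thresholds in the configuration, so labels
#' are consistent with the emitted files by construction.
#'
#' @param config A \code{sim_config}.
#' @param dir Output directory (created if needed).
#' @return List with \code{paths} (named file paths), \code{truth}
#'   (elements / transcripts / lsvs data frames) and \code{config}.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("simdata")) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister")

  ann_rows <- list()     # annotation GTF exon rows
  long_rows <- list()    # long-read GTF exon rows
  long_counts <- list()  # transcript_id -> count
  sj_rows <- list()
  ir_rows <- list()
  truth_el <- list()
  truth_tx <- list()
  truth_lsv <- list()
  read_lengths <- numeric()

  cursor <- 10000L
  for (g in seq_len(config$n_genes)) {
    gene <- sprintf("G%04d", g)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
    ex_w <- sample(config$exon_len[1]:config$exon_len[2], n_ex, replace = TRUE)
    in_w <- sample(config$intron_len[1]:config$intron_len[2], n_ex - 1, replace = TRUE)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor
    for (i in seq_len(n_ex)) {
      starts[i] <- pos; ends[i] <- pos + ex_w[i] - 1L
      pos <- ends[i] + (if (i < n_ex) in_w[i] else 0L) + 1L
    }
    exons1 <- cbind(start = starts, end = ends)
    cursor <- ends[n_ex] + 10000L

    gb <- .simulate_gene(gene, strand, exons1, config)

    ann_rows[[gene]] <- gb$ann_rows
    long_rows[[gene]] <- gb$long_rows
    long_counts[[gene]] <- gb$long_counts
    sj_rows[[gene]] <- gb$sj_rows
    ir_rows[[gene]] <- gb$ir_rows
    truth_el[[gene]] <- gb$truth_el
    truth_tx[[gene]] <- gb$truth_tx
    truth_lsv[[gene]] <- gb$truth_lsv
    read_lengths <- c(read_lengths, gb$read_lengths)
  }

  paths <- list(
    annotation = file.path(dir, "annotation.gtf"),
    long_gtf = file.path(dir, "long_reads.gtf"),
    long_counts = file.path(dir, "long_counts.tsv"),
    sj = file.path(dir, "SJ.out.tab"),
    ir = file.path(dir, "ir.tsv"),
    truth_elements = file.path(dir, "truth_elements.tsv"),
    truth_transcripts = file.path(dir, "truth_transcripts.tsv"),
    truth_lsvs = file.path(dir, "truth_lsvs.tsv"),
    read_lengths = file.path(dir, "read_lengths.txt")
  )

  .write_gtf(do.call(rbind, unname(ann_rows)), paths$annotation, counts = FALSE)
  lr <- do.call(rbind, unname(long_rows))
  .write_gtf(lr, paths$long_gtf, counts = TRUE)
  lc <- do.call(rbind, unname(lapply(unname(long_counts), function(x)
    data.frame(transcript_id = names(x), count = as.numeric(x),
               stringsAsFactors = FALSE))))
  utils::write.table(lc, paths$long_counts, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sj <- do.call(rbind, unname(sj_rows))
  utils::write.table(sj, paths$sj, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ir <- do.call(rbind, unname(ir_rows))
  if (is.null(ir)) ir <- data.frame(chromosome = character(), strand = character(),
                                    intron_start = integer(), intron_end = integer(),
                                    supporting_reads = integer())
  utils::write.table(ir, paths$ir, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  truth <- list(
    elements = do.call(rbind, unname(truth_el)),
    transcripts = do.call(rbind, unname(truth_tx)),
    lsvs = do.call(rbind, unname(truth_lsv))
  )
  for (nm in names(truth)) rownames(truth[[nm]]) <- NULL
  write_table_tsv(truth$elements, paths$truth_elements)
  write_table_tsv(truth$transcripts, paths$truth_transcripts)
  write_table_tsv(truth$lsvs, paths$truth_lsvs)
  writeLines(format(read_lengths, trim = TRUE, scientific = FALSE),
             paths$read_lengths)
  list(paths = paths, truth = truth, config = config, dir = dir)
}

# one gene's worth of simulation; returns emitted rows plus realised truth
.simulate_gene <- function(gene, strand, exons1, config) {
  chrom <- "chr1"
  n_ex <- nrow(exons1)
  ann_iso <- list(T1 = exons1)
  skip_k <- NA_integer_
  if (n_ex >= 4 && stats::runif(1) < config$p_skip_isoform) {
    skip_k <- sample(2:(n_ex - 1), 1)
    ann_iso$T2 <- exons1[-skip_k, , drop = FALSE]
  }
  # pools of internal positions available for injections
  intron_pool <- setdiff(seq_len(n_ex - 1), c(skip_k - 1L, skip_k))
  intron_pool <- intron_pool[intron_pool >= 2 & intron_pool <= n_ex - 2]
  junc_pool <- intron_pool
  draw_intron <- function() {
    if (length(intron_pool) == 0) return(NA_integer_)
    i <- intron_pool[sample.int(length(intron_pool), 1)]
    intron_pool <<- setdiff(intron_pool, i)
    junc_pool <<- setdiff(junc_pool, i)
    i
  }

  ann_ir_intron <- NA_integer_
  if (stats::runif(1) < config$p_ir_annot) {
    i <- draw_intron()
    if (!is.na(i)) {
      ann_ir_intron <- i
      merged <- exons1
      merged[i, 2] <- merged[i + 1, 2]
      ann_iso$T3 <- merged[-(i + 1), , drop = FALSE]
    }
  }

  ann_sites_start <- integer(); ann_sites_end <- integer()
  ann_jmat <- matrix(integer(), 0, 2)
  for (exo in ann_iso) ann_jmat <- rbind(ann_jmat, junctions_of(exo))
  ann_jmat <- unique(ann_jmat)
  ann_keys <- .ikey(ann_jmat)
  ann_sites_start <- unique(ann_jmat[, 1])
  ann_sites_end <- unique(ann_jmat[, 2])
  ann_tss <- unique(vapply(ann_iso, function(e)
    if (strand == "+") e[1, 1] else e[nrow(e), 2], numeric(1)))
  ann_tes <- unique(vapply(ann_iso, function(e)
    if (strand == "+") e[nrow(e), 2] else e[1, 1], numeric(1)))
  ann_exmat <- unique(do.call(rbind, unname(ann_iso)))

  shift_draw <- function() sample(config$novel_shift[1]:config$novel_shift[2], 1)
  site_free <- function(s, side) {
    if (side == "start") !(s %in% ann_sites_start) else !(s %in% ann_sites_end)
  }

  # --- long-read novelty isoforms ---------------------------------------
  novel_iso <- list()   # name -> exon matrix
  novel_meta <- list()  # name -> list(type, junctions recorded)
  add_alt <- function(type) {
    j <- if (length(junc_pool)) junc_pool[sample.int(length(junc_pool), 1)] else NA
    if (is.na(j)) return(invisible(NULL))
    junc_pool <<- setdiff(junc_pool, j)
    exo <- exons1
    d <- shift_draw()
    ok <- TRUE
    do_start <- switch(type, ALT_5SS = strand == "+", ALT_3SS = strand == "-",
                       MIXED = TRUE)
    do_end <- switch(type, ALT_5SS = strand == "-", ALT_3SS = strand == "+",
                     MIXED = TRUE)
    if (do_start) {  # move intron start by shrinking exon j
      new_site <- exo[j, 2] - d + 1L
      if (!site_free(new_site, "start") || exo[j, 2] - d - exo[j, 1] < 20) ok <- FALSE
      else exo[j, 2] <- exo[j, 2] - d
    }
    if (ok && do_end) {  # move intron end by shrinking exon j+1
      new_site <- exo[j + 1, 1] + d - 1L
      if (!site_free(new_site, "end") || exo[j + 1, 2] - (exo[j + 1, 1] + d) < 20) ok <- FALSE
      else exo[j + 1, 1] <- exo[j + 1, 1] + d
    }
    if (!ok) return(invisible(NULL))
    nm <- sprintf("N%s", type)
    novel_iso[[nm]] <<- exo
    novel_meta[[nm]] <<- list(type = type,
                              junction = c(exo[j, 2] + 1L, exo[j + 1, 1] - 1L))
  }
  if (stats::runif(1) < config$p_alt5) add_alt("ALT_5SS")
  if (stats::runif(1) < config$p_alt3) add_alt("ALT_3SS")
  if (stats::runif(1) < config$p_mixed) add_alt("MIXED")
  if (n_ex >= 5 && stats::runif(1) < config$p_novel_comb_long) {
    a <- sample(seq_len(n_ex - 3), 1)
    key <- sprintf("%d-%d", exons1[a, 2] + 1L, exons1[a + 3, 1] - 1L)
    if (!(key %in% ann_keys)) {
      novel_iso$NCOMB <- exons1[-c(a + 1, a + 2), , drop = FALSE]
      novel_meta$NCOMB <- list(type = "NOVEL_COMBINATION",
                               junction = c(exons1[a, 2] + 1L, exons1[a + 3, 1] - 1L))
    }
  }
  if (stats::runif(1) < config$p_new_exon) {
    i <- draw_intron()
    if (!is.na(i)) {
      gap_lo <- exons1[i, 2] + 1L; gap_hi <- exons1[i + 1, 1] - 1L
      if (gap_hi - gap_lo > 200) {
        ns <- gap_lo + 50L + sample.int(50L, 1)
        ne <- ns + 60L + sample.int(40L, 1)
        if (site_free(ns - 1L, "end") && site_free(ne + 1L, "start") &&
            ne < gap_hi - 20L) {
          exo <- rbind(exons1[1:i, , drop = FALSE],
                       c(ns, ne),
                       exons1[(i + 1):n_ex, , drop = FALSE])
          novel_iso$NEWEX <- exo
          novel_meta$NEWEX <- list(type = "NEW_EXON", exon = c(ns, ne),
                                   junctions = rbind(c(exons1[i, 2] + 1L, ns - 1L),
                                                     c(ne + 1L, exons1[i + 1, 1] - 1L)))
        }
      }
    }
  }
  ir_long_intron <- NA_integer_
  if (stats::runif(1) < config$p_ir_long) {
    i <- draw_intron()
    if (!is.na(i)) {
      ir_long_intron <- i
      merged <- exons1
      merged[i, 2] <- merged[i + 1, 2]
      novel_iso$NIR <- merged[-(i + 1), , drop = FALSE]
      novel_meta$NIR <- list(type = "IR",
                             intron = c(exons1[i, 2] + 1L, exons1[i + 1, 1] - 1L))
    }
  }

  # --- short-only evidence ----------------------------------------------
  short_extra <- list()  # list of c(start, end, count)
  if (stats::runif(1) < config$p_short_novel) {
    if (stats::runif(1) < config$short_novel_ss_frac) {
      j <- if (length(junc_pool)) junc_pool[sample.int(length(junc_pool), 1)] else NA
      if (!is.na(j)) {
        junc_pool <- setdiff(junc_pool, j)
        d <- shift_draw()
        s <- exons1[j, 2] + 1L - d
        e <- exons1[j + 1, 1] - 1L
        if (site_free(s, "start"))
          short_extra[[length(short_extra) + 1]] <-
            c(s, e, config$short_min_reads +
                stats::rnbinom(1, mu = config$short_mu / 2, size = config$short_size))
      }
    } else if (n_ex >= 5) {
      a <- sample(seq_len(n_ex - 3), 1)
      s <- exons1[a, 2] + 1L; e <- exons1[a + 3, 1] - 1L
      if (!(sprintf("%d-%d", s, e) %in% ann_keys) &&
          !("NCOMB" %in% names(novel_meta) &&
            all(novel_meta$NCOMB$junction == c(s, e))))
        short_extra[[length(short_extra) + 1]] <-
          c(s, e, config$short_min_reads +
              stats::rnbinom(1, mu = config$short_mu / 2, size = config$short_size))
    }
  }
  ir_short_intron <- NA_integer_
  if (stats::runif(1) < config$p_ir_short) {
    if (!is.na(ir_long_intron) && stats::runif(1) < 0.5) {
      ir_short_intron <- ir_long_intron
    } else {
      i <- draw_intron()
      if (!is.na(i)) ir_short_intron <- i
    }
  }

  # --- expression, PSI, counts ------------------------------------------
  E <- stats::rlnorm(1, config$expr_meanlog, config$expr_sdlog)
  psi <- if (stats::runif(1) < 0.5) stats::rbeta(1, 0.2, 0.8) else stats::rbeta(1, 0.8, 0.2)
  iso_names <- c(names(ann_iso), names(novel_iso))
  w <- stats::setNames(numeric(length(iso_names)), iso_names)
  if ("T2" %in% iso_names) { w["T1"] <- psi; w["T2"] <- 1 - psi } else w["T1"] <- 1
  for (nm in names(novel_iso)) w[nm] <- stats::runif(1, 0.05, 0.3)
  if ("T3" %in% iso_names) w["T3"] <- stats::runif(1, 0.05, 0.3)
  w <- w / sum(w)
  iso_all <- c(ann_iso, novel_iso)

  # per-junction true inclusion = summed weight of isoforms containing it
  all_jkeys <- unique(unlist(lapply(iso_all, function(e) .ikey(junctions_of(e)))))
  incl <- stats::setNames(numeric(length(all_jkeys)), all_jkeys)
  for (nm in names(iso_all))
    for (k in .ikey(junctions_of(iso_all[[nm]]))) incl[k] <- incl[k] + w[nm]

  # long-read dropout: hidden junctions never appear in emitted transcript
  # models; chains covering one are split into fragment models, so the
  # visibility of every other junction is unaffected
  hidden <- character()
  if (config$long_dropout_rate > 0) {
    cand <- names(incl)[incl > config$long_dropout_min_psi]
    hidden <- cand[stats::runif(length(cand)) < config$long_dropout_rate]
  }

  # short-read counts: annotated + long novel junctions (the latter seen
  # with probability p_short_sees_long_novel)
  sj_counts <- stats::setNames(integer(0), character())
  for (k in all_jkeys) {
    seen <- k %in% ann_keys || stats::runif(1) < config$p_short_sees_long_novel
    if (!seen) next
    cnt <- stats::rnbinom(1, mu = config$short_mu * incl[k], size = config$short_size)
    if (cnt >= 1) sj_counts[k] <- cnt
  }
  for (x in short_extra) sj_counts[sprintf("%d-%d", x[1], x[2])] <- x[3]

  ir_tab <- list()
  if (!is.na(ir_short_intron)) {
    iv <- c(exons1[ir_short_intron, 2] + 1L, exons1[ir_short_intron + 1, 1] - 1L)
    ir_tab[[1]] <- c(iv, 1L + stats::rnbinom(1, mu = 10, size = 5))
  }

  # --- long-read emission with 3'-anchored truncation -------------------
  emitted <- list()  # chain key -> list(exons, count)
  read_lengths <- numeric()
  ptes_iso <- names(iso_all)[stats::runif(length(iso_all)) < config$p_ptes]
  for (nm in names(iso_all)) {
    exo <- iso_all[[nm]]
    if (nm %in% ptes_iso) {  # shifted 3' end: shorten the terminal exon
      d3 <- 20L + sample.int(60L, 1)
      if (strand == "+") exo[nrow(exo), 2] <- exo[nrow(exo), 2] - d3
      else exo[1, 1] <- exo[1, 1] + d3
    }
    n_reads <- stats::rpois(1, config$long_depth * E * w[nm])
    if (n_reads == 0) next
    lay <- .spliced_layout(exo, strand)
    full <- stats::runif(n_reads) < config$full_length_prob
    Tlen <- ifelse(full, lay$L,
                   pmin(lay$L, ceiling(stats::rexp(n_reads, 1 / config$trunc_scale))))
    if (is.infinite(config$trunc_scale)) Tlen <- rep(lay$L, n_reads)
    read_lengths <- c(read_lengths, Tlen)
    k <- vapply(Tlen, function(t) sum(lay$S < t), integer(1))
    for (kk in sort(unique(k))) {
      chain <- .suffix_chain(exo, strand, kk)
      for (frag in .split_chain(chain, hidden)) {
        key <- .chain_key(frag)
        if (is.null(emitted[[key]])) emitted[[key]] <- list(exons = frag, count = 0L)
        emitted[[key]]$count <- emitted[[key]]$count + sum(k == kk)
      }
    }
  }
  if (length(emitted) > 0)
    emitted <- emitted[order(names(emitted), method = "radix")]

  # --- assemble output rows ---------------------------------------------
  gtf_rows <- function(iso_list, counts = NULL) {
    out <- list()
    for (nm in names(iso_list)) {
      exo <- iso_list[[nm]]
      tid <- sprintf("%s.%s", gene, nm)
      out[[nm]] <- data.frame(chrom = chrom, start = exo[, 1], end = exo[, 2],
                              strand = strand, gene_id = gene,
                              transcript_id = tid,
                              read_count = if (is.null(counts)) NA_real_ else counts[[nm]],
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  ann_rows <- gtf_rows(ann_iso)
  em_names <- sprintf("LR%03d", seq_along(emitted))
  names(emitted) <- NULL
  em_list <- stats::setNames(lapply(emitted, `[[`, "exons"), em_names)
  em_counts <- stats::setNames(lapply(emitted, `[[`, "count"), em_names)
  long_rows <- if (length(em_list)) gtf_rows(em_list, counts = em_counts) else NULL
  long_counts <- stats::setNames(
    as.numeric(unlist(em_counts)),
    sprintf("%s.%s", gene, em_names))
  if (length(em_list) == 0) long_counts <- stats::setNames(numeric(0), character(0))

  sj_keys <- names(sj_counts)
  sj_rows <- NULL
  if (length(sj_keys) > 0) {
    km <- .key_mat(sj_keys)
    ord <- order(km[, 1], km[, 2])
    sj_rows <- data.frame(chrom = chrom, start = km[ord, 1], end = km[ord, 2],
                          strand_code = if (strand == "+") 1L else 2L,
                          motif = 1L,
                          annotated = as.integer(sj_keys[ord] %in% ann_keys),
                          unique_reads = as.integer(sj_counts[ord]),
                          multi_reads = 0L, overhang = 40L,
                          stringsAsFactors = FALSE)
  }
  ir_rows <- NULL
  if (length(ir_tab) > 0) {
    ir_rows <- data.frame(chromosome = chrom, strand = strand,
                          intron_start = ir_tab[[1]][1], intron_end = ir_tab[[1]][2],
                          supporting_reads = ir_tab[[1]][3],
                          stringsAsFactors = FALSE)
  }

  truth <- .gene_truth(gene, chrom, strand, config,
                       ann_keys = ann_keys, ann_jmat = ann_jmat,
                       ann_sites_start = ann_sites_start,
                       ann_sites_end = ann_sites_end,
                       ann_tss = ann_tss, ann_tes = ann_tes,
                       ann_exmat = ann_exmat,
                       sj_counts = sj_counts, ir_tab = ir_tab,
                       emitted_exons = em_list, emitted_counts = em_counts)
  truth_lsv <- NULL
  if ("T2" %in% names(ann_iso)) {
    truth_lsv <- data.frame(gene_id = gene,
                            ref_start = exons1[skip_k - 1, 1],
                            ref_end = exons1[skip_k - 1, 2],
                            psi_inclusion = psi, stringsAsFactors = FALSE)
  }
  list(ann_rows = ann_rows, long_rows = long_rows, long_counts = long_counts,
       sj_rows = sj_rows, ir_rows = ir_rows,
       truth_el = truth$elements, truth_tx = truth$transcripts,
       truth_lsv = truth_lsv, read_lengths = read_lengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# realised ground-truth labels, derived from the emitted draws with the
# same definitions the pipeline implements (set logic over annotated
# sites/junctions and emitted chains)
.gene_truth <- function(gene, chrom, strand, config, ann_keys, ann_jmat,
                        ann_sites_start, ann_sites_end, ann_tss, ann_tes,
                        ann_exmat, sj_counts, ir_tab, emitted_exons,
                        emitted_counts) {
  long_keys <- unique(unlist(lapply(emitted_exons, function(e) .ikey(junctions_of(e)))))
  if (is.null(long_keys)) long_keys <- character()
  sj_det <- names(sj_counts)[sj_counts >= config$short_min_reads]
  all_j <- unique(c(ann_keys, sj_det, long_keys))

  donor_known <- function(s, e) {
    if (strand == "+") s %in% ann_sites_start else e %in% ann_sites_end
  }
  acceptor_known <- function(s, e) {
    if (strand == "+") e %in% ann_sites_end else s %in% ann_sites_start
  }
  new_exon_geom <- function(s, e) {
    for (exo in emitted_exons) {
      jm <- junctions_of(exo)
      if (nrow(jm) == 0) next
      hit <- which(jm[, 1] == s & jm[, 2] == e)
      for (h in hit) for (exi in c(h, h + 1L)) {
        if (exi <= 1L || exi >= nrow(exo)) next
        a <- exo[exi, 1]; b <- exo[exi, 2]
        if (any(ann_jmat[, 1] <= a & b <= ann_jmat[, 2]) &&
            !((a - 1L) %in% ann_sites_end) && !((b + 1L) %in% ann_sites_start))
          return(TRUE)
      }
    }
    FALSE
  }

  el <- list()
  for (k in all_j) {
    km <- .key_mat(k)
    s <- km[1, 1]; e <- km[1, 2]
    ann <- k %in% ann_keys
    short <- k %in% sj_det
    long <- k %in% long_keys
    if (!short && !long) next  # annotation-only: not detected
    cat6 <- six_category(data.frame(ann = ann, short = short, long = long))
    denovo <- NA_character_; nst <- NA_character_
    if (!ann) {
      dk <- donor_known(s, e); ak <- acceptor_known(s, e)
      denovo <- if (dk && ak) "NOVEL_COMBINATION" else "NOVEL_SPLICE_SITE"
      if (long && denovo == "NOVEL_SPLICE_SITE") {
        nst <- if (new_exon_geom(s, e)) "NEW_EXON"
        else if (!dk && !ak) "MIXED"
        else if (!dk) "ALT_5SS" else "ALT_3SS"
      }
    }
    el[[k]] <- data.frame(gene_id = gene, kind = "junction", start = s, end = e,
                          six_category = cat6, denovo_class = denovo,
                          novel_ss_type = nst, stringsAsFactors = FALSE)
  }

  # retained introns: comparison set mirrors the graph builder
  sj_det_mat <- if (length(sj_det)) .key_mat(sj_det) else matrix(integer(), 0, 2)
  ir_mat <- if (length(ir_tab)) matrix(c(ir_tab[[1]][1], ir_tab[[1]][2]), 1, 2) else
    matrix(integer(), 0, 2)
  comp <- unique(rbind(ann_jmat, sj_det_mat, ir_mat))
  long_span <- function(s, e) {
    for (exo in emitted_exons)
      if (any(exo[, 1] < s & exo[, 2] > e)) return(TRUE)
    FALSE
  }
  ann_span <- function(s, e) {
    nrow(ann_exmat) > 0 && any(ann_exmat[, 1] < s & ann_exmat[, 2] > e)
  }
  ir_keys <- character()
  if (nrow(comp) > 0)
    ir_keys <- .ikey(comp[apply(comp, 1, function(r) long_span(r[1], r[2])), , drop = FALSE])
  if (nrow(ir_mat) > 0) ir_keys <- c(ir_keys, .ikey(ir_mat))
  # annotated retained introns present only via annotation are NOT_DETECTED
  for (k in unique(ir_keys)) {
    km <- .key_mat(k); s <- km[1, 1]; e <- km[1, 2]
    ann <- ann_span(s, e)
    short <- nrow(ir_mat) > 0 && any(ir_mat[, 1] == s & ir_mat[, 2] == e)
    long <- long_span(s, e)
    if (!short && !long) next
    cat6 <- six_category(data.frame(ann = ann, short = short, long = long))
    el[[paste0("ir:", k)]] <- data.frame(
      gene_id = gene, kind = "retained_intron", start = s, end = e,
      six_category = cat6, denovo_class = NA_character_,
      novel_ss_type = if (long && !ann) "IR" else NA_character_,
      stringsAsFactors = FALSE)
  }
  elements <- if (length(el)) do.call(rbind, unname(el)) else NULL

  tx <- list()
  for (nm in names(emitted_exons)) {
    exo <- emitted_exons[[nm]]
    p5 <- if (strand == "+") exo[1, 1] else exo[nrow(exo), 2]
    p3 <- if (strand == "+") exo[nrow(exo), 2] else exo[1, 1]
    ptss <- !(p5 %in% ann_tss)
    ptes <- !(p3 %in% ann_tes)
    ks <- .ikey(junctions_of(exo))
    nov <- ks[!(ks %in% ann_keys)]
    nc <- FALSE; nss <- FALSE
    for (k in nov) {
      km <- .key_mat(k)
      if (donor_known(km[1, 1], km[1, 2]) && acceptor_known(km[1, 1], km[1, 2]))
        nc <- TRUE else nss <- TRUE
    }
    cls <- .venn_of_features(nc, nss, ptss || ptes)
    tx[[nm]] <- data.frame(gene_id = gene,
                           transcript_id = sprintf("%s.%s", gene, nm),
                           venn_class = cls, excluded = identical(cls, "VII"),
                           ptss = ptss, ptes = ptes, stringsAsFactors = FALSE)
  }
  transcripts <- if (length(tx)) do.call(rbind, unname(tx)) else NULL
  list(elements = elements, transcripts = transcripts)
}

# manual GTF emission (exon features only), 1-based inclusive, GTF-quoted
# attributes; deterministic line order
.write_gtf <- function(rows, path, counts = FALSE) {
  if (is.null(rows) || nrow(rows) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order(rows$gene_id, rows$transcript_id, rows$start, method = "radix")
  rows <- rows[ord, ]
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                      rows$gene_id, rows$transcript_id)
  if (counts)
    attr_str <- sprintf('%s read_count "%s";', attr_str,
                        format(rows$read_count, trim = TRUE, scientific = FALSE))
  lines <- sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                   rows$chrom, rows$start, rows$end, rows$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}
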