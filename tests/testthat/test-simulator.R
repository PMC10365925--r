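test_that("expression-count draws match their configured Gamma means", {
  set.seed(501)
  # raw draws: mean k*theta (Monte-Carlo at 1e5 draws)
  raw_umis <- draw_expression_counts(1e5, c(1, 6), raw = TRUE)
  expect_lt(abs(mean(raw_umis) - 6) / 6, 0.02)
  raw_reads <- draw_expression_counts(1e5, c(2, 2), raw = TRUE)
  expect_lt(abs(mean(raw_reads) - 4) / 4, 0.02)
  # counts are clamped at 1 (a raw draw below 0.5 becomes 1)
  counts <- draw_expression_counts(1e4, c(0.2, 0.5))
  expect_true(all(counts >= 1L))
})

test_that("cell profiles respect catalogue size, distinctness and barcodes", {
  set.seed(502)
  genome <- as_genome(c(chr1 = random_dna_str(30000)))
  cat <- simple_catalogue(starts = seq(1L, 29001L, by = 1500L),
                          ends = seq(1000L, 30000L, by = 1500L),
                          genome = genome)
  wl <- make_whitelist(80, 16)
  p <- sim_params(n_cells = 40)
  pr <- draw_cell_profiles(p, cat, wl)
  expect_length(pr$barcodes, 40L)
  expect_false(anyDuplicated(pr$barcodes) > 0)
  expect_true(all(pr$barcodes %in% wl))
  # genes per cell capped at catalogue size, genes distinct within cell
  per_cell <- split(pr$genes$gene_id, pr$genes$cell)
  expect_true(all(lengths(per_cell) <= nrow(cat$genes)))
  expect_true(all(vapply(per_cell, anyDuplicated, integer(1)) == 0L))
  # one UMI row per planted UMI
  expect_identical(nrow(pr$umis), sum(pr$genes$n_umis))
  expect_error(draw_cell_profiles(sim_params(n_cells = 100), cat, wl),
               "whitelist")
})

test_that("fragment sampling hits the 3' window with the configured geometry", {
  set.seed(503)
  genome <- as_genome(c(chr1 = random_dna_str(12000)))
  cat <- simple_catalogue(starts = 1001L, ends = 11000L, genome = genome)
  g <- cat$genes[1, ]
  # degenerate sd = 0: every fragment's 3'-most base exactly 350 upstream
  p0 <- sim_params(n_cells = 1, frag_dist_sd = 0)
  for (i in 1:10) {
    fr <- sample_fragment(g, genome, p0)
    expect_identical(fr$end, g$tpp - 350L)
    expect_identical(fr$seq, substr(genome[["chr1"]], fr$start, fr$end))
    expect_identical(nchar(fr$seq), 90L)
  }
  # minus strand returns the reverse complement
  catm <- simple_catalogue(starts = 1001L, ends = 11000L, strands = "-",
                           genome = genome)
  frm <- sample_fragment(catm$genes[1, ], genome, p0)
  expect_identical(frm$start, catm$genes$tpp[1] + 350L)
  expect_identical(frm$seq,
                   oracle_revcomp(substr(genome[["chr1"]], frm$start, frm$end)))
  # empirical mean/sd over many fragments
  p <- sim_params(n_cells = 1)
  d <- replicate(2000, sample_fragment(g, genome, p)$distance)
  expect_lt(abs(mean(d) - 350), 350 * 0.05)
  expect_lt(abs(sd(d) - 30), 30 * 0.1)
})

test_that("short gene spans truncate the feasible fragment distances", {
  set.seed(504)
  genome <- as_genome(c(chr1 = random_dna_str(1000)))
  cat <- simple_catalogue(starts = 101L, ends = 500L, genome = genome)  # 400 b
  p <- sim_params(n_cells = 1)
  d <- replicate(300, sample_fragment(cat$genes[1, ], genome, p)$distance)
  expect_true(all(d >= 0 & d <= 400 - 90))
})

test_that("variant planting matches its configured rates and edge cases", {
  set.seed(505)
  seqs <- vapply(1:20, function(i) random_dna_str(500), character(1))
  # zero-rate identity
  out <- plant_variants(seqs, 0, 0)
  expect_identical(out$seqs, seqs)
  expect_identical(nrow(out$variants), 0L)
  # saturation: snp_rate 1 changes every base
  sat <- plant_variants(seqs[1], 1, 0)
  expect_identical(nchar(sat$seqs), nchar(seqs[1]))
  expect_true(all(chars(sat$seqs) != chars(seqs[1])))
  # recorded SNP refs match the input sequence at their positions
  set.seed(506)
  out <- plant_variants(seqs, 0.02, 0.002)
  snp <- out$variants[out$variants$type == "snp", ]
  expect_true(all(substring(seqs[snp$seq], snp$pos, snp$pos) == snp$ref))
  expect_true(all(snp$alt != snp$ref))
  # observed rates near nominal over ~1e6 bases (10% relative)
  set.seed(507)
  big <- vapply(1:10, function(i) random_dna_str(1e5), character(1))
  out <- plant_variants(big, 0.0009, 0.0001)
  n_b <- sum(nchar(big))
  snp_rate <- sum(out$variants$type == "snp") / n_b
  ind_rate <- sum(out$variants$type %in% c("ins", "del")) / n_b
  expect_lt(abs(snp_rate - 9e-4) / 9e-4, 0.10)
  expect_lt(abs(ind_rate - 1e-4) / 1e-4, 0.25)
})

test_that("sequencing errors follow the Phred profile", {
  set.seed(508)
  # flat q = 40: error fraction ~1e-4 over 1e6 bases
  reads <- vapply(1:10000, function(i) random_dna_str(100), character(1))
  out <- apply_sequencing_errors(reads, rep(40, 100))
  frac <- sum(mapply(function(a, b) sum(chars(a) != chars(b)),
                     out$reads, reads)) / 1e6
  expect_lt(abs(frac - 1e-4) / 1e-4, 0.35)
  # q = 2 at the last cycle: ~0.63 of last bases flip
  qp <- c(rep(40, 9), 2)
  reads10 <- vapply(1:4000, function(i) random_dna_str(10), character(1))
  out <- apply_sequencing_errors(reads10, qp)
  last_err <- mean(substring(out$reads, 10, 10) != substring(reads10, 10, 10))
  expect_lt(abs(last_err - 10^(-0.2)), 0.05)
  # quality strings are Phred+33 of the profile
  expect_identical(out$qual[1], intToUtf8(c(rep(40, 9), 2) + 33))
  # more errors at the 3' end than the 5' end under the default profile
  set.seed(509)
  reads90 <- vapply(1:5000, function(i) random_dna_str(90), character(1))
  out <- apply_sequencing_errors(reads90, quality_profile(90))
  diffs <- mapply(function(a, b) which(chars(a) != chars(b)),
                  out$reads, reads90)
  pos <- unlist(diffs)
  expect_gt(sum(pos > 80), sum(pos <= 10))
  # error-free path
  clean <- apply_sequencing_errors(reads10, rep(Inf, 10))
  expect_identical(clean$reads, reads10)
})

test_that("a minimal assembled instance shares barcode+UMI across its reads", {
  set.seed(510)
  genome <- as_genome(c(chr1 = random_dna_str(2000)))
  cat <- simple_catalogue(starts = 501L, ends = 1500L, genome = genome)
  pr <- manual_profiles(
    barcodes = "ACGTACGTACGTACGT",
    umis = data.frame(cell = 1L, gene_id = "g01", reads = 3L,
                      stringsAsFactors = FALSE)
  )
  p <- noiseless_params(1)
  sim <- assemble_reads(pr, cat, genome, p)
  expect_length(sim$r1, 3L)
  expect_identical(length(unique(sim$r1)), 1L)
  expect_identical(substr(sim$r1[1], 1, 16), "ACGTACGTACGTACGT")
  expect_identical(sum(sim$truth), 1)
  expect_identical(unique(nchar(sim$r2)), 90L)
})

test_that("read and UMI conservation holds and noise-free reads are genomic", {
  set.seed(511)
  genome <- as_genome(c(chr1 = random_dna_str(30000)))
  cat <- simple_catalogue(starts = seq(1L, 28001L, by = 1500L),
                          ends = seq(1200L, 29200L, by = 1500L),
                          strands = c("+", "-"), genome = genome)
  wl <- make_whitelist(30, 16)
  p <- noiseless_params(10)
  pr <- draw_cell_profiles(p, cat, wl)
  sim <- assemble_reads(pr, cat, genome, p)
  expect_identical(length(sim$r2), sum(pr$umis$reads))
  expect_equal(sum(sim$truth), sum(pr$genes$n_umis))
  # with all noise off every R2 read is an exact genomic substring of its
  # gene's 3' window (transcript orientation)
  for (i in sample(length(sim$r2), 25)) {
    ori <- sim$per_read[i, ]
    gseq <- substr(genome[["chr1"]], ori$start, ori$end)
    if (ori$strand == "-") gseq <- oracle_revcomp(gseq)
    expect_identical(sim$r2[i], gseq)
    expect_true(grepl(sim$r2[i], genome[["chr1"]], fixed = TRUE) ||
                  grepl(oracle_revcomp(sim$r2[i]), genome[["chr1"]],
                        fixed = TRUE))
  }
  # UMIs distinct within every (cell, gene)
  key <- paste(sim$per_read$barcode, sim$per_read$gene_id)
  per_group <- split(sim$per_read$umi, key)
  n_distinct <- vapply(per_group, function(u) length(unique(u)), integer(1))
  planted <- table(paste(pr$barcodes[pr$umis$cell], pr$umis$gene_id))
  expect_identical(unname(n_distinct[names(planted)]), as.vector(planted))
})

test_that("simulation output is byte-identical under a fixed seed", {
  genome <- as_genome(c(chr1 = random_dna_str(20000)))
  # (genome drawn outside the compared section)
  cat <- simple_catalogue(starts = c(1001L, 6001L, 11001L),
                          ends = c(2000L, 7000L, 12000L), genome = genome)
  wl <- make_whitelist(20, 16)
  p <- sim_params(n_cells = 5)
  run <- function() {
    d <- tempfile()
    set.seed(99)
    simulate_chromium(genome, cat, wl, p, d)
    lapply(c("R1.fastq.gz", "R2.fastq.gz", "I1.fastq.gz"), function(f)
      readLines(gzfile(file.path(d, f))))
  }
  expect_identical(run(), run())
})
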