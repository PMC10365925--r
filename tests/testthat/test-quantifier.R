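test_that("barcode correction allows one mismatch and rejects ambiguity", {
  wl <- barcode_whitelist(c("AAAA", "CCCC"))
  expect_identical(as.vector(correct_barcodes("AAAA", wl)), "AAAA")
  expect_identical(as.vector(correct_barcodes("AAAT", wl)), "AAAA")
  expect_true(is.na(correct_barcodes("AATT", wl)))  # distance 2
  wl2 <- barcode_whitelist(c("AAAA", "AAAG"))
  expect_true(is.na(correct_barcodes("AAAC", wl2)))  # two distance-1 hits
  # exact membership wins even when neighbours exist
  expect_identical(as.vector(correct_barcodes("AAAG", wl2)), "AAAG")
  # wrong length is rejected and counted
  out <- correct_barcodes(c("AAA", "AAAA"), wl)
  expect_identical(attr(out, "n_length_mismatch"), 1L)
  expect_true(is.na(out[1]))
})

test_that("barcode correction matches a brute-force Hamming scan", {
  set.seed(701)
  for (rep in 1:5) {
    wl_v <- unique(random_dna(40, 6))
    wl <- barcode_whitelist(wl_v)
    obs <- c(sample(wl_v, 10, replace = TRUE), random_dna(40, 6))
    got <- as.vector(correct_barcodes(obs, wl))
    want <- vapply(obs, oracle_correct_barcode, character(1), wl = wl_v,
                   USE.NAMES = FALSE)
    expect_identical(got, want)
  }
})

test_that("gene assignment follows featureCounts largest-overlap rules", {
  genome <- as_genome(c(chr1 = strrep("A", 1000)))
  cat <- simple_catalogue(starts = c(1L, 91L), ends = c(100L, 290L),
                          genome = genome)
  aln <- data.frame(
    mapped = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    chrom = "chr1",
    pos = c(11L, 41L, 51L, NA, 901L),
    ref_span = c(60L, 60L, 90L, NA, 60L),
    stringsAsFactors = FALSE
  )
  out <- assign_to_genes(aln, cat)
  # fully inside g01
  expect_identical(out$gene_id[1], "g01")
  # pos 41-100 overlaps g01 by 60, g02 by 10
  expect_identical(out$gene_id[2], "g01")
  expect_identical(out$status[2], "assigned")
  # pos 51-140: g01 by 50, g02 by 50 -> ambiguous tie
  expect_identical(out$status[3], "ambiguous")
  expect_true(is.na(out$gene_id[3]))
  expect_identical(out$status[4], "unmapped")
  # outside any exon
  expect_identical(out$status[5], "no_feature")
})

test_that("intron-only alignments are unassigned", {
  genome <- as_genome(c(chr1 = strrep("A", 1000)))
  cat <- build_catalogue(gene_id = c("g1", "g1"), chrom = c("chr1", "chr1"),
                         strand = c("+", "+"), start = c(1L, 401L),
                         end = c(100L, 500L), genome = genome)
  aln <- data.frame(mapped = TRUE, chrom = "chr1", pos = 151L, ref_span = 90L,
                    stringsAsFactors = FALSE)
  expect_identical(assign_to_genes(aln, cat)$status, "no_feature")
})

test_that("UMI collapsing counts Hamming-linked components", {
  one <- collapse_umis(c(ACGTACGTACGT = 5L))
  expect_identical(one$count, 1L)
  two <- collapse_umis(c(ACGTACGTACGT = 5L, ACGTACGTACGA = 1L))
  expect_identical(two$count, 1L)
  expect_identical(two$components$umi, "ACGTACGTACGT")  # max reads wins
  expect_identical(two$components$reads, 6L)
  chain <- collapse_umis(c(AAAAAAAAAAAA = 3L, AAAAAAAAAAAT = 1L,
                           AAAAAAAAAATT = 1L))
  expect_identical(chain$count, 1L)  # single-linkage chain
  far <- collapse_umis(c(AAAAAAAAAAAA = 1L, AAAATTTTAAAA = 1L))
  expect_identical(far$count, 2L)
  # representative tie: equal reads -> lexicographically smallest
  tie <- collapse_umis(c(CAAAAAAAAAAA = 2L, AAAAAAAAAAAA = 2L))
  expect_identical(tie$components$umi, "AAAAAAAAAAAA")
})

test_that("UMI component counts match a single-linkage oracle", {
  set.seed(702)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    umis <- unique(random_dna(n, 4))  # short UMIs force collisions
    reads <- sample(5, length(umis), replace = TRUE)
    names(reads) <- umis
    got <- collapse_umis(reads)
    expect_identical(got$count, length(unique(oracle_umi_components(umis))))
    expect_identical(sum(got$components$reads), sum(reads))
  }
})

test_that("cross-gene UMIs go to the gene with most supporting reads", {
  tbl <- data.frame(gene_id = c("gB", "gA"), umi = "ACGTACGTACGT",
                    reads = c(2L, 5L), stringsAsFactors = FALSE)
  out <- resolve_multigene_umis(tbl)
  expect_identical(out$gene_id, "gA")
  # single-gene UMIs are kept
  tbl1 <- data.frame(gene_id = "gC", umi = "TTTTTTTTTTTT", reads = 1L,
                     stringsAsFactors = FALSE)
  expect_identical(resolve_multigene_umis(tbl1)$gene_id, "gC")
  # read-count ties break to the smaller gene id
  tie <- data.frame(gene_id = c("gB", "gA"), umi = "ACGTACGTACGT",
                    reads = c(3L, 3L), stringsAsFactors = FALSE)
  expect_identical(resolve_multigene_umis(tie)$gene_id, "gA")
})

test_that("build_matrix deduplicates reads and resolves cross-gene UMIs", {
  genome <- as_genome(c(chr1 = strrep("A", 1000)))
  cat <- simple_catalogue(starts = c(1L, 501L), ends = c(400L, 900L),
                          genome = genome)
  # 7 duplicate reads of one UMI -> a single count
  a <- data.frame(barcode = "B1", umi = "ACGTACGTACGT", gene_id = "g01",
                  stringsAsFactors = FALSE)[rep(1, 7), ]
  m <- build_matrix(a, cat)
  expect_equal(sum(m), 1)
  expect_equal(m["g01", "B1"], 1)
  # same UMI in two genes: 5 reads in g01, 2 in g02 -> g01 keeps it
  b <- rbind(a[rep(1, 5), ],
             data.frame(barcode = "B1", umi = "ACGTACGTACGT", gene_id = "g02",
                        stringsAsFactors = FALSE)[rep(1, 2), ])
  m2 <- build_matrix(b, cat)
  expect_equal(m2["g01", "B1"], 1)
  expect_equal(m2["g02", "B1"], 0)
  # ...but the same UMI in two different barcodes counts twice
  c2 <- rbind(a, within(a, barcode <- "B2")[1, ])
  m3 <- build_matrix(c2, cat)
  expect_equal(sum(m3), 2)
})

test_that("no UMI is double-counted across a barcode's column", {
  set.seed(703)
  genome <- as_genome(c(chr1 = strrep("A", 2000)))
  cat <- simple_catalogue(starts = c(1L, 501L, 1001L),
                          ends = c(400L, 900L, 1400L), genome = genome)
  a <- data.frame(
    barcode = sample(c("B1", "B2"), 300, replace = TRUE),
    umi = random_dna(300, 3),  # tiny UMI space forces heavy collisions
    gene_id = sample(cat$genes$gene_id, 300, replace = TRUE),
    stringsAsFactors = FALSE
  )
  m <- build_matrix(a, cat)
  for (bc in colnames(m)) {
    rows <- a[a$barcode == bc, ]
    # a column can never exceed its distinct raw UMI count, and within any
    # single gene the collapsed count matches the single-linkage oracle
    expect_lte(sum(m[, bc]), length(unique(rows$umi)))
    for (g in unique(rows$gene_id)) {
      u <- unique(rows$umi[rows$gene_id == g])
      expect_lte(m[g, bc], length(unique(oracle_umi_components(u))))
    }
  }
})

test_that("noise-free quantification reproduces the planted truth exactly", {
  set.seed(704)
  fx <- make_fixture(n_genes = 15, genome_size = 30000, whitelist_size = 80)
  idx <- build_kmer_index(fx$genome)
  p <- noiseless_params(25)
  pr <- draw_cell_profiles(p, fx$catalogue, fx$whitelist)
  sim <- assemble_reads(pr, fx$catalogue, fx$genome, p)
  q <- quantify_reads(sim$r1, sim$r2, idx, fx$catalogue,
                      barcode_whitelist(fx$whitelist))
  expect_identical(unname(q$stats["assigned"]), length(sim$r2))
  truth <- sim$truth[, colnames(q$matrix)]
  expect_true(all(q$matrix == truth))
  expect_identical(dim(q$matrix), c(15L, 25L))
})

test_that("count matrices round-trip through the MatrixMarket triplet", {
  set.seed(705)
  m <- Matrix::rsparsematrix(30, 10, density = 0.2,
                             rand.x = function(n) rpois(n, 3) + 1)
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("BC%02d", 1:10))
  d <- tempfile()
  write_counts(m, d)
  m2 <- read_counts(d)
  expect_equal(as.matrix(m), as.matrix(m2))
})
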