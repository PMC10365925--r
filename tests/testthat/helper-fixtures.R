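# Small reusable fixtures, all generated in code at test time.

# a Genome object straight from a character vector
as_genome <- function(x) structure(x, class = "Genome")

# one random DNA string of length n
random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# single-chromosome genome with one or more plus-strand genes
simple_catalogue <- function(starts, ends, strands = "+",
                             chrom = "chr1", genome = NULL) {
  n <- length(starts)
  build_catalogue(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = rep(chrom, n),
    strand = rep_len(strands, n),
    start = starts, end = ends,
    genome = genome
  )
}

# write a FASTA fixture and return its path
write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

# noise-free simulation parameters
noiseless_params <- function(n_cells, ...) {
  sim_params(n_cells = n_cells, snp_rate = 0, indel_rate = 0,
             frag_dist_sd = 0, q_profile = rep(Inf, 90), ...)
}

# hand-built CellProfiles (bypasses the Gamma draws)
manual_profiles <- function(barcodes, umis) {
  genes <- stats::aggregate(list(n_umis = umis$reads), # placeholder, fixed below
                            by = list(cell = umis$cell, gene_id = umis$gene_id),
                            FUN = length)
  genes <- genes[, c("cell", "gene_id", "n_umis")]
  structure(list(barcodes = barcodes, genes = genes, umis = umis),
            class = "CellProfiles")
}

# ambient-only droplet columns drawn from a multinomial profile; returns a
# sparse genes x n matrix whose column totals are sampled from `totals`
ambient_droplets <- function(n, profile, totals, prefix = "bg") {
  tot <- sample(totals, n, replace = TRUE)
  m <- vapply(tot, function(t) stats::rmultinom(1, t, profile)[, 1],
              numeric(length(profile)))
  m <- Matrix::Matrix(m, sparse = TRUE)
  dimnames(m) <- list(names(profile), sprintf("%s%05d", prefix, seq_len(n)))
  m
}
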