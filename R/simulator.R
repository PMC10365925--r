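#' Simulation parameters for Chromium-style reads
#'
#' Defaults describe the simulated study conditions: expression structure is
#' Gamma-distributed (genes per cell `Gamma(4.5, 550)`, UMIs per gene
#' `Gamma(1, 6)`, reads per UMI `Gamma(2, 2)`, each rounded and clamped at 1),
#' fragments sit 350 +/- 30 bases upstream of each gene's 3' end, and planted
#' variants occur at 9e-4 (SNP) and 1e-4 (indel initiation) per base. Read
#' segment lengths follow Chromium Next GEM v3.1 conventions: 16-base cell
#' barcode, 12-base UMI, 90-base cDNA read, fixed 8-base sample index.
#'
#' @param n_cells number of cells to simulate.
#' @param genes_per_cell_gamma,umis_per_gene_gamma,reads_per_umi_gamma
#'   two-element vectors `c(shape, scale)`.
#' @param frag_dist_mean,frag_dist_sd mean/SD (bases) of the distance between
#'   a fragment's 3'-most base and the gene's 3' end.
#' @param snp_rate,indel_rate per-base rates of planted substitutions and
#'   indel initiations.
#' @param read2_length,barcode_length,umi_length segment lengths in bases.
#' @param sample_index fixed 8-base sample index sequence.
#' @param q_profile per-cycle Phred scores driving sequencing errors; must be
#'   non-increasing (more errors toward the 3' end of reads). Use `Inf` for
#'   error-free reads.
#' @return an object of class `SimParams`.
#' @export
sim_params <- function(n_cells = 10000L,
                       genes_per_cell_gamma = c(4.5, 550),
                       umis_per_gene_gamma = c(1, 6),
                       reads_per_umi_gamma = c(2, 2),
                       frag_dist_mean = 350,
                       frag_dist_sd = 30,
                       snp_rate = 0.0009,
                       indel_rate = 0.0001,
                       read2_length = 90L,
                       barcode_length = 16L,
                       umi_length = 12L,
                       sample_index = "ACGTACGT",
                       q_profile = quality_profile(90L)) {
  stopifnot(n_cells >= 1,
            all(genes_per_cell_gamma > 0), all(umis_per_gene_gamma > 0),
            all(reads_per_umi_gamma > 0),
            snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            frag_dist_sd >= 0, read2_length >= 1,
            nchar(sample_index) == 8L,
            length(q_profile) >= read2_length,
            !is.unsorted(rev(q_profile)))
  structure(list(
    n_cells = as.integer(n_cells),
    genes_per_cell_gamma = genes_per_cell_gamma,
    umis_per_gene_gamma = umis_per_gene_gamma,
    reads_per_umi_gamma = reads_per_umi_gamma,
    frag_dist_mean = frag_dist_mean, frag_dist_sd = frag_dist_sd,
    snp_rate = snp_rate, indel_rate = indel_rate,
    read2_length = as.integer(read2_length),
    barcode_length = as.integer(barcode_length),
    umi_length = as.integer(umi_length),
    sample_index = sample_index,
    q_profile = q_profile
  ), class = "SimParams")
}

#' Per-cycle Phred quality profile
#'
#' A parametric per-cycle quality curve, linearly decaying from `q_start` to
#' `q_end`, hence non-increasing toward the 3' end of the read. The
#' substitution probability at cycle i is `10^(-q_i/10)`.
#'
#' @param length number of cycles.
#' @param q_start,q_end Phred score at the first and last cycle.
#' @return numeric vector of per-cycle Phred scores.
#' @export
quality_profile <- function(length = 90L, q_start = 37, q_end = 25) {
  stopifnot(length >= 1, q_end <= q_start)
  if (length == 1L) return(q_start)
  q_start + (q_end - q_start) * (seq_len(length) - 1) / (length - 1)
}

# round-and-clamp a Gamma draw into a count >= 1
round_clamp <- function(x) pmax(1L, as.integer(round(x)))

#' Draw Gamma-distributed simulation counts
#'
#' The generator behind genes-per-cell, UMIs-per-gene and reads-per-UMI:
#' `Gamma(shape, scale)` draws, rounded to the nearest integer and clamped
#' at 1 (`raw = TRUE` returns the draws before rounding, e.g. for checking
#' the configured distribution against its `shape * scale` mean).
#'
#' @param n number of draws.
#' @param gamma two-element vector `c(shape, scale)`.
#' @param raw return the raw continuous draws instead of counts.
#' @return integer counts (or numeric draws when `raw = TRUE`).
#' @export
draw_expression_counts <- function(n, gamma, raw = FALSE) {
  x <- stats::rgamma(n, shape = gamma[1], scale = gamma[2])
  if (raw) x else round_clamp(x)
}

#' Draw per-cell expression profiles
#'
#' For each cell, the number of expressed genes is a `Gamma(4.5, 550)` draw
#' rounded to the nearest integer, clamped at 1 and capped at the catalogue
#' size; that many distinct genes are drawn uniformly without replacement.
#' Each expressed gene receives `max(1, round(Gamma(1, 6)))` UMIs and each
#' UMI `max(1, round(Gamma(2, 2)))` reads. Cell barcodes are sampled without
#' replacement from the whitelist.
#'
#' @param params a `SimParams`.
#' @param catalogue a `GeneCatalogue`.
#' @param whitelist character vector of barcode sequences, at least
#'   `params$n_cells` long.
#' @return an object of class `CellProfiles`: list with `barcodes`
#'   (per-cell), `genes` (data.frame cell, gene_id, n_umis) and `umis`
#'   (data.frame cell, gene_id, reads; one row per planted UMI).
#' @export
draw_cell_profiles <- function(params, catalogue, whitelist) {
  G <- nrow(catalogue$genes)
  if (G == 0L) stop("gene catalogue is empty")
  n <- params$n_cells
  if (length(whitelist) < n)
    stop("whitelist has ", length(whitelist), " barcodes but ", n,
         " cells requested")
  barcodes <- sample(whitelist, n)
  n_genes <- pmin(draw_expression_counts(n, params$genes_per_cell_gamma), G)
  gene_idx <- unlist(lapply(n_genes, function(k) sample.int(G, k)),
                     use.names = FALSE)
  cell <- rep.int(seq_len(n), n_genes)
  n_umis <- draw_expression_counts(length(gene_idx),
                                   params$umis_per_gene_gamma)
  umi_cell <- rep.int(cell, n_umis)
  umi_gene <- rep.int(gene_idx, n_umis)
  reads <- draw_expression_counts(length(umi_cell),
                                  params$reads_per_umi_gamma)
  ids <- catalogue$genes$gene_id
  structure(list(
    barcodes = barcodes,
    genes = data.frame(cell = cell, gene_id = ids[gene_idx],
                       n_umis = n_umis, stringsAsFactors = FALSE),
    umis = data.frame(cell = umi_cell, gene_id = ids[umi_gene],
                      reads = reads, stringsAsFactors = FALSE)
  ), class = "CellProfiles")
}

#' @export
print.CellProfiles <- function(x, ...) {
  cat("CellProfiles:", length(x$barcodes), "cell(s),",
      nrow(x$umis), "planted UMI(s),", sum(x$umis$reads), "read(s)\n")
  invisible(x)
}

#' Ground-truth UMI count matrix from cell profiles
#'
#' @param profiles a `CellProfiles`.
#' @param catalogue a `GeneCatalogue` fixing row order.
#' @return a sparse genes x barcodes matrix of planted UMI counts.
#' @export
truth_matrix <- function(profiles, catalogue) {
  ids <- catalogue$genes$gene_id
  gi <- match(profiles$genes$gene_id, ids)
  Matrix::sparseMatrix(
    i = gi, j = profiles$genes$cell, x = profiles$genes$n_umis,
    dims = c(length(ids), length(profiles$barcodes)),
    dimnames = list(ids, profiles$barcodes)
  )
}

#' Sample one 3'-biased fragment from a gene
#'
#' Draws the distance d between the fragment's 3'-most base and the gene's 3'
#' end from `Normal(frag_dist_mean, frag_dist_sd)` (rounded), resampling
#' until the `read2_length` window ending d bases from the 3' end fits inside
#' the gene's genomic span.
#'
#' @param gene one row of `catalogue$genes`.
#' @param genome a `Genome`.
#' @param params a `SimParams`.
#' @return list with `seq` (transcript-oriented), `chrom`, `start`, `end`
#'   (genomic, 1-based closed), `strand` and `distance`.
#' @export
sample_fragment <- function(gene, genome, params) {
  L <- params$read2_length
  span <- gene$end - gene$start + 1L
  if (span < L) stop("gene '", gene$gene_id, "' shorter than read length")
  d <- sample_distances(1L, span, params)
  if (gene$strand == "+") {
    hi <- gene$tpp - d; lo <- hi - L + 1L
  } else {
    lo <- gene$tpp + d; hi <- lo + L - 1L
  }
  sq <- substr(genome[[gene$chrom]], lo, hi)
  if (gene$strand == "-") sq <- revcomp(sq)
  list(seq = sq, chrom = gene$chrom, start = lo, end = hi,
       strand = gene$strand, distance = d)
}

# vectorised truncated-normal distances: one per element of `span`
sample_distances <- function(n, span, params) {
  L <- params$read2_length
  span <- rep_len(span, n)
  d <- round(stats::rnorm(n, params$frag_dist_mean, params$frag_dist_sd))
  bad <- which(d < 0 | d > span - L)
  tries <- 0L
  while (length(bad) > 0L) {
    if ((tries <- tries + 1L) > 1000L)
      stop("cannot place a fragment inside the gene span; gene too short")
    d[bad] <- round(stats::rnorm(length(bad), params$frag_dist_mean,
                                 params$frag_dist_sd))
    bad <- bad[d[bad] < 0 | d[bad] > span[bad] - L]
  }
  as.integer(d)
}

#' Plant genomic variants into sequences
#'
#' Each base independently receives a substitution with probability
#' `snp_rate` (to a uniformly chosen different base) and initiates an indel
#' with probability `indel_rate` (insertion or deletion with equal odds,
#' length uniform on 1-3).
#'
#' @param seqs character vector of sequences.
#' @param snp_rate,indel_rate per-base probabilities.
#' @return list with `seqs` (mutated) and `variants` (data.frame: seq index,
#'   pos, type in snp/ins/del, ref, alt).
#' @export
plant_variants <- function(seqs, snp_rate, indel_rate) {
  stopifnot(all(nchar(seqs) > 0), snp_rate >= 0, snp_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  nc <- nchar(seqs)
  cum <- cumsum(as.numeric(nc))
  total <- cum[length(cum)]
  locate <- function(pos) {
    idx <- findInterval(pos - 1, c(0, cum), rightmost.closed = FALSE)
    off <- as.integer(pos - c(0, cum)[idx])
    list(idx = idx, off = off)
  }
  bases <- c("A", "C", "G", "T")
  vars <- list()
  # substitutions
  n_snp <- stats::rbinom(1L, total, snp_rate)
  if (n_snp > 0L) {
    loc <- locate(sort(sample(total, n_snp)))
    ref <- substring(seqs[loc$idx], loc$off, loc$off)
    alt <- vapply(ref, function(r) {
      pool <- setdiff(bases, r)
      pool[sample.int(length(pool), 1L)]
    }, character(1), USE.NAMES = FALSE)
    for (e in seq_len(n_snp))
      substr(seqs[loc$idx[e]], loc$off[e], loc$off[e]) <- alt[e]
    vars[[length(vars) + 1L]] <- data.frame(
      seq = loc$idx, pos = loc$off, type = "snp", ref = ref, alt = alt,
      stringsAsFactors = FALSE)
  }
  # indel initiations (positions on the pre-indel coordinate system;
  # applied per sequence from right to left so positions stay valid)
  n_ind <- stats::rbinom(1L, total, indel_rate)
  if (n_ind > 0L) {
    loc <- locate(sort(sample(total, n_ind)))
    len <- sample.int(3L, n_ind, replace = TRUE)
    is_ins <- stats::runif(n_ind) < 0.5
    ins_seq <- random_dna(n_ind, 3L)
    ord <- order(loc$idx, -loc$off)
    idf <- vector("list", n_ind)
    for (t in seq_len(n_ind)) {
      e <- ord[t]
      i <- loc$idx[e]; o <- loc$off[e]; s <- seqs[i]
      if (is_ins[e]) {
        ins <- substr(ins_seq[e], 1L, len[e])
        seqs[i] <- paste0(substr(s, 1L, o), ins, substr(s, o + 1L, nchar(s)))
        idf[[t]] <- data.frame(seq = i, pos = o, type = "ins", ref = "",
                               alt = ins, stringsAsFactors = FALSE)
      } else {
        hi <- min(o + len[e] - 1L, nchar(s))
        ref <- substr(s, o, hi)
        seqs[i] <- paste0(substr(s, 1L, o - 1L),
                          substr(s, hi + 1L, nchar(s)))
        idf[[t]] <- data.frame(seq = i, pos = o, type = "del", ref = ref,
                               alt = "", stringsAsFactors = FALSE)
      }
    }
    vars[[length(vars) + 1L]] <- do.call(rbind, idf)
  }
  variants <- if (length(vars) > 0) do.call(rbind, vars) else
    data.frame(seq = integer(0), pos = integer(0), type = character(0),
               ref = character(0), alt = character(0), stringsAsFactors = FALSE)
  list(seqs = seqs, variants = variants)
}

#' Apply quality-driven sequencing errors
#'
#' The base at cycle i is substituted (to a uniformly chosen different base)
#' with probability `10^(-q_i/10)` given the per-cycle Phred profile. The
#' same model is applied to technical (R1/I1) and biological (R2) reads.
#'
#' @param reads character vector of reads.
#' @param q_profile per-cycle Phred scores, at least as long as the longest
#'   read.
#' @return list with `reads` (after errors) and `qual` (Phred+33 strings).
#' @export
apply_sequencing_errors <- function(reads, q_profile) {
  nc <- nchar(reads)
  if (length(reads) > 0 && max(nc) > length(q_profile))
    stop("read length exceeds quality profile length")
  p <- 10^(-q_profile / 10)
  p[!is.finite(q_profile)] <- 0
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(if (length(reads)) max(nc) else 0L)) {
    if (p[i] <= 0) next
    eligible <- if (min(nc) >= i) seq_along(reads) else which(nc >= i)
    n_err <- stats::rbinom(1L, length(eligible), p[i])
    if (n_err == 0L) next
    pick <- if (length(eligible) == 1L) eligible else
      sample(eligible, n_err)
    cur <- substring(reads[pick], i, i)
    for (t in seq_len(n_err)) {
      pool <- setdiff(bases, cur[t])
      substr(reads[pick[t]], i, i) <- pool[sample.int(3L, 1L)]
    }
  }
  qmax <- if (length(reads)) max(nc) else 0L
  qcodes <- pmin(pmax(round(q_profile[seq_len(qmax)]), 0), 93)
  qcodes[!is.finite(qcodes)] <- 93
  qfull <- intToUtf8(qcodes + 33L)
  list(reads = reads, qual = substring(qfull, 1L, nc))
}

# decode integer codes (0-based) to DNA strings of fixed length
int_to_dna <- function(codes, len) {
  bases <- c("A", "C", "G", "T")
  m <- matrix("", nrow = length(codes), ncol = len)
  x <- codes
  for (j in len:1) {
    m[, j] <- bases[x %% 4 + 1]
    x <- x %/% 4
  }
  apply(m, 1, paste, collapse = "")
}

#' Assemble simulated FASTQ records and ground truth
#'
#' One cDNA fragment is sampled per UMI; genomic variants are planted once
#' per UMI so that all reads of a UMI derive from the same molecule, and each
#' read then receives independent sequencing errors. R1 carries
#' barcode + UMI, R2 the cDNA sequence, I1 the fixed sample index. UMI
#' sequences are drawn uniformly over the 4^umi_length space; two UMIs of
#' the same cell and gene within Hamming distance 1 of each other count as a
#' collision and are resampled, keeping the planted count well defined under
#' one-mismatch UMI collapsing.
#'
#' @param profiles a `CellProfiles`.
#' @param catalogue a `GeneCatalogue`.
#' @param genome a `Genome`.
#' @param params a `SimParams`.
#' @return object of class `SimReads`: list with `id`, `r1`, `q1`, `r2`,
#'   `q2`, `i1`, `qi1` (parallel per-read vectors), `truth` (sparse planted
#'   UMI count matrix) and `per_read` (provenance data.frame).
#' @export
assemble_reads <- function(profiles, catalogue, genome, params) {
  um <- profiles$umis
  n_umi <- nrow(um)
  if (n_umi == 0L) stop("no UMIs to simulate")
  genes <- catalogue$genes[um$gene_id, , drop = FALSE]
  span <- genes$end - genes$start + 1L
  if (any(span < params$read2_length))
    stop("catalogue contains genes shorter than read2_length; exclude them ",
         "before simulating")
  # UMI sequences per (cell, gene): pairs within Hamming distance 1 of each
  # other count as collisions and are resampled, so the planted UMI count
  # stays well defined under one-mismatch collapsing
  umi_seq <- int_to_dna(
    sample.int(4^params$umi_length, n_umi, replace = TRUE) - 1L,
    params$umi_length)
  gi <- as.integer(factor(paste(um$cell, um$gene_id, sep = "\r")))
  ord <- order(gi)
  repeat {
    comp <- .collapse_umis_grouped(gi[ord], umi_seq[ord],
                                   rep(1L, n_umi))
    n_members <- tabulate(gi)
    n_comp <- tabulate(comp$group, nbins = max(gi))
    bad <- which(n_comp < n_members)
    if (length(bad) == 0L) break
    for (g in bad) {
      idx <- which(gi == g)
      m <- length(idx)
      # redraw the later member of every distance-<=1 pair
      redraw <- rep(FALSE, m)
      for (i in seq_len(m - 1L)) {
        if (redraw[i]) next
        for (j in seq(i + 1L, m)) {
          if (!redraw[j] &&
              sum(charToRaw(umi_seq[idx[i]]) !=
                    charToRaw(umi_seq[idx[j]])) <= 1L)
            redraw[j] <- TRUE
        }
      }
      umi_seq[idx[redraw]] <- int_to_dna(
        sample.int(4^params$umi_length, sum(redraw), replace = TRUE) - 1L,
        params$umi_length)
    }
  }
  # one fragment per UMI
  d <- sample_distances(n_umi, span, params)
  L <- params$read2_length
  plus <- genes$strand == "+"
  lo <- integer(n_umi); hi <- integer(n_umi)
  hi[plus] <- genes$tpp[plus] - d[plus]
  lo[plus] <- hi[plus] - L + 1L
  lo[!plus] <- genes$tpp[!plus] + d[!plus]
  hi[!plus] <- lo[!plus] + L - 1L
  frag <- unname(substring(unclass(genome)[genes$chrom], lo, hi))
  if (any(!plus)) frag[!plus] <- revcomp(frag[!plus])
  pv <- plant_variants(frag, params$snp_rate, params$indel_rate)
  frag <- substr(pv$seqs, 1L, L)
  # replicate per read and add sequencing errors
  idx <- rep.int(seq_len(n_umi), um$reads)
  n_reads <- length(idx)
  r2 <- apply_sequencing_errors(frag[idx], params$q_profile)
  bc <- profiles$barcodes[um$cell[idx]]
  r1 <- apply_sequencing_errors(paste0(bc, umi_seq[idx]), params$q_profile)
  i1 <- apply_sequencing_errors(rep(params$sample_index, n_reads),
                                params$q_profile)
  ids <- sprintf("r%07d", seq_len(n_reads))
  per_read <- data.frame(
    read_id = ids,
    barcode = bc,
    umi = umi_seq[idx],
    gene_id = um$gene_id[idx],
    chrom = genes$chrom[idx],
    start = lo[idx], end = hi[idx],
    strand = genes$strand[idx],
    stringsAsFactors = FALSE
  )
  structure(list(
    id = ids,
    r1 = r1$reads, q1 = r1$qual,
    r2 = r2$reads, q2 = r2$qual,
    i1 = i1$reads, qi1 = i1$qual,
    truth = truth_matrix(profiles, catalogue),
    per_read = per_read
  ), class = "SimReads")
}

#' @export
print.SimReads <- function(x, ...) {
  cat("SimReads:", length(x$id), "read pair(s),",
      sum(x$truth), "planted UMI(s) in",
      ncol(x$truth), "cell(s)\n")
  invisible(x)
}

# write one FASTQ file (gzipped when path ends in .gz)
write_fastq <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a Chromium dataset to disk
#'
#' Draws cell profiles, assembles reads and writes `R1.fastq.gz`,
#' `R2.fastq.gz`, `I1.fastq.gz`, the ground-truth matrix in MatrixMarket
#' triplet form (`truth/matrix.mtx` + `barcodes.tsv` + `features.tsv`) and
#' a per-read provenance table (`per_read.tsv`).
#'
#' @param genome a `Genome`.
#' @param catalogue a `GeneCatalogue`.
#' @param whitelist character vector of barcodes.
#' @param params a `SimParams`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the `SimReads` object and output paths.
#' @export
simulate_chromium <- function(genome, catalogue, whitelist, params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- draw_cell_profiles(params, catalogue, whitelist)
  sim <- assemble_reads(profiles, catalogue, genome, params)
  paths <- list(
    r1 = file.path(out_dir, "R1.fastq.gz"),
    r2 = file.path(out_dir, "R2.fastq.gz"),
    i1 = file.path(out_dir, "I1.fastq.gz"),
    truth = file.path(out_dir, "truth"),
    per_read = file.path(out_dir, "per_read.tsv")
  )
  write_fastq(sim$id, sim$r1, sim$q1, paths$r1)
  write_fastq(sim$id, sim$r2, sim$q2, paths$r2)
  write_fastq(sim$id, sim$i1, sim$qi1, paths$i1)
  write_counts(sim$truth, paths$truth)
  utils::write.table(sim$per_read, paths$per_read, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(sim = sim, profiles = profiles, paths = paths))
}
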