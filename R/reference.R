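#' Load a reference genome from FASTA
#'
#' Reads a (possibly gzipped) FASTA file into a named character vector of
#' uppercase sequences. The chromosome name is the header token before the
#' first whitespace. Characters outside `{A,C,G,T,N}` are mapped to `N`.
#'
#' @param path path to a FASTA file, plain or gzip-compressed.
#' @return an object of class `Genome`: a named character vector, one
#'   element per chromosome.
#' @export
load_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L)
    stop("duplicate chromosome name(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(ss))
  seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1),
                 USE.NAMES = FALSE)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(nm[nchar(seqs) == 0L], collapse = ", "))
  names(seqs) <- nm
  structure(seqs, class = "Genome")
}

#' Write a genome to FASTA
#' @param genome a `Genome`.
#' @param path output path (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x), "chromosome(s),",
      format(sum(nchar(x)), big.mark = ","), "bases\n")
  for (i in seq_len(min(length(x), 10L)))
    cat("  ", names(x)[i], ": ", nchar(x[[i]]), " bases\n", sep = "")
  invisible(x)
}

#' Load gene models from a GTF file
#'
#' Parses `exon` features (1-based closed coordinates, GTF standard) into a
#' gene catalogue. Overlapping or adjacent exons of the same gene are merged;
#' strand is taken from the feature strand; genes on chromosomes absent from
#' the genome are skipped with a warning.
#'
#' The 3'-terminal coordinate of a gene (`tpp`, 1-based) is the largest exon
#' end for `+` genes and the smallest exon start for `-` genes.
#'
#' @param path path to a GTF file.
#' @param genome a `Genome`; used to validate chromosome names.
#' @return an object of class `GeneCatalogue` with components
#'   `genes` (data.frame: gene_id, chrom, strand, start, end, tpp) and
#'   `exons` (a [GenomicRanges::GRanges] of merged exons with a `gene_id`
#'   metadata column).
#' @export
load_gtf <- function(path, genome) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("GTF file '", path, "' contains no exon features")
  gid <- gr$gene_id
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    bad <- if (is.null(gid)) seq_along(gr) else which(is.na(gid) | gid == "")
    stop("exon feature(s) without gene_id (exon record ",
         paste(utils::head(bad, 3), collapse = ", "), ")")
  }
  chroms <- as.character(GenomicRanges::seqnames(gr))
  keep <- chroms %in% names(genome)
  if (!all(keep)) {
    skipped <- unique(gid[!keep])
    warning("skipping ", length(skipped),
            " gene(s) on chromosomes absent from genome: ",
            paste(utils::head(skipped, 5), collapse = ", "))
    gr <- gr[keep]
    gid <- gid[keep]
  }
  if (length(gr) == 0L) stop("no exon features left after chromosome filtering")
  build_catalogue(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    genome = genome
  )
}

#' Build a gene catalogue from exon coordinates
#'
#' @param gene_id,chrom,strand,start,end parallel vectors of exon records;
#'   coordinates 1-based closed.
#' @param genome optional `Genome` for bounds checking.
#' @return a `GeneCatalogue`.
#' @export
build_catalogue <- function(gene_id, chrom, strand, start, end, genome = NULL) {
  stopifnot(length(gene_id) == length(chrom), length(chrom) == length(start),
            length(start) == length(end), all(strand %in% c("+", "-")),
            all(start <= end))
  per_gene <- split(seq_along(gene_id), gene_id)
  ex_list <- lapply(per_gene, function(idx) {
    ch <- unique(chrom[idx]); st <- unique(strand[idx])
    if (length(ch) > 1L || length(st) > 1L)
      stop("gene '", gene_id[idx[1]], "' spans multiple chromosomes or strands")
    r <- IRanges::reduce(IRanges::IRanges(start[idx], end[idx]))
    list(chrom = ch, strand = st, ranges = r)
  })
  ids <- names(ex_list)
  chs <- vapply(ex_list, `[[`, character(1), "chrom")
  sts <- vapply(ex_list, `[[`, character(1), "strand")
  g_start <- vapply(ex_list, function(x) min(IRanges::start(x$ranges)), numeric(1))
  g_end <- vapply(ex_list, function(x) max(IRanges::end(x$ranges)), numeric(1))
  genes <- data.frame(
    gene_id = ids, chrom = chs, strand = sts,
    start = as.integer(g_start), end = as.integer(g_end),
    tpp = as.integer(ifelse(sts == "+", g_end, g_start)),
    row.names = ids, stringsAsFactors = FALSE
  )
  n_ex <- vapply(ex_list, function(x) length(x$ranges), integer(1))
  exons <- GenomicRanges::GRanges(
    seqnames = rep(chs, n_ex),
    ranges = do.call(c, unname(lapply(ex_list, `[[`, "ranges"))),
    strand = rep(sts, n_ex),
    gene_id = rep(ids, n_ex)
  )
  if (!is.null(genome)) {
    lens <- nchar(genome)[genes$chrom]
    if (any(genes$end > lens))
      stop("exon coordinates beyond chromosome end for gene(s): ",
           paste(genes$gene_id[genes$end > lens], collapse = ", "))
  }
  structure(list(genes = genes, exons = exons), class = "GeneCatalogue")
}

#' @export
print.GeneCatalogue <- function(x, ...) {
  cat("GeneCatalogue:", nrow(x$genes), "gene(s),",
      length(x$exons), "merged exon(s) on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a gene catalogue back to GTF
#' @param catalogue a `GeneCatalogue`.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalogue, path) {
  gr <- catalogue$exons
  gr$type <- "exon"
  gr$source <- "chromquant"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Genes whose exons overlap an interval
#'
#' @param catalogue a `GeneCatalogue`.
#' @param chrom chromosome name.
#' @param start,end query interval, 1-based closed.
#' @return character vector of gene ids with at least one overlapping exon
#'   base.
#' @export
gene_overlaps <- function(catalogue, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, catalogue$exons,
                                      ignore.strand = TRUE)
  unique(catalogue$exons$gene_id[S4Vectors::subjectHits(hits)])
}

#' Extract genomic sequence from a gene's 3' end
#'
#' Returns the unspliced genomic subsequence of `length` bases whose 3'-most
#' base (in transcript orientation) lies `distance` bases upstream of the
#' gene's 3' terminus. Minus-strand genes return the reverse complement. The
#' window is clipped to the gene's genomic span; a window that clips shorter
#' than `length` is returned truncated, and a `distance` beyond the gene span
#' yields an empty string.
#'
#' @param gene one row of `catalogue$genes` (or a list with fields `chrom`,
#'   `strand`, `start`, `end`, `tpp`).
#' @param genome a `Genome`.
#' @param distance non-negative integer distance upstream of the 3' end.
#' @param length window length in bases, at least 1.
#' @return a character scalar (possibly empty).
#' @export
three_prime_sequence <- function(gene, genome, distance, length) {
  stopifnot(distance >= 0, length >= 1)
  chromseq <- genome[[gene$chrom]]
  if (gene$strand == "+") {
    hi <- gene$tpp - distance
    lo <- hi - length + 1L
    lo <- max(lo, gene$start)
    if (hi < gene$start || hi < lo) return("")
    substr(chromseq, lo, hi)
  } else {
    lo <- gene$tpp + distance
    hi <- lo + length - 1L
    hi <- min(hi, gene$end)
    if (lo > gene$end || hi < lo) return("")
    revcomp(substr(chromseq, lo, hi))
  }
}

#' Build a k-mer index over a genome
#'
#' Indexes every position carrying a fully determined (N-free) k-mer;
#' occurrence lists are stored in genomic order. The index is the structure
#' the seed-and-vote aligner votes against.
#'
#' @param genome a `Genome`.
#' @param k seed length, between 8 and 24 (default 16).
#' @return an object of class `KmerIndex`.
#' @export
build_kmer_index <- function(genome, k = 16L) {
  stopifnot(k >= 8L, k <= 24L)
  ptr <- .kmer_index_build(unclass(genome), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), chroms = names(genome)),
            class = "KmerIndex")
}

#' @export
print.KmerIndex <- function(x, ...) {
  cat("KmerIndex: k =", x$k, "over", length(x$chroms), "chromosome(s),",
      format(.kmer_index_nkeys(x$ptr), big.mark = ","), "distinct k-mers\n")
  invisible(x)
}

#' Look up a k-mer's occurrences
#'
#' @param index a `KmerIndex`.
#' @param kmer a k-length nucleotide string.
#' @return data.frame with columns `chrom` (name) and `pos` (1-based start),
#'   empty if the k-mer is absent or contains N.
#' @export
kmer_lookup <- function(index, kmer) {
  hits <- .kmer_index_lookup(index$ptr, kmer)
  data.frame(chrom = index$chroms[hits$chrom], pos = hits$pos,
             stringsAsFactors = FALSE)
}
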