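#' Extract evenly spaced seeds from a read
#'
#' Up to `n_seeds` k-mers at offsets `round(i*(L-k)/(n-1))` for
#' `i = 0..n-1`, deduplicated by offset; seeds containing N are dropped.
#'
#' @param read a nucleotide string.
#' @param n_seeds number of seeds (default 15).
#' @param k seed length (default 16).
#' @return data.frame with columns `offset` (0-based position in the read)
#'   and `kmer`; zero rows if the read is shorter than `k`.
#' @export
extract_seeds <- function(read, n_seeds = 15L, k = 16L) {
  L <- nchar(read)
  if (L < k)
    return(data.frame(offset = integer(0), kmer = character(0),
                      stringsAsFactors = FALSE))
  off <- .seed_offsets(L, as.integer(k), as.integer(n_seeds))
  kmer <- substring(read, off + 1L, off + k)
  keep <- !grepl("[^ACGT]", kmer)
  data.frame(offset = off[keep], kmer = kmer[keep], stringsAsFactors = FALSE)
}

#' Candidate mapping locations for one read
#'
#' Looks up each seed in the k-mer index on both strands, translates
#' occurrences to implied read-start positions and pools implied starts
#' within `max_indel` of each other into candidates; every candidate with at
#' least one vote is reported.
#'
#' @param read a nucleotide string.
#' @param index a `KmerIndex`.
#' @param n_seeds number of seeds.
#' @param max_indel pooling window (bases).
#' @return data.frame with columns `chrom`, `pos` (1-based implied read
#'   start), `strand`, `votes`.
#' @export
vote_read <- function(read, index, n_seeds = 15L, max_indel = 16L) {
  v <- .vote_read(index$ptr, read, as.integer(n_seeds), as.integer(max_indel))
  data.frame(chrom = index$chroms[v$chrom], pos = v$pos,
             strand = as.character(v$strand), votes = v$votes,
             stringsAsFactors = FALSE)
}

# merged exon intervals per index chromosome, 0-based half-open
exon_interval_lists <- function(index, catalogue) {
  red <- GenomicRanges::reduce(catalogue$exons, ignore.strand = TRUE)
  chr <- as.character(GenomicRanges::seqnames(red))
  starts <- lapply(index$chroms, function(cn) {
    as.integer(BiocGenerics::start(red)[chr == cn] - 1L)
  })
  ends <- lapply(index$chroms, function(cn) {
    as.integer(BiocGenerics::end(red)[chr == cn])
  })
  list(starts = starts, ends = ends)
}

#' Align reads with the sensitized seed-and-vote scheme
#'
#' Seeds vote for candidate locations on both strands; the best-voted
#' candidates (up to `max_candidates`) are extended over the full read,
#' placing at most one indel inferred from the offset difference between the
#' candidate's two best-supported implied starts. The alignment score is
#' `matched - mismatched` bases; among score ties a location overlapping a
#' catalogued gene is preferred, and remaining ties go to the smallest
#' (chrom, position). Reads whose best score falls below `min_score` are
#' reported unmapped.
#'
#' @param reads character vector of read sequences.
#' @param index a `KmerIndex`.
#' @param catalogue a `GeneCatalogue` (gene-overlap preference); may be
#'   `NULL` to disable the preference.
#' @param n_seeds,min_votes,min_score,max_indel,max_candidates tuning
#'   parameters (defaults 15, 1, 16, 16, 8).
#' @return data.frame of `AlignmentRecord`s, one row per read: `read`,
#'   `mapped`, `chrom`, `pos` (1-based), `strand`, `matched`, `mismatched`,
#'   `votes`, `score`, `indel_pos` (1-based offset in the read), `indel_len`
#'   (>0 deletion, <0 insertion, 0 none), `ref_span`, `gene_overlap`.
#' @export
align_reads <- function(reads, index, catalogue = NULL, n_seeds = 15L,
                        min_votes = 1L, min_score = 16L, max_indel = 16L,
                        max_candidates = 8L) {
  if (is.null(catalogue)) {
    ex <- list(starts = rep(list(integer(0)), length(index$chroms)),
               ends = rep(list(integer(0)), length(index$chroms)))
  } else {
    ex <- exon_interval_lists(index, catalogue)
  }
  a <- .align_reads(index$ptr, as.character(reads), as.integer(n_seeds),
                    as.integer(min_votes), as.integer(min_score),
                    as.integer(max_indel), as.integer(max_candidates),
                    ex$starts, ex$ends)
  a$chrom <- index$chroms[a$chrom]
  a$strand <- as.character(a$strand)
  a$read <- seq_along(reads)
  a[, c("read", setdiff(names(a), "read"))]
}
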