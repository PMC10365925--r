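# Independent brute-force oracles used to pin expected values.
# These deliberately avoid the package's own k-mer index / union-find /
# voting code paths.

# all start positions (1-based) of `kmer` in `s` by sliding comparison
oracle_kmer_positions <- function(s, kmer) {
  k <- nchar(kmer)
  n <- nchar(s)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  hits <- starts[substring(s, starts, starts + k - 1L) == kmer]
  hits
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

rc_chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
oracle_revcomp <- function(x) paste(rev(rc_chars[chars(x)]), collapse = "")

# best ungapped Hamming alignment of `read` over a genome (named character
# vector), both strands, score = matched - mismatched over full-length
# in-bounds placements; ties: gene overlap first (exon data.frame with
# chrom/start/end, may be NULL), then chrom order, position, forward strand.
oracle_hamming_align <- function(read, genome, exons = NULL) {
  L <- nchar(read)
  best <- NULL
  consider <- function(chrom, pos, strand, score) {
    ov <- FALSE
    if (!is.null(exons)) {
      ov <- any(exons$chrom == chrom & exons$start <= pos + L - 1L &
                  exons$end >= pos)
    }
    cand <- list(chrom = chrom, pos = pos, strand = strand, score = score,
                 overlap = ov)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    better <- FALSE
    if (cand$score != best$score) better <- cand$score > best$score
    else if (cand$overlap != best$overlap) better <- cand$overlap
    else if (cand$chrom != best$chrom)
      better <- match(cand$chrom, names(genome)) < match(best$chrom, names(genome))
    else if (cand$pos != best$pos) better <- cand$pos < best$pos
    else better <- cand$strand == "+" && best$strand == "-"
    if (better) best <<- cand
  }
  for (cn in names(genome)) {
    g <- chars(genome[[cn]])
    n <- length(g)
    if (n < L) next
    E <- sapply(seq_len(L), function(j) g[seq_len(n - L + 1L) + j - 1L])
    if (is.null(dim(E))) E <- matrix(E, nrow = 1L)
    for (strand in c("+", "-")) {
      r <- if (strand == "+") chars(read) else chars(oracle_revcomp(read))
      mm <- rowSums(E != matrix(r, nrow(E), L, byrow = TRUE))
      sc <- (L - mm) - mm
      for (pos in seq_along(sc)) consider(cn, pos, strand, sc[pos])
    }
  }
  best
}

# single-linkage components of UMIs under Hamming distance <= 1
oracle_umi_components <- function(umis) {
  n <- length(umis)
  comp <- seq_len(n)
  d1 <- function(a, b) sum(chars(a) != chars(b)) <= 1L
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && d1(umis[i], umis[j])) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# brute-force one-mismatch barcode correction
oracle_correct_barcode <- function(obs, wl) {
  if (obs %in% wl) return(obs)
  d <- vapply(wl, function(w) sum(chars(obs) != chars(w)), numeric(1))
  hit <- wl[d == 1]
  if (length(hit) == 1L) hit else NA_character_
}
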