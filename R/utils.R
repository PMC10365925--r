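#' Reverse complement of nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a stage-specific RNG seed from a global seed
#'
#' Stages of the pipeline draw from independent streams keyed by stage name,
#' so each stage is individually reproducible from the global seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2123 + h * 7919) %% 2147483587) + 1L
}

# uniformly sample n random DNA strings of given length
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = len)
  apply(m, 2, paste, collapse = "")
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
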