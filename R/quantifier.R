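#' Read a barcode whitelist
#'
#' @param path text file with one barcode per line, optionally gzipped.
#' @return a `BarcodeWhitelist`.
#' @export
read_whitelist <- function(path) {
  barcode_whitelist(readLines(path))
}

#' Construct a barcode whitelist
#'
#' @param barcodes character vector of equal-length barcode sequences.
#' @return an object of class `BarcodeWhitelist`.
#' @export
barcode_whitelist <- function(barcodes) {
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(barcodes) == 0L) stop("empty whitelist")
  if (length(unique(nchar(barcodes))) != 1L)
    stop("whitelist barcodes must all have the same length")
  if (anyDuplicated(barcodes)) stop("whitelist contains duplicate barcodes")
  structure(list(barcodes = barcodes, length = nchar(barcodes[1])),
            class = "BarcodeWhitelist")
}

#' @export
print.BarcodeWhitelist <- function(x, ...) {
  cat("BarcodeWhitelist:", length(x$barcodes), "barcode(s) of length",
      x$length, "\n")
  invisible(x)
}

#' Correct observed cell barcodes against a whitelist
#'
#' An exact whitelist member is kept as is; otherwise, if exactly one
#' whitelist barcode lies at Hamming distance 1 the observed barcode is
#' corrected to it; zero or several distance-1 candidates reject the barcode
#' (the read is dropped from quantification). Barcodes of the wrong length
#' are rejected and counted.
#'
#' @param observed character vector of observed barcodes.
#' @param whitelist a `BarcodeWhitelist`.
#' @return character vector of corrected barcodes, `NA` where rejected, with
#'   attribute `n_length_mismatch` counting wrong-length inputs.
#' @export
correct_barcodes <- function(observed, whitelist) {
  wl <- whitelist$barcodes
  L <- whitelist$length
  u <- unique(observed)
  good_len <- nchar(u) == L
  corrected_u <- rep(NA_character_, length(u))
  exact <- good_len & (u %in% wl)
  corrected_u[exact] <- u[exact]
  todo <- which(good_len & !exact)
  if (length(todo) > 0L) {
    cand_n <- integer(length(todo))
    cand <- character(length(todo))
    base <- u[todo]
    for (pos in seq_len(L)) {
      for (b in c("A", "C", "G", "T")) {
        v <- base
        substr(v, pos, pos) <- b
        hit <- v != base & v %in% wl
        cand_n[hit] <- cand_n[hit] + 1L
        cand[hit] <- v[hit]
      }
    }
    one <- cand_n == 1L
    corrected_u[todo[one]] <- cand[one]
  }
  out <- corrected_u[match(observed, u)]
  attr(out, "n_length_mismatch") <- sum(nchar(observed) != L)
  out
}

#' Assign mapped reads to genes
#'
#' featureCounts-style assignment against the exon unions: genes overlapping
#' the aligned interval by at least one base are collected; a single
#' overlapper is assigned, none yields `no_feature`, several yield the gene
#' with the largest base overlap, and an exact tie on the largest overlap
#' yields `ambiguous`.
#'
#' @param alignments data.frame from [align_reads()] (mapped rows are
#'   considered; unmapped rows get status `unmapped`).
#' @param catalogue a `GeneCatalogue`.
#' @return data.frame with one row per alignment row: `gene_id` (`NA` when
#'   unassigned) and `status` in assigned/no_feature/ambiguous/unmapped.
#' @export
assign_to_genes <- function(alignments, catalogue) {
  n <- nrow(alignments)
  gene_id <- rep(NA_character_, n)
  status <- rep("unmapped", n)
  m <- which(alignments$mapped)
  if (length(m) > 0L) {
    status[m] <- "no_feature"
    q <- GenomicRanges::GRanges(
      alignments$chrom[m],
      IRanges::IRanges(alignments$pos[m],
                       alignments$pos[m] + alignments$ref_span[m] - 1L)
    )
    hits <- GenomicRanges::findOverlaps(q, catalogue$exons, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      w <- BiocGenerics::width(IRanges::pintersect(
        GenomicRanges::ranges(q)[qh], GenomicRanges::ranges(catalogue$exons)[sh]))
      g <- catalogue$exons$gene_id[sh]
      key <- paste0(qh, "\r", g)
      agg <- rowsum(w, key, reorder = FALSE)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      rq <- as.integer(vapply(parts, `[[`, character(1), 1L))
      rg <- vapply(parts, `[[`, character(1), 2L)
      rw <- agg[, 1]
      ord <- order(rq, -rw, rg)
      rq <- rq[ord]; rg <- rg[ord]; rw <- rw[ord]
      first <- !duplicated(rq)
      best_w <- rw[first][match(rq, rq[first])]
      # a second gene matching the best overlap makes the read ambiguous
      tied <- tapply(rw == best_w, rq, sum) > 1L
      amb <- names(tied)[tied]
      idx <- rq[first]
      gene_id[m[idx]] <- rg[first]
      status[m[idx]] <- "assigned"
      amb_i <- as.integer(amb)
      gene_id[m[amb_i]] <- NA_character_
      status[m[amb_i]] <- "ambiguous"
    }
  }
  data.frame(gene_id = gene_id, status = status, stringsAsFactors = FALSE)
}

#' Collapse UMIs within one gene and barcode
#'
#' UMIs at Hamming distance at most 1 are joined into a graph; the
#' deduplicated count is the number of connected components. Each
#' component's representative is its highest-read-count UMI (ties broken by
#' the lexicographically smallest sequence) and carries the component's
#' summed reads, for later cross-gene resolution.
#'
#' @param umi_read_counts named integer vector: UMI sequence -> read count.
#' @return list with `count` (number of components) and `components`
#'   (data.frame: `umi` representative, `reads` summed).
#' @export
collapse_umis <- function(umi_read_counts) {
  if (length(umi_read_counts) == 0L)
    return(list(count = 0L,
                components = data.frame(umi = character(0), reads = integer(0),
                                        stringsAsFactors = FALSE)))
  stopifnot(length(unique(nchar(names(umi_read_counts)))) == 1L)
  res <- .collapse_umis_grouped(rep(1L, length(umi_read_counts)),
                                names(umi_read_counts),
                                as.integer(umi_read_counts))
  list(count = nrow(res),
       components = data.frame(umi = res$umi, reads = res$reads,
                               stringsAsFactors = FALSE))
}

#' Resolve UMIs claimed by multiple genes of one barcode
#'
#' A UMI representative appearing under several genes is kept only by the
#' gene with the most supporting reads; ties go to the lexicographically
#' smallest gene id. Each surviving (gene, UMI) pair contributes one count.
#'
#' @param tbl data.frame with columns `gene_id`, `umi`, `reads` — the
#'   collapsed components across all genes of one barcode.
#' @return the surviving rows of `tbl`.
#' @export
resolve_multigene_umis <- function(tbl) {
  if (nrow(tbl) == 0L) return(tbl)
  ord <- order(tbl$umi, -tbl$reads, tbl$gene_id)
  tbl <- tbl[ord, , drop = FALSE]
  tbl[!duplicated(tbl$umi), , drop = FALSE]
}

#' Build the UMI count matrix from read assignments
#'
#' Groups assigned reads by (barcode, gene), collapses UMIs within each
#' group allowing one mismatch, then resolves UMI representatives claimed by
#' several genes of the same barcode. Rows cover all catalogue genes;
#' columns cover every barcode with at least one assigned read.
#'
#' @param assignments data.frame with columns `barcode` (corrected), `umi`
#'   and `gene_id`, one row per assigned read.
#' @param catalogue a `GeneCatalogue`.
#' @return sparse genes x barcodes matrix of deduplicated UMI counts.
#' @export
build_matrix <- function(assignments, catalogue) {
  ids <- catalogue$genes$gene_id
  bcs <- sort(unique(assignments$barcode))
  if (nrow(assignments) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(ids), 0),
                                dimnames = list(ids, character(0))))
  key3 <- paste(assignments$barcode, assignments$gene_id, assignments$umi,
                sep = "\r")
  tab <- rowsum(rep(1L, length(key3)), key3)
  parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
  bc <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  umi <- vapply(parts, `[[`, character(1), 3L)
  reads <- as.integer(tab[, 1])
  grp_key <- paste(bc, gene, sep = "\r")
  grp <- as.integer(factor(grp_key))
  ord <- order(grp)
  col <- .collapse_umis_grouped(grp[ord], umi[ord], reads[ord])
  lev <- levels(factor(grp_key))
  gparts <- strsplit(lev[col$group], "\r", fixed = TRUE)
  comp <- data.frame(
    barcode = vapply(gparts, `[[`, character(1), 1L),
    gene_id = vapply(gparts, `[[`, character(1), 2L),
    umi = col$umi, reads = col$reads, stringsAsFactors = FALSE
  )
  sp <- split(comp, comp$barcode)
  kept_list <- lapply(sp, function(d)
    resolve_multigene_umis(d[, c("gene_id", "umi", "reads")]))
  kept <- do.call(rbind, kept_list)
  kept$barcode <- rep(names(sp), vapply(kept_list, nrow, integer(1)))
  gi <- match(kept$gene_id, ids)
  bi <- match(kept$barcode, bcs)
  Matrix::sparseMatrix(i = gi, j = bi, x = 1,
                       dims = c(length(ids), length(bcs)),
                       dimnames = list(ids, bcs), use.last.ij = FALSE)
}

#' Read sequences from a FASTQ file
#' @param path FASTQ path, optionally gzipped.
#' @return list with `id` and `seq` character vectors.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  list(id = sub("\\s.*$", "", names(ss)), seq = toupper(as.character(ss)))
}

#' Quantify paired Chromium reads into a UMI count matrix
#'
#' Full quantification path: parse barcode and UMI from R1, correct barcodes
#' against the whitelist (one mismatch), align R2 with the seed-and-vote
#' aligner, assign mapped reads to genes, collapse UMIs and resolve
#' cross-gene UMIs.
#'
#' @param r1,r2 character vectors of R1 (barcode+UMI) and R2 (cDNA)
#'   sequences, parallel.
#' @param index a `KmerIndex`.
#' @param catalogue a `GeneCatalogue`.
#' @param whitelist a `BarcodeWhitelist`.
#' @param barcode_length,umi_length segment lengths in R1.
#' @param ... further arguments to [align_reads()].
#' @return list with `matrix` (sparse UMI counts), `stats` (read
#'   accounting: reads_in, barcode_rejected, unmapped, unassigned, assigned)
#'   and `assignments` (per-assigned-read data.frame).
#' @export
quantify_reads <- function(r1, r2, index, catalogue, whitelist,
                           barcode_length = 16L, umi_length = 12L, ...) {
  stopifnot(length(r1) == length(r2))
  bc_obs <- substr(r1, 1L, barcode_length)
  umi <- substr(r1, barcode_length + 1L, barcode_length + umi_length)
  bc <- correct_barcodes(bc_obs, whitelist)
  bc_ok <- !is.na(bc)
  aln <- align_reads(r2, index, catalogue, ...)
  asg <- assign_to_genes(aln, catalogue)
  keep <- bc_ok & asg$status == "assigned"
  stats <- c(
    reads_in = length(r1),
    barcode_rejected = sum(!bc_ok),
    unmapped = sum(bc_ok & !aln$mapped),
    unassigned = sum(bc_ok & aln$mapped & asg$status != "assigned"),
    assigned = sum(keep)
  )
  assignments <- data.frame(
    read = which(keep), barcode = bc[keep], umi = umi[keep],
    gene_id = asg$gene_id[keep], stringsAsFactors = FALSE
  )
  list(matrix = build_matrix(assignments, catalogue), stats = stats,
       assignments = assignments)
}

#' Write a count matrix in CellRanger-style triplet layout
#'
#' @param mat sparse genes x barcodes matrix with dimnames.
#' @param dir output directory.
#' @param mtx_name file name for the MatrixMarket part.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(mat, dir, mtx_name = "matrix.mtx") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), file.path(dir, mtx_name))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts()]
#' @param dir directory containing the triplet files.
#' @param mtx_name file name of the MatrixMarket part.
#' @return sparse matrix with dimnames restored.
#' @export
read_counts <- function(dir, mtx_name = "matrix.mtx") {
  m <- Matrix::readMM(file.path(dir, mtx_name))
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}
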