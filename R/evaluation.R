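#' log2 counts-per-million transformation
#'
#' `value(g, c) = log2((count(g, c) + offset) / libsize(c) * 1e6)` with the
#' library size taken as the raw (offset-free) column total. Cells with a
#' zero library size are excluded with a warning unless `zero_libsize` is
#' `"one"`, in which case their library size is set to 1 so that missing
#' cells can still be scored as all-zero columns.
#'
#' @param mat genes x cells matrix of non-negative integer UMI counts.
#' @param offset pseudo-count added to counts before the log (default 0.5).
#' @param zero_libsize `"exclude"` (default) or `"one"`.
#' @return dense matrix of log2-cpm values with attributes `offset` and
#'   `libsize`.
#' @export
log2_cpm <- function(mat, offset = 0.5, zero_libsize = c("exclude", "one")) {
  zero_libsize <- match.arg(zero_libsize)
  lib <- Matrix::colSums(mat)
  if (any(lib == 0)) {
    if (zero_libsize == "exclude") {
      warning(sum(lib == 0), " cell(s) with zero library size excluded")
      mat <- mat[, lib > 0, drop = FALSE]
      lib <- lib[lib > 0]
    } else {
      lib[lib == 0] <- 1
    }
  }
  dense <- as.matrix(mat)
  out <- log2(sweep(dense + offset, 2, lib, "/") * 1e6)
  attr(out, "offset") <- offset
  attr(out, "libsize") <- lib
  out
}

#' RMSE of log2-cpm expression against ground truth
#'
#' Matrices are matched by gene id (rows) and barcode (columns of the truth
#' matrix); truth cells missing from the estimate are scored against
#' all-zero columns (library size 1), or excluded when
#' `missing_cells = "exclude"`. The RMSE is taken jointly over all matched
#' gene x cell entries.
#'
#' @param est,truth genes x cells UMI count matrices with dimnames.
#' @param offset pseudo-count for the log2-cpm transform.
#' @param missing_cells `"zero"` (default) or `"exclude"`.
#' @return the RMSE (numeric scalar).
#' @export
expression_rmse <- function(est, truth, offset = 0.5,
                            missing_cells = c("zero", "exclude")) {
  missing_cells <- match.arg(missing_cells)
  cells <- colnames(truth)
  if (missing_cells == "exclude") cells <- intersect(cells, colnames(est))
  if (length(cells) == 0L) stop("no overlapping cells between matrices")
  genes <- union(rownames(truth), rownames(est))
  expand <- function(m) {
    out <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(genes), length(cells)),
                                dimnames = list(genes, cells))
    gi <- intersect(rownames(m), genes)
    ci <- intersect(colnames(m), cells)
    out[gi, ci] <- m[gi, ci]
    out
  }
  e <- log2_cpm(expand(est), offset, zero_libsize = "one")
  t <- log2_cpm(expand(truth), offset, zero_libsize = "one")
  sqrt(mean((e - t)^2))
}

#' In-silico mixture concordance
#'
#' Pseudo-bulk expression profiles (pooled counts per gene, converted to
#' cpm) are computed for samples A, B and the sequenced mixture; the
#' predicted mixture profile is `ratio * cpmA + (1 - ratio) * cpmB` on the
#' cpm scale. Returns the RMSE between predicted and observed mixture
#' profiles on the log2 scale, over genes shared by all three matrices.
#'
#' @param mat_a,mat_b,mat_mix genes x cells UMI count matrices.
#' @param ratio fraction of sample A in the mixture, strictly in (0, 1).
#' @param offset pseudo-count for the cpm transform.
#' @return the concordance RMSE (numeric scalar).
#' @export
mixture_concordance <- function(mat_a, mat_b, mat_mix, ratio, offset = 0.5) {
  stopifnot(ratio > 0, ratio < 1)
  genes <- Reduce(intersect, list(rownames(mat_a), rownames(mat_b),
                                  rownames(mat_mix)))
  if (length(genes) == 0L) stop("no shared genes")
  bulk_cpm <- function(m) {
    counts <- Matrix::rowSums(m[genes, , drop = FALSE])
    (counts + offset) / sum(counts) * 1e6
  }
  pred <- ratio * bulk_cpm(mat_a) + (1 - ratio) * bulk_cpm(mat_b)
  obs <- bulk_cpm(mat_mix)
  sqrt(mean((log2(pred) - log2(obs))^2))
}

#' Cell recall of a calling result
#'
#' @param called a `CallResult` or a character vector of called barcodes.
#' @param truth_barcodes barcodes of the true (planted) cells.
#' @return fraction of truth barcodes that were called.
#' @export
cell_recall <- function(called, truth_barcodes) {
  stopifnot(length(truth_barcodes) > 0)
  if (inherits(called, "CallResult")) called <- called_barcodes(called)
  length(intersect(called, truth_barcodes)) / length(unique(truth_barcodes))
}
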