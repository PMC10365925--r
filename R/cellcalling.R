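#' Cell-calling parameters
#'
#' Parameters for the two-stage CellRanger-3.0-style procedure: a bootstrap
#' total-UMI cutoff for high-confidence cells, an ambient-RNA expression
#' profile estimated from very-low-count barcodes, and a Monte-Carlo
#' multinomial rescue of sub-threshold barcodes whose profiles deviate from
#' ambient (Benjamini-Hochberg controlled).
#'
#' @param expected_cells expected number of cells (default 3000).
#' @param bootstrap_reps bootstrap resamples for the cutoff (default 100).
#' @param quantile quantile of the top-`expected_cells` block (default 0.99).
#' @param divisor the quantile is divided by this factor (default 10).
#' @param ambient_rank_range two barcode ranks (by descending total UMI)
#'   bounding the window used for ambient estimation, clipped to the
#'   available barcodes (default ranks 10000 to 100000).
#' @param rescue_floor minimum total UMI for a rescue candidate (default 10).
#' @param rescue_mc_iters Monte-Carlo iterations per candidate total
#'   (default 10000).
#' @param fdr_threshold BH false discovery rate for rescue (default 0.01).
#' @return an object of class `CallParams`.
#' @export
call_params <- function(expected_cells = 3000L, bootstrap_reps = 100L,
                        quantile = 0.99, divisor = 10,
                        ambient_rank_range = c(10000L, 100000L),
                        rescue_floor = 10L, rescue_mc_iters = 10000L,
                        fdr_threshold = 0.01) {
  stopifnot(expected_cells >= 1, bootstrap_reps >= 1,
            quantile > 0, quantile < 1, divisor > 1,
            length(ambient_rank_range) == 2L,
            ambient_rank_range[1] <= ambient_rank_range[2],
            rescue_floor >= 1, rescue_mc_iters >= 1,
            fdr_threshold > 0, fdr_threshold < 1)
  structure(list(expected_cells = as.integer(expected_cells),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 quantile = quantile, divisor = divisor,
                 ambient_rank_range = as.integer(ambient_rank_range),
                 rescue_floor = as.integer(rescue_floor),
                 rescue_mc_iters = as.integer(rescue_mc_iters),
                 fdr_threshold = fdr_threshold),
            class = "CallParams")
}

#' Bootstrap total-UMI cutoff for high-confidence cells
#'
#' For each bootstrap resample of the per-barcode totals (with replacement,
#' same size), the `quantile` quantile of the top `expected_cells` totals is
#' divided by `divisor`; the threshold is the mean over resamples.
#'
#' @param totals numeric vector of per-barcode total UMI counts.
#' @param p a `CallParams`.
#' @return the threshold (numeric scalar); barcodes with total at or above
#'   it are high-confidence.
#' @export
bootstrap_threshold <- function(totals, p = call_params()) {
  if (!any(totals > 0)) stop("no barcode with a positive total")
  totals <- sort(unname(totals))  # threshold invariant to barcode order
  n_top <- p$expected_cells
  n_nz <- sum(totals > 0)
  if (n_nz < n_top) {
    warning("fewer nonzero barcodes (", n_nz, ") than expected_cells (",
            n_top, "); lowering expected_cells")
    n_top <- n_nz
  }
  n <- length(totals)
  reps <- vapply(seq_len(p$bootstrap_reps), function(i) {
    rs <- totals[sample.int(n, n, replace = TRUE)]
    top <- sort(rs, decreasing = TRUE)[seq_len(n_top)]
    stats::quantile(top, p$quantile, names = FALSE) / p$divisor
  }, numeric(1))
  mean(reps)
}

#' Estimate the ambient-RNA expression profile
#'
#' Gene counts are summed over the barcodes ranked (by descending total UMI)
#' inside `ambient_rank_range`, a pseudocount of 1 is added per gene and the
#' result is normalized to proportions. An empty window falls back to a
#' uniform profile with a warning.
#'
#' @param mat sparse genes x barcodes UMI count matrix.
#' @param p a `CallParams`.
#' @return named numeric vector of per-gene proportions summing to 1.
#' @export
estimate_ambient <- function(mat, p = call_params()) {
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty count matrix")
  totals <- Matrix::colSums(mat)
  ord <- order(totals, decreasing = TRUE)
  lo <- p$ambient_rank_range[1]
  hi <- min(p$ambient_rank_range[2], ncol(mat))
  if (lo > ncol(mat)) {
    warning("ambient rank window beyond available barcodes; ",
            "using a uniform ambient profile")
    prof <- rep(1 / nrow(mat), nrow(mat))
    names(prof) <- rownames(mat)
    return(prof)
  }
  win <- ord[lo:hi]
  counts <- Matrix::rowSums(mat[, win, drop = FALSE]) + 1
  prof <- counts / sum(counts)
  names(prof) <- rownames(mat)
  prof
}

# multinomial log-likelihood of count columns under profile `prob`
multinom_loglik <- function(counts, prob) {
  lp <- log(prob)
  tot <- colSums(counts)
  lgamma(tot + 1) - colSums(lgamma(counts + 1)) + colSums(counts * lp)
}

#' Rescue sub-threshold barcodes with non-ambient profiles
#'
#' Candidates are barcodes below the threshold with total UMI at or above
#' the floor. Each candidate receives a Monte-Carlo p-value for its count
#' vector under a multinomial with the candidate's total and the ambient
#' proportions, using the multinomial log-likelihood as test statistic with
#' the add-one correction `(r+1)/(N+1)`. Candidates at FDR below
#' `fdr_threshold` (Benjamini-Hochberg) are rescued.
#'
#' @param mat sparse genes x barcodes UMI count matrix.
#' @param ambient ambient profile from [estimate_ambient()].
#' @param threshold cutoff from [bootstrap_threshold()].
#' @param p a `CallParams`.
#' @return character vector of rescued barcodes.
#' @export
rescue_barcodes <- function(mat, ambient, threshold, p = call_params()) {
  totals <- Matrix::colSums(mat)
  cand <- which(totals < threshold & totals >= p$rescue_floor)
  if (length(cand) == 0L) return(character(0))
  cm <- as.matrix(mat[, cand, drop = FALSE])
  obs_ll <- multinom_loglik(cm, ambient)
  tot <- colSums(cm)
  pval <- numeric(length(cand))
  for (t in unique(tot)) {
    sim <- stats::rmultinom(p$rescue_mc_iters, t, ambient)
    sim_ll <- multinom_loglik(sim, ambient)
    sel <- tot == t
    r <- vapply(obs_ll[sel], function(o) sum(sim_ll <= o), numeric(1))
    pval[sel] <- (r + 1) / (p$rescue_mc_iters + 1)
  }
  ok <- stats::p.adjust(pval, method = "BH") < p$fdr_threshold
  colnames(mat)[cand[ok]]
}

#' Call cells from a UMI count matrix
#'
#' Composes the three stages: bootstrap cutoff for high-confidence cells,
#' ambient profile estimation, and rescue of sub-threshold barcodes with
#' significantly non-ambient profiles.
#'
#' @param mat sparse genes x barcodes UMI count matrix.
#' @param p a `CallParams`.
#' @return an object of class `CallResult`: list with `high_confidence` and
#'   `rescued` barcode vectors, `ambient_profile`, `threshold`, `totals` and
#'   `params`.
#' @export
call_cells <- function(mat, p = call_params()) {
  totals <- Matrix::colSums(mat)
  threshold <- bootstrap_threshold(totals, p)
  high <- colnames(mat)[totals >= threshold]
  ambient <- estimate_ambient(mat, p)
  rescued <- rescue_barcodes(mat, ambient, threshold, p)
  structure(list(high_confidence = high, rescued = rescued,
                 ambient_profile = ambient, threshold = threshold,
                 totals = totals, params = p),
            class = "CallResult")
}

#' Barcodes called as cells
#' @param result a `CallResult`.
#' @return character vector: high-confidence plus rescued barcodes.
#' @export
called_barcodes <- function(result) {
  c(result$high_confidence, result$rescued)
}

#' @export
print.CallResult <- function(x, ...) {
  cat("CallResult: threshold", format(x$threshold, digits = 4), "->",
      length(x$high_confidence), "high-confidence cell(s),",
      length(x$rescued), "rescued cell(s) of", length(x$totals),
      "barcode(s)\n")
  invisible(x)
}

#' Write a cell-calling result as a table
#'
#' Emits `cells.tsv` with columns barcode, total and status
#' (high_confidence or rescued).
#'
#' @param result a `CallResult`.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_cells <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bc <- called_barcodes(result)
  df <- data.frame(
    barcode = bc,
    total = as.integer(result$totals[bc]),
    status = rep(c("high_confidence", "rescued"),
                 c(length(result$high_confidence), length(result$rescued))),
    stringsAsFactors = FALSE
  )
  path <- file.path(dir, "cells.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
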