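#' Generate a tiny synthetic reference fixture
#'
#' Builds a random genome carrying `n_genes` non-overlapping single-exon
#' genes (each at least 600 bases so the 350 +/- 30 fragment window fits),
#' the matching GTF, and a whitelist of random distinct barcodes with
#' pairwise Hamming distance at least 3 (so one-mismatch barcode correction
#' is never ambiguous).
#'
#' @param n_genes number of genes.
#' @param genome_size genome length in bases (single chromosome).
#' @param gene_length span of each gene (default 1000, minimum 600).
#' @param whitelist_size number of whitelist barcodes.
#' @param barcode_length barcode length (default 16).
#' @param out_dir optional directory; when given, `genome.fa`, `genes.gtf`
#'   and `whitelist.txt` are written there.
#' @return list with `genome`, `catalogue`, `whitelist` and (when written)
#'   `paths`. Set the RNG seed before calling for reproducible fixtures.
#' @export
make_fixture <- function(n_genes = 20L, genome_size = 50000L,
                         gene_length = 1000L, whitelist_size = 1000L,
                         barcode_length = 16L, out_dir = NULL) {
  stopifnot(n_genes >= 1, gene_length >= 600)
  slot <- genome_size %/% n_genes
  if (slot < gene_length + 20L)
    stop("infeasible packing: ", n_genes, " genes of ", gene_length,
         " bases do not fit in ", genome_size, " bases")
  seqs <- paste(random_dna(1L, genome_size), collapse = "")
  genome <- structure(c(chr1 = seqs), class = "Genome")
  jitter <- sample.int(slot - gene_length - 10L, n_genes, replace = TRUE)
  start <- (seq_len(n_genes) - 1L) * slot + jitter
  end <- start + gene_length - 1L
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ids <- sprintf("g%03d", seq_len(n_genes))
  catalogue <- build_catalogue(gene_id = ids, chrom = rep("chr1", n_genes),
                               strand = strand, start = start, end = end,
                               genome = genome)
  whitelist <- make_whitelist(whitelist_size, barcode_length)
  out <- list(genome = genome, catalogue = catalogue, whitelist = whitelist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(out_dir, "genome.fa"),
                  gtf = file.path(out_dir, "genes.gtf"),
                  whitelist = file.path(out_dir, "whitelist.txt"))
    write_fasta(genome, paths$fasta)
    write_gtf(catalogue, paths$gtf)
    writeLines(whitelist, paths$whitelist)
    out$paths <- paths
  }
  out
}

# indices of barcodes violating pairwise Hamming distance >= 3 (the later
# member of each offending pair), found by pigeonhole: two barcodes at
# distance <= 2 agree exactly on at least one of three parts
dist3_offenders <- function(barcodes) {
  L <- nchar(barcodes[1])
  cuts <- round(c(0, L / 3, 2 * L / 3, L))
  bad <- integer(0)
  for (k in 1:3) {
    part <- substr(barcodes, cuts[k] + 1L, cuts[k + 1])
    for (grp in split(seq_along(barcodes), part)) {
      if (length(grp) < 2L) next
      for (i in seq_len(length(grp) - 1L)) {
        for (j in seq(i + 1L, length(grp))) {
          if (hamming(barcodes[grp[i]], barcodes[grp[j]]) <= 2L)
            bad <- c(bad, grp[j])
        }
      }
    }
  }
  unique(bad)
}

#' Generate a whitelist of well-separated barcodes
#'
#' Random distinct barcodes with pairwise Hamming distance at least 3.
#'
#' @param n number of barcodes.
#' @param barcode_length barcode length.
#' @return character vector of barcodes.
#' @export
make_whitelist <- function(n, barcode_length = 16L) {
  bc <- random_dna(n, barcode_length)
  repeat {
    bad <- dist3_offenders(bc)
    if (length(bad) == 0L) break
    bc[bad] <- random_dna(length(bad), barcode_length)
  }
  bc
}

#' Pipeline configuration
#'
#' Bundles the reference paths and per-stage parameters for
#' [run_pipeline()]. The single global `seed` fans out to per-stage streams
#' via [stage_seed()], so stages are individually reproducible.
#'
#' @param fasta,gtf,whitelist reference file paths.
#' @param out_dir output directory.
#' @param seed global RNG seed.
#' @param sim a `SimParams` for the simulation stage.
#' @param call a `CallParams` for the cell-calling stage; by default
#'   `expected_cells` is set to the simulated cell count.
#' @param seed_k k-mer/seed length for the index and aligner.
#' @param aligner named list of overrides for [align_reads()] tuning
#'   parameters (`n_seeds`, `min_votes`, `min_score`, `max_indel`,
#'   `max_candidates`).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(fasta, gtf, whitelist, out_dir, seed = 1L,
                            sim = sim_params(n_cells = 100L),
                            call = NULL, seed_k = 16L, aligner = list()) {
  if (is.null(call))
    call <- call_params(expected_cells = sim$n_cells,
                        ambient_rank_range = c(10000L, 100000L))
  structure(list(fasta = fasta, gtf = gtf, whitelist = whitelist,
                 out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 call = call, seed_k = as.integer(seed_k), aligner = aligner),
            class = "PipelineConfig")
}

# flat key=value provenance dump of a config
write_config <- function(config, path) {
  flat <- c(
    fasta = config$fasta, gtf = config$gtf, whitelist = config$whitelist,
    out_dir = config$out_dir, seed = config$seed, seed_k = config$seed_k,
    n_cells = config$sim$n_cells,
    genes_per_cell_gamma = paste(config$sim$genes_per_cell_gamma, collapse = ","),
    umis_per_gene_gamma = paste(config$sim$umis_per_gene_gamma, collapse = ","),
    reads_per_umi_gamma = paste(config$sim$reads_per_umi_gamma, collapse = ","),
    frag_dist_mean = config$sim$frag_dist_mean,
    frag_dist_sd = config$sim$frag_dist_sd,
    snp_rate = config$sim$snp_rate, indel_rate = config$sim$indel_rate,
    expected_cells = config$call$expected_cells,
    fdr_threshold = config$call$fdr_threshold
  )
  writeLines(paste0(names(flat), "=", unname(flat)), path)
  invisible(path)
}

#' Run the full simulate / count / call / evaluate pipeline
#'
#' Executes all stages against the referenced genome, annotation and
#' whitelist, writing FASTQ files, truth and quantified matrices, the cell
#' calls, evaluation metrics, a provenance copy of the configuration, and a
#' log with per-stage read accounting satisfying
#' `reads_in = barcode_rejected + unmapped + unassigned + assigned`.
#'
#' @param config a `PipelineConfig` from [pipeline_config()].
#' @return invisibly, a list with `stats` (read accounting), `metrics`
#'   (cell_recall, log2-cpm RMSE), `call` (the `CallResult`), `matrix`,
#'   `truth` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    message(msg)
  }
  run_stage <- function(name, expr) {
    say("stage ", name, " start")
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage ", name, " done")
    res
  }
  write_config(config, file.path(out_dir, "config.txt"))

  ref <- run_stage("reference", {
    genome <- load_fasta(config$fasta)
    catalogue <- load_gtf(config$gtf, genome)
    wl <- read_whitelist(config$whitelist)
    index <- build_kmer_index(genome, config$seed_k)
    list(genome = genome, catalogue = catalogue, wl = wl, index = index)
  })

  sim <- run_stage("simulate", {
    set.seed(stage_seed(config$seed, "simulate"))
    simulate_chromium(ref$genome, ref$catalogue, ref$wl$barcodes,
                      config$sim, out_dir)
  })

  quant <- run_stage("count", {
    set.seed(stage_seed(config$seed, "count"))
    r1 <- read_fastq(sim$paths$r1)
    r2 <- read_fastq(sim$paths$r2)
    args <- c(list(r1 = r1$seq, r2 = r2$seq, index = ref$index,
                   catalogue = ref$catalogue, whitelist = ref$wl,
                   barcode_length = config$sim$barcode_length,
                   umi_length = config$sim$umi_length),
              config$aligner)
    q <- do.call(quantify_reads, args)
    write_counts(q$matrix, file.path(out_dir, "raw"))
    q
  })
  st <- quant$stats
  say("accounting: reads_in=", st["reads_in"],
      " barcode_rejected=", st["barcode_rejected"],
      " unmapped=", st["unmapped"], " unassigned=", st["unassigned"],
      " assigned=", st["assigned"])
  if (st["reads_in"] != sum(st[c("barcode_rejected", "unmapped",
                                 "unassigned", "assigned")]))
    stop("read accounting identity violated")

  call <- run_stage("callcells", {
    set.seed(stage_seed(config$seed, "callcells"))
    cc <- call_cells(quant$matrix, config$call)
    write_cells(cc, out_dir)
    filtered <- quant$matrix[, intersect(colnames(quant$matrix),
                                         called_barcodes(cc)), drop = FALSE]
    write_counts(filtered, file.path(out_dir, "filtered"))
    cc
  })

  metrics <- run_stage("evaluate", {
    truth <- sim$sim$truth
    recall <- cell_recall(call, colnames(truth))
    rmse <- expression_rmse(quant$matrix, truth)
    m <- c(cell_recall = recall, log2cpm_rmse = rmse)
    utils::write.table(
      data.frame(metric = names(m), value = unname(m)),
      file.path(out_dir, "metrics.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    m
  })
  say("metrics: cell_recall=", format(metrics["cell_recall"], digits = 6),
      " log2cpm_rmse=", format(metrics["log2cpm_rmse"], digits = 6))

  invisible(list(stats = st, metrics = metrics, call = call,
                 matrix = quant$matrix, truth = sim$sim$truth,
                 out_dir = out_dir))
}
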