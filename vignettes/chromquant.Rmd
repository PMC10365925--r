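---
title: "chromquant: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromquant: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromquant quantifies 10x Chromium 3' gene-expression libraries: paired
FASTQ reads (R1 = cell barcode + UMI, R2 = cDNA) go in, a called genes x
cells matrix of deduplicated UMI counts comes out. The package also ships
the read simulator used to validate the pipeline and the accuracy metrics
used to score it. This vignette describes the methods, the tunable
parameters, and the design decisions taken where the published descriptions
of comparable pipelines leave the details open.

## Read alignment: sensitized seed-and-vote

R2 reads are mapped with a seed-and-vote scheme. Up to 15 seeds of length
`k = 16` are extracted at evenly spaced offsets `round(i (L - k)/(n - 1))`;
each seed is looked up in a hash index of all N-free genomic k-mers, on both
strands, and every occurrence is translated to an implied read-start
position. Implied starts within `max_indel = 16` bases of each other pool
into one candidate location whose vote count is the number of distinct
contributing seed offsets. Sensitivity is deliberately high: a single vote
suffices to nominate a candidate. This matters for 3'-biased single-cell
reads, where elevated error toward the read's 3' end can destroy most seeds
of a genuinely alignable read.

The best 8 candidates by votes are extended over the full read. Extension
places at most one indel, whose size and position are inferred from the two
best-supported implied starts within the candidate's cluster: the read is
split at the position that maximises matches with the prefix anchored at
one start and the suffix at the other, in both arm assignments. The
alignment score is `matched - mismatched` bases; bases extending past a
chromosome end are soft-clipped and count as neither. Among score ties, a
location overlapping a catalogued gene's exons wins; remaining ties go to
the smallest (chromosome, position), forward strand first. Reads scoring
below `min_score = 16` are unmapped. Only `n_seeds = 15` and the one-vote
threshold are fixed by the design; seed length, pooling window, extension
cap and score floor follow common seed-and-vote practice and are exposed as
arguments.

One indel per alignment is a deliberate simplification: the simulator
plants short (1-3 base), sparse indels, and a read carrying two indel
events can still map with mismatches. Splice-aware alignment is out of
scope; the simulator is unspliced by construction, and gene models are
collapsed to exon unions.

## From alignments to UMI counts

Cell barcodes are validated against a chemistry whitelist. An exact member
passes; otherwise a barcode with exactly one whitelist neighbour at Hamming
distance 1 is corrected to it. Zero or several distance-1 candidates reject
the read: with two equidistant candidates the evidence is ambiguous, and
dropping the read is the conservative choice.

Mapped reads are assigned to genes featureCounts-style against exon
unions: one overlapping gene assigns the read; several assign the gene with
the largest base overlap; an exact tie discards the read as ambiguous;
reads falling wholly outside exons (including introns) are unassigned.

Within each (gene, cell), reads sharing a UMI up to one mismatch are
collapsed: UMIs at Hamming distance <= 1 are joined single-linkage and the
deduplicated count is the number of connected components. Each component is
represented by its highest-read-count UMI (ties: lexicographically
smallest). If the same representative appears under several genes of one
cell, only the gene with the most supporting reads keeps it (ties: smallest
gene id). Collapsing happens within gene first and cross-gene resolution
second; resolution therefore compares component representatives, not raw
UMIs.

## Cell calling

Barcodes are partitioned by the two-stage procedure popularised by droplet
pipelines (CellRanger 3.0 / EmptyDrops):

1. **Bootstrap cutoff.** For each of 100 bootstrap resamples of the
   per-barcode totals, the 0.99 quantile of the top `expected_cells`
   totals is divided by 10; the threshold is the mean over resamples.
   Totals are sorted internally, so the threshold does not depend on
   barcode order. Barcodes at or above the threshold are high-confidence
   cells.
2. **Ambient profile.** Gene counts are pooled over barcodes ranked
   10,000-100,000 by descending total (clipped to the data), plus one
   pseudocount per gene, and normalised to proportions. The window is a
   package default — "very low total" is not standardised — and is
   configurable.
3. **Rescue.** Barcodes below the threshold with at least 10 total UMIs
   are tested against a multinomial with the ambient proportions and the
   barcode's own total. The test statistic is the multinomial
   log-likelihood; the Monte-Carlo p-value uses 10,000 simulated vectors
   per distinct total with the add-one correction `(r + 1)/(N + 1)`, which
   can never return zero. Benjamini-Hochberg across candidates at FDR 1%
   decides rescue.

The contract here is the three-stage structure, not numerical
bit-compatibility with any external implementation; quantile, divisor,
window, iteration count and FDR are all exposed in `call_params()`.
Note the interplay of the Monte-Carlo floor and BH: with `N` iterations
the smallest achievable p-value is `1/(N + 1)`, so a lone deviant barcode
among `m` candidates is only rescuable when `1/(N + 1) <= FDR / m`.

## The read simulator

The simulator draws per-cell expression structure from Gamma
distributions: genes per cell ~ Gamma(shape 4.5, scale 550), rounded,
clamped at 1 and capped at the catalogue size; UMIs per gene ~ Gamma(1, 6)
and reads per UMI ~ Gamma(2, 2), both rounded and clamped at 1. On genome-
scale annotation the genes-per-cell draw (mean 2,475) is effectively never
capped; on the desk-scale catalogues used in the tests every cell expresses
most of the catalogue, which concentrates per-gene counts but leaves the
UMI- and read-level structure untouched.

Fragments mimic the 3' bias of Chromium libraries: the distance between a
fragment's 3'-most base and the gene's 3' terminus is Normal(mean 350, SD
30), rounded, and resampled until the 90-base window fits inside the
gene's genomic (unspliced) span — a truncated normal in effect. Genes
shorter than a read cannot be simulated and must be excluded up front;
fixture genes are at least 600 bases so the window almost always fits.

Each UMI corresponds to one molecule: a single fragment is sampled per
UMI, genomic variants are planted once on that fragment, and every read of
the UMI is a copy differing only by sequencing errors. Variants are
substitutions at 9e-4 per base (to a uniformly chosen different base) and
indel initiations at 1e-4 per base (insertion or deletion with equal odds,
length uniform on 1-3). A deletion can shorten a fragment below the read
length; such reads are emitted slightly short rather than re-extended
beyond the sampled window.

Sequencing errors are driven by a per-cycle Phred profile: the base at
cycle i flips with probability `10^(-q_i/10)`. The default profile decays
linearly from Q37 to Q25, a parametric stand-in with the one property that
matters — non-increasing quality toward the 3' end, hence more errors
there. The same model is applied to the technical (R1, I1) and biological
(R2) segments. Setting the profile to `Inf` turns errors off exactly,
which the exact-recovery tests rely on. Segment lengths follow Chromium
Next GEM v3.1 conventions: 16-base barcodes, 12-base UMIs, 90-base cDNA
reads, one fixed 8-base sample index.

UMI sequences are drawn uniformly over the 4^12 space. Two UMIs of the
same cell and gene at Hamming distance <= 1 are treated as a collision and
resampled, not just identical pairs: under one-mismatch collapsing a
distance-1 planted pair is indistinguishable from a sequencing error, so
the planted count would otherwise be unrecoverable even by a perfect
quantifier. At 12-base UMIs this rejects roughly one draw per few hundred
cells and leaves the marginal UMI distribution essentially uniform.

What the generator does **not** emulate: spliced transcripts and junction
reads, doublets, ambient RNA contamination inside cell-containing
droplets, barcode-frequency biases, PCR amplification bias beyond the
reads-per-UMI distribution, and empirically shaped quality curves. Tests
passing on this generator therefore validate the pipeline's logic —
correction, collapse, resolution, calling — under a clean model of the
assay, not its robustness to every artefact of real libraries. Ambient-only
droplets for the cell-calling tests are added at the matrix level by the
test fixtures, as multinomial draws from a pooled expression profile.

## Evaluation metrics

Expression accuracy is log2-cpm RMSE against the planted truth:
`log2((count + 0.5) / libsize * 1e6)` per gene and cell, with the library
size the raw (offset-free) column total, and the RMSE taken jointly over
all matched gene x cell entries. Cells missing from an estimate are scored
as all-zero columns (library size 1 by convention, since 0/0 is undefined);
a flag excludes them instead. Mixture concordance compares pseudo-bulk
per-gene cpm of a sequenced A/B mixture against
`ratio * cpmA + (1 - ratio) * cpmB` on the log2 scale — sample-level, not
per-cell. Cell recall is the fraction of planted barcodes among called
(high-confidence plus rescued) barcodes.

## Numerical and scale choices

Coordinates are 1-based closed on the R surface (the IRanges convention)
and 0-based half-open inside the C++ core; GTF input is 1-based closed and
converted on load. Seed offsets round half away from zero in both
implementations so R and C++ agree exactly. Bootstrap quantiles use R's
default (type 7) definition. Pipeline stages derive their RNG streams from
one global seed keyed by stage name, so a stage can be reproduced without
re-running its predecessors, and a fixed seed reproduces FASTQ and matrix
files byte for byte.

The shipped tests run the complete pipeline at desk scale — fixtures of
15-50 genes on 20-80 kb genomes, 25-500 cells, up to ~620,000 reads, and
20,000 synthetic empty droplets for the calling tests. These sizes exercise
every code path (multi-mapping loci, barcode errors, UMI collisions,
ambient rescue) while keeping the suite fast; they are the package's chosen
study conditions, not limits of the implementation.

## Known limitations

BCL input is not supported (FASTQ only); alignments place at most one
indel; no spliced alignment or intronic counting modes; no barcode
frequency priors in correction (ambiguous barcodes are dropped rather than
probabilistically resolved); cell calling reproduces a published *design*,
not any specific tool's numeric output; and SAM/BAM export is not
provided — alignments pass to the quantifier in memory as data frames.
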