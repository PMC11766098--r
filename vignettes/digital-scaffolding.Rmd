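---
title: "Digital scaffolding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital scaffolding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiscaff)
```

## The problem

Long-read *de novo* assemblies of repeat-rich genomes (the motivating case
is an Oxford Nanopore assembly of the invasive pest fly *Drosophila
suzukii*) typically come out as large, redundant contig collections:
thousands of contigs, duplication ratios well above 1, and no placement
along chromosomes.  Digital scaffolding sidesteps consensus-based
scaffolders: it aligns a set of reference-derived probe sequences
("queries") against the contigs with BLAST, turns the filtered alignments
into an incidence grid, and reads contig order and redundancy directly off
that grid.  The end product of interest is a *minimal complete scaffold* —
a smallest ordered subset of contigs that covers a chromosome linearly —
plus a visual account of which genomic regions are repeat-rich and which
contigs are redundant.

The package is aimed at genome-assembly practitioners who have (i) a
chromosome- or scaffold-level reference for their species or a close
relative, (ii) a draft contig set, and (iii) BLAST+.  Everything else
(query construction, filtering, ordering, selection, coverage estimation,
plots, run statistics) is done here.

## Queries

Two probe strategies are supported.

* **Gene-queries** (`extract_gene_queries()`): annotated genes whose span
  is strictly greater than `min_gene_len = 2500` bases.  The strict
  inequality is deliberate — a gene of exactly 2500 bases is excluded.
  Shorter genes carry too little alignment signal relative to the
  successive coverage thresholds below.  Sequences are always taken from
  the forward strand regardless of the annotated strand: BLAST recovers
  minus-strand alignments anyway, and the procedure never assigns contig
  orientations, so strand bookkeeping at the query stage would add nothing.
  Only features of type `gene` are used from a GFF3 file.
* **Ranked-queries** (`extract_ranked_queries()`): fixed-length genomic
  fragments (`fragment_len = 4000`) cut at regular spacing.  Starts form
  an arithmetic progression with step `fragment_len + spacing`; the rank
  records the order along the chromosome.  Spacing trades resolution for
  run time: 5000 bases suits a single scaffold under close scrutiny,
  20 000 bases suits whole chromosomes.  A trailing fragment shorter than
  `fragment_len` is dropped by default so every query has the same
  coverage denominator; `keep_partial = TRUE` restores it for users who
  prefer edge coverage over uniformity.  Whether the original
  fragment-extraction tooling emits that partial fragment is not
  documented anywhere we could check, so the drop-partial default is this
  package's decision.

Query ids encode `seq_id`, rank and 0-based half-open coordinates
(`chr2R|r17|357000-361000`), so every downstream step — and any external
tool that only sees the FASTA — can recover the ordering from headers
alone.

## From alignments to the positive-cell matrix

`run_blast()` drives `makeblastdb`/`blastn` (task `blastn`, E-value
`1e-10` by default; the queries are multi-kilobase near-identical
sequences, so stringency costs nothing and removes noise).  The original
procedure does not document its BLAST parameters, so these defaults are
ours and are exposed as arguments.  `parse_tabular()` and
`write_tabular()` speak the standard 12-column tabular dialect; hits are
kept raw at this layer — no merging — so the evidence stays auditable.

`compute_query_coverage()` collapses all hits of one (query, contig) pair
into a single record: hit intervals on the query axis are unioned (an
overlap is never counted twice) and divided by the query length.  This is
the "unique query per subject" filtering that defuses repeat-induced
multiple alignments between the same pair.

`filter_by_thresholds()` applies successive coverage tiers, by default
`0.90, 0.80, 0.70, 0.50`.  A pair becomes a *positive cell* at the highest
tier its covered fraction meets; pairs below the lowest tier are dropped.
The original publication defers its exact threshold schedule to companion
work, so the schedule here is a concrete, auditable default and is fully
configurable — results on real data will depend on it.

`order_contigs()` sorts rows by (leftmost positive rank, then rightmost
rank descending, then contig id).  The first key is the obvious one; the
span tie-break puts the contig that reaches furthest right first, which
keeps the greedy selection's preferred candidates near the top of the
grid; the id tie-break makes the order total, hence the whole pipeline
deterministic — identical hit files yield byte-identical
`mapped_contigs.csv` output.

## Minimal complete scaffold

`select_minimal_scaffold()` is a greedy furthest-reach interval cover over
query ranks: from the current frontier, take the contig whose
positive-rank interval starts at or before `frontier + 1` and extends
furthest right.  For gapless instances this greedy rule is provably
optimal in cardinality (the classic interval-covering exchange argument);
the test suite checks it exhaustively against subset enumeration on
instances with up to 12 contigs.  When no contig continues the cover, a
gap is recorded and the cover restarts at the next covered rank — real
chromosome arms are rarely covered end to end, so gaps are data, not
errors.

Positive cells of selected contigs are classified **red**, all remaining
positive cells **blue**.  A contig's interval is taken as `min..max` of
its positive ranks, so under this definition a selected contig has no
cells outside its own interval and the red/blue split is exactly
selected-versus-rest.  Blue cells are the useful by-product: their density
measures assembly redundancy, and their clustering flags repeats.

`linear_coverage_pct()` converts the selection to a chromosome coverage
estimate: consecutive selected intervals that overlap *or abut* in rank
space merge into runs (an abutting contig is a valid continuation of the
cover, so treating adjacency as continuity is consistent with the
selection rule); each run spans from the start of its first query to the
end of its last query; the union of spans is divided by the **full
reference length**.  Using the full length (rather than the span of the
query set) means uncovered chromosome ends count against the estimate,
which is what a chromosome-level coverage claim should mean.  Since query
spacing is covered implicitly inside a run, the estimate is an upper
bound at the resolution of one spacing unit; with the default
fragment/spacing settings that granularity is well under a percentage
point of a chromosome arm.

`flag_repeat_regions()` counts, per query rank, the number of distinct
contigs with a positive cell, slides a `window` (default 5 ranks) over
these counts, and flags a rank when it carries at least one positive cell
and lies inside some window whose mean count reaches `min_contigs`
(default 4).  The requirement that a flagged rank itself be covered stops
a dense block from bleeding into empty flanking ranks; maximal flagged
runs are reported.  There is no published rule for this operation — the
parameters are tuning knobs, and the defaults mark a block only when
several consecutive queries each light up several contigs.

`plot_grid()` renders the grid with contigs on the Y axis, ranks on the X
axis, red/blue cell coloring and the coverage percentage in the title;
`red_only = TRUE` reproduces the minimal-scaffold-only view.

## Read splitting and the homopolymer census

`split_reads()` cuts each read into `floor(L/k)` non-overlapping k-mers
(`k = 250` by default — short-read length, which is the point: the output
feeds short-read polishing tools), slicing qualities in lockstep.  "Split
evenly" is read as equal-length pieces, so the trailing remainder is
dropped; `keep_remainder = TRUE` emits it as a final short record.  Base
conservation (`bases_out == n_kmers_out * k`) is asserted in tests.

`homopolymer_census()` reports, per base, the fraction of k-mers
containing at least `run_len = 10` consecutive copies of that base; each
k-mer counts at most once per base.  Homopolymer runs are the classic
nanopore error mode, and their relative weight inside a 250-mer is far
larger than inside a multi-kilobase read — the census quantifies how much
of the polishing input is exposed to that risk.

## Flow-cell run statistics

`read_run_table()` consumes a delimited run summary with explicit units
(bases as integers, file size in GB) rather than mixed human-readable
suffixes.  The package ships such a table for a published *D. suzukii*
sequencing experiment (one MinION R10 run, five Flongle R10 runs) in
`inst/extdata/flowcell_runs_gb.tsv`.

* `one_sample_t()` compares the repeated Flongle measurements with the
  single MinION value as reference: `t = (mean - ref) / (sd / sqrt(n))`,
  sample sd, two-sided p on `n - 1` df.  Read and base counts are
  `log2_values()`-transformed first because the two flow-cell formats
  differ by an order of magnitude.
* `paired_t()` is the one-sample test on paired differences, used when
  comparing two basecalling models on the same runs.
* `rm_anova()` implements the univariate two-way repeated-measures
  decomposition with subject error strata (`aov` with
  `Error(subject/(A*B))`): each effect is tested against its own
  subject-by-effect interaction.  Different popular front-ends disagree
  on this model's output depending on how they resolve the error strata;
  this package targets the explicit sums-of-squares definition and
  validates against an independent SS-partition oracle in the test suite,
  rather than against any one front-end's printout.
* `table1_summary()` derives the throughput comparisons: Flongle totals
  and their percentage of the MinION output, MinION shares of bases,
  reads and input DNA, mean Flongle input, per-pore output (default
  `flg_pores_total = 250`, i.e. about 50 starting pores per Flongle), and
  the contribution of the two top-performing Flongle runs.

On the shipped table these reproduce the published values: t = −353.583
on file sizes (sample mean 2.98 GB vs 198.7 GB), t = −16.996 on log2
bases (27.779 vs 33.949), t = −11.914 on log2 read counts, 7.68% of
MinION bases from the Flongle group, 88.3% MinION read share, 17.8%
MinION input share, 14.962 fmoles mean Flongle input, 4.07% from the top
two Flongle runs, 5.1 Mb per Flongle pore.  One caveat: the published
log2 read-count sample mean (16.18) is inconsistent with the published
run table itself (recomputing gives 16.63) while the published t
statistic matches the recomputation exactly; the package reports the
recomputed value.

## Synthetic data and what passing tests mean

`simulate_genome()`, `fragment_into_contigs()`, `simulate_annotation()`
and `simulate_reads()` generate the full input stack with known ground
truth: a background i.i.d. sequence with planted tandem or dispersed
repeat families, contigs tiling the reference with configurable overlap,
duplicates (optionally reverse-complemented), non-overlapping gene
annotations with a controlled short-gene fraction, and error-free reads.
All generators are pure functions of (parameters, seed).

Default test scale: a 200 kb chromosome, 12 contigs with 5 kb overlaps,
4 kb ranked-queries at 1 kb spacing (40 queries), 60–200 reads of
0.3–5 kb.  At this scale the full pipeline — including real `blastn`
calls — runs in seconds, and the suite completes in about a minute.  On
this clean data the pipeline recovers the true contig order exactly
(Spearman rank correlation 1.0) and estimates linear coverage within 0.5
percentage points of truth.

What the synthetic data does *not* emulate: sequencing errors and
basecalling artifacts (reads are exact substrings), assembly chimerism and
misjoins, heterozygosity, and biologically structured repeat families
(transposon superfamilies, satellite arrays with diverged copies).
Passing tests therefore demonstrate the correctness of the algorithms —
coverage arithmetic, tiering, ordering, cover optimality, conservation —
not the robustness of any particular threshold schedule on noisy real
assemblies.  In particular, published chromosome-level results obtained
with other threshold schedules on deposited assemblies are not expected
to be reproduced number-for-number by the defaults here.

## Numerical choices and degenerate inputs

* Ties in contig ordering and in greedy candidate choice are broken by
  span, then lexicographic id: total order, deterministic output.
* An empty hit set yields an empty matrix; an empty matrix yields an
  empty scaffold with 0% coverage, not an error.
* `one_sample_t()`/`paired_t()` refuse zero-variance input (the t
  statistic is undefined) rather than returning `Inf`.
* `rm_anova()` requires a complete balanced design and warns when an
  error stratum has zero variance.
* Coverage fractions are exact rationals evaluated in doubles; tier
  comparison uses `>=`, so a fraction exactly at a tier passes it.
* All file outputs are plain text (FASTA/FASTQ/GFF3/CSV/TSV) and
  round-trip through the package's own readers.

## Known limitations

* Contig orientation is never assigned — deliberately, as the grid
  carries no strand signal that survives the coverage union.
* No consensus, joining, patching or AGP output: the minimal scaffold is
  a *selection*, not a merged sequence.
* The greedy cover is optimal per gap-free segment; with gaps the
  selection is optimal within each covered segment but no claim is made
  across alternative gap placements.
* `oracle_align()` reports exact matches only; it is a cross-checking
  instrument for synthetic data, not a sensitive aligner.
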