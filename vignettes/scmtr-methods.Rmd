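---
title: "Models and methods behind scmtr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmtr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scmtr` is a simulation and processing toolkit for multi-target single-cell
CUT&Tag with a joint transcriptome readout (scMTR-seq). In this assay,
several antibody–Tn5 complexes — each carrying a 5-nt antibody index —
tagment chromatin in situ at the sites of different histone modifications,
an indexed poly-T primer reverse-transcribes RNA in the same nuclei, and
three rounds of split-pool ligation give every cell a combinatorial barcode
without physical isolation. The result is one sequencing library in which
every read carries: which cell it came from (BC1:BC2:BC3), which modality
(antibody index for DNA, RT index for RNA), which molecule (UMI, for RNA),
and the genomic sequence itself.

This vignette explains the models the package implements, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The barcode model

A `barcode_design` holds three round whitelists (default 48 barcodes of
8 nt each), the antibody-index table (five histone-mark targets plus IgG,
5 nt), the RT-index table, and the fixed Read2 layout: BC3 at bases 1–8,
BC2 at 39–46, BC1 at 77–84, the antibody/RT index at 115–119 and the UMI at
120–127, with fixed 30-nt ligation linkers in the gaps. Linker sequences
are arbitrary and never matched.

Two quantities follow analytically:

* **Capacity.** `barcode_combinations()` is the product of round sizes:
  $48^3 = 110{,}592$ cell-identifying combinations. The antibody index is
  excluded by default because every cell carries *all* antibody indexes —
  the index identifies modality/target, not the cell. When multiple RT
  indexes split cells into sublibraries, `include_rt = TRUE` multiplies
  them in.
* **Collision rate.** With $n$ cells drawing uniformly from $B$
  combinations, `collision_rate()` offers the linear occupancy estimate
  $n/B$ (the convention behind the familiar "1% at ~1,100 cells, 10% at
  ~11,000 cells" guidance for this capacity) and the birthday-process
  per-cell probability $1-(1-1/B)^{n-1}$. The linear form is the default
  because it reproduces those printed guidance figures exactly after
  rounding; the birthday form is exact for the per-cell collision
  probability and always lies at or below it. A Monte-Carlo simulation in
  the test suite confirms the birthday value.

**Whitelist distances.** One-mismatch correction is unambiguous only when
whitelist minimum pairwise Hamming distance is ≥ 3. The shipped round
whitelists are drawn from random linear [8,3] codes over GF(4) with minimum
distance 5, and the 5-nt indexes from an extended Reed–Solomon MDS code
over GF(4) with distance 4 — so that *two* sequencing errors can never be
"corrected" into a different barcode. With distance exactly 3 that failure
mode is possible and measurable at realistic error rates, which is why the
shipped sets exceed the minimum requirement.
`min_pairwise_distance()` lets users audit their own whitelists before
enabling `max_mismatch = 1`.

## The synthetic experiment

A `scenario()` describes the experiment the simulator generates:

* **Genome**: uniform random sequence (default 1 Mb over two contigs).
  Random 50-mers in a megabase genome are essentially unique, which is what
  lets a desk-scale exact aligner stand in for a production aligner.
* **Cell types**: labels with mixing proportions (default two types,
  50/50). Types differ in which peaks are active and in gene expression.
* **Peaks**: per (target, type), `n_peaks` fixed-width intervals on a
  non-overlapping slot grid; a `peak_shared_frac` of them (default 0.5) is
  shared between types, the rest are type-specific. The IgG-like target has
  no peaks — it is background only.
* **DNA molecules**: per cell and target, negative-binomial counts
  (defaults: mean 1300, size 5 per active mark; mean 200 for IgG — per-mark
  depths in the range reported for multi-target CUT&Tag assays, and chosen
  so per-cell totals genuinely straddle the standard DNA > 2500 filter).
  Each molecule falls inside a peak of its cell's type with probability
  `frip` (default 0.8), fully contained in the peak, or uniformly in the
  background *outside* that target's peaks (rejection sampling). Fragment
  lengths are uniform on 150–500 bp. Within one cell and target, molecules
  occupy distinct read start positions — distinct Tn5 insertion events —
  so position-only deduplication recovers molecule counts exactly and PCR
  duplication is the only source of duplicates.
* **RNA molecules**: negative-binomial UMI counts per cell (default mean
  2400, size 5); the gene is drawn from type-specific expression rates
  (normalized Gamma(0.5) draws per type), the position uniformly inside the
  gene, the UMI uniformly from the $4^8$ space.
* **Duplication**: each molecule is emitted $1 + \mathrm{Poisson}(f-1)$
  times (default factor $f = 2$, i.e. an expected duplication rate of 0.5).
* **Barcode errors**: independent per-base substitutions on Read2 at
  `barcode_error_rate`; the exact-match valid fraction then follows
  $((1-\varepsilon)^8)^3 (1-\varepsilon)^5$.
* **Collisions**: cells receive *distinct* combinations by default;
  `inject_collisions()` (or `collision_rate` in the scenario) reassigns a
  fraction of cells another cell's combination, flagging both members, for
  end-to-end collision studies.

Everything is seeded; an identical seed yields byte-identical FASTQ and
truth tables. The truth tables record, per read, the cell, modality,
target, UMI, origin interval and in-peak flag, and per cell both molecule
counts and the unique counts the deduplication rules can recover.

**What the generator does not emulate**: sequencing quality scores and
quality-dependent errors, indels, chimeric reads, splicing and transcript
structure, copy-number and accessibility biases, doublets other than
barcode collisions, and ambient contamination. Gene positions and
expression rates are also drawn independently of the peak sets, so
cross-modality associations (e.g. Cramér's V between a mark and
expression) are near zero by construction on synthetic data — the
association statistics are validated against exact contingency-table
oracles, not against a biological coupling the generator does not model. Passing tests therefore
demonstrate the correctness of the decoding/quantification machinery under
the stated generative model, not robustness to every artefact of real
libraries.

## Demultiplexing

`demux_reads()` mirrors the fixed-position extraction used for this assay:
substrings at the printed coordinates, then per-segment whitelist matching.
The default is exact matching (the equivalent of unique forward-strand
zero-mismatch alignment of the concatenated combination); `max_mismatch =
1` corrects a cell-barcode segment only when exactly one whitelist entry
lies within Hamming distance 1 — zero or two candidates fail, the latter as
`ambiguous`. The antibody/RT index is matched exactly by default even when
barcode correction is on (`id_max_mismatch = 0`): a wrongly corrected index
silently moves a read to another target or modality, and ten codewords in a
5-nt space can reach pairwise distance at most 4, so a three-error index
can land within the correction radius of a different codeword — whereas the
distance-5 8-mer whitelists make the analogous cell-barcode event require
four errors in one segment. Failures are reported per segment with a fixed precedence in
read order (BC3 → BC2 → BC1 → ID) so statistics are reproducible; UMIs are
never corrected ('N's are kept verbatim). Modality is resolved per read by
which ID table matched, which is well-defined because the antibody and RT
index sets are disjoint by construction. Conservation (valid + failure
classes = input reads) is asserted in the pipeline.

## Alignment at desk scale

`align_exact()` indexes every substring of the read length in the genome
(both strands) and reports reads with exactly one occurrence at mapq 60;
multi-hits and misses are dropped and counted. Only exact full-length
matches are searched — the simulator places errors on the barcode read, not
the genomic read, so a mismatch-tolerant search would never fire here.
`read_alignments()` ingests externally produced minimal SAM, applying the
assay's modality-specific strict filters (mapq > 10 for DNA, > 50 for RNA)
and, for paired input, the proper-pair FR-orientation filter, merging mates
into one fragment-spanning record. Coordinates are 0-based half-open
internally and in all BED-like outputs; SAM positions are converted on
input. No Tn5 +4/−5 shift is applied anywhere — none is defined for this
data model — and fragment ends for paired data are simply (min start, max
end) of the mates.

## Deduplication and quantification

The two modalities deduplicate differently, which is the central
bookkeeping rule of the pipeline:

* **DNA**: duplicates share a mapping position within one cell and target;
  the UMI is ignored. One fragment per distinct (cell, target, contig,
  start, end), with multiplicity.
* **RNA**: duplicates share mapping position *and* UMI within a cell; the
  position anchor is the strand-aware 5' base (the standard UMI anchor; the
  choice is a package decision, as no finer definition is fixed by the
  processing convention).

Both rules are set-theoretic and idempotent, and conservation
(Σ multiplicities = input reads) is asserted. RNA molecules are assigned to
the unique gene containing their 5' position; molecules hitting zero or
two-plus genes are dropped and counted (unique-overlap-else-drop — the
upstream convention's internals are not published, so the simplest
well-defined rule is used). Fragment files follow the five-column dialect
(contig, start, end, barcode, duplicate count), one file per target. The
genome-wide bin matrix (default 5 kb) increments every bin a fragment
overlaps — interval-overlap semantics, not midpoint assignment, matching
how downstream interval tools count.

## Quality control and association statistics

* **FRiP** is computed per (cell, target) against merged peaks with ≥ 1 bp
  overlap; cells without fragments are missing, not zero.
* **Cell filtering** uses the assay's strict thresholds: total unique DNA
  reads (all targets, IgG included — matching the single per-cell DNA
  number the filters are quoted against) > 2500 and unique RNA molecules >
  2000; recovery is the passing fraction of loaded cells.
* **Cramér's V** between two modalities binarizes both matrices at
  count > 0, forms the 2×2 contingency table over all (cell, feature)
  entries and returns $\sqrt{\chi^2/N}$ with Pearson's statistic, no
  continuity correction (for 2×2 this equals |φ|). The default feature unit
  is gene-level activity (fragments over gene bodies vs UMI counts per
  gene), binarized at > 0 — the feature unit is configurable since no
  single convention is fixed for it.
* **kNN label agreement** (default k = 50) measures how well a feature
  space separates RNA-defined lineages: the mean fraction of each cell's k
  Euclidean nearest neighbours (self excluded, ties broken by cell index
  for determinism) sharing its label.

## Aggregation

`pseudobulk()` sums fragment–bin overlaps per (group, target) at 50-bp
resolution, optionally CPM-scaled. Effective-genome-size (RPGC-style)
scaling is deliberately replaced by CPM: genome-wide binned correlations
are invariant to global scale, so cross-dataset comparisons are unaffected
while the dependency on an effective genome size disappears.
`igg_normalize()` forms per-bin linear ratios (signal + 1)/(control + 1)
against the IgG track. `track_correlation()` re-bins to 5 kb by summation
and reports genome-wide Pearson r. `saturation_curve()` subsamples cells
without replacement to show how aggregate–reference correlation grows with
cell number. `median_normalize()` rescales each cell to the per-target
median depth prior to dimensional reduction.

**Poisson binarization** (200-bp bins, p = 5e-7) marks a bin when its
count reaches the smallest $t$ with $P(\mathrm{Poisson}(\lambda) \ge t)
\le p$. Without a control, $\lambda$ is the genome-wide mean per bin; with
an IgG control, the local expectation is the depth-matched control floored
at the genome-wide mean. The floor mirrors the documented behaviour of the
standard binarization tool when controls are sparse; since only the flag,
not the internal rule, is public, this mapping is stated explicitly as the
package's interpretation and the floor can be disabled.

## Numerical and design choices

* Coordinates: 0-based half-open everywhere internally and in BED/fragment
  outputs; printed Read2 coordinates and SAM input are 1-based inclusive
  and converted at the boundary.
* Thresholds are strict (`>`), matching the quoted filters; a cell at
  exactly 2500 DNA reads fails.
* All randomness flows from a single integer seed, split per stage with a
  fixed multiplier below $2^{31}$; reports and artifacts contain no
  timestamps, so equal seeds give byte-identical outputs.
* Degenerate inputs are defined, not silently absorbed: empty fragment
  sets give empty-but-correctly-shaped matrices, FRiP for fragment-less
  cells is missing, Cramér's V with a constant margin is 0 with a warning,
  pseudocount 0 with a zero control bin is an error.
* Problem sizes in the tests: unit tests run 10–120-cell scenarios on
  60–80 kb genomes; the end-to-end acceptance check runs the default
  scenario (500 cells, 1 Mb genome, ~5M reads), the scale at which the
  per-cell filters and 3-standard-error comparisons are meaningful.

## Known limitations

The toy aligner requires fixed-length, error-free reads and is quadratic
in genome size in memory if abused; it is a stand-in for desk-scale
verification, not a general aligner. UMI collapsing is exact-match only
(no directional graph). Peak calling, chromatin-state model training,
LSI/UMAP embeddings and metacell/pseudotime analyses are out of scope:
peaks and annotations are inputs, and the bin matrices, fragment files and
MTX outputs are formatted to feed the standard downstream tools.
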