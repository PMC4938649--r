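---
title: "Models and methods: breakpoints and crossovers on balancer chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: breakpoints and crossovers on balancer chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balancerseq)
```

# The problem

Balancer chromosomes carry several nested or overlapping inversions that
suppress the recovery of meiotic crossover products, which is what makes
them indispensable for maintaining deleterious alleles in *Drosophila*
stocks. Their own structure, however, is usually known only to cytological
resolution. Sequencing a balancer/reference-strain heterozygote makes two
analyses possible:

1. **Breakpoint mapping.** Read pairs that straddle an inversion junction
   become orientation- or insert-size-discordant on the reference, and
   reads that cross the junction align in two soft-clipped pieces (split
   reads). Clustering this evidence localises each junction; the soft-clip
   positions give base-pair resolution.
2. **Crossover archaeology.** Because the heterozygote's second haplotype
   is the reference strain itself, every heterozygous SNP can be assigned
   to the balancer. Comparing the SNP complements of many stocks carrying
   the "same" balancer reveals single crossovers (SCOs) in the poorly
   balanced region distal to the distal-most breakpoint, and rare double
   crossovers (DCOs) inside inverted segments, as tracts of rare SNPs.

This package implements both analyses plus a deterministic simulator that
generates every input (reference, karyotype, stock panel, aligned reads,
VCFs, masks, gene models) with truth records, so the whole pipeline can be
validated end to end.

# The rearrangement model

## Junction delta

A cut is described on the reference by the last retained base on its 5'
side, $f$, and the first retained base on its 3' side, $t$ (both 1-based).
The signed length change at the junction is

$$
\Delta(f, t) \;=\;
\begin{cases}
-(t - f - 1) & t > f \quad \text{(deletion of the skipped bases)}\\
\;\;\,f - t + 1 & t \le f \quad \text{(duplication of the overlap)}
\end{cases}
$$

so adjacent coordinates give $\Delta = 0$ (clean join). Duplicated bases
appear once on each side of the junction in the derived sequence; deleted
bases appear nowhere. The published breakpoint tables for TM3/TM6/TM6B
never state this rule explicitly, but `junction_delta()` reproduces every
printed row, and the test suite validates the rule against an independent
base-counting oracle (join a prefix to a suffix of a toy string and
measure the length change).

## Segment maps

A `balancer_map` is an ordered list of oriented reference intervals that
tile the derived chromosome. Rearrangements are applied *sequentially*,
each expressed in the current derived frame, matching how balancer
histories were actually built (an inversion superimposed on an already
inverted chromosome). A 2-cut event inverts the interval between its cuts.
A 3-cut event inverts **both** internal segments in place
(A&nbsp;B'&nbsp;C'&nbsp;D): this is the only three-cut assembly that
creates three novel junctions and leaves both internal segments inverted,
the configuration reported for the three-breakpoint rearrangements on TM6
and TM6B. Liftover in both directions (`lift_to_reference()`,
`lift_to_derived()`) is exact: a bijection away from duplicated bases,
with deleted bases unreachable.

`span_mb()` rounds half-up, the convention used when quoting segment and
tract sizes to one decimal (e.g. 9,216,999–10,625,261 → 1.4 Mb).

# Breakpoint calling

* **Classification.** A pair is *split* when a read has a supplementary
  alignment and its primary carries a soft-clip of at least `min_clip`
  (default 20 bp; the clip length equals the smaller aligned piece, so
  this suppresses micro-clips). Otherwise a pair is *discordant* when mate
  orientation deviates from the library expectation (FR by default) or
  the inferred insert falls outside the bounds; otherwise concordant.
  Insert bounds default to mean ± 3 SD of the orientation-concordant
  pairs, estimated per library; no published cutoff exists for this step,
  so an empirical rule is used.
* **Window rule.** Events (one per anchored side of each split/discordant
  pair, anchored at the leftmost aligned base — a choice made so counts
  are brute-force checkable) are tallied in fixed 1-kb windows tiled from
  position 1. A window is a candidate iff it holds *strictly more than*
  10 events. Both the window size and threshold are parameters.
* **Regions and refinement.** Adjacent candidate windows (bridging up to
  `max_gap = 2` empty windows) merge into a region, so the two clip
  clusters of a junction with a kilobase-scale deletion stay together.
  Within a region, the modal reference-high clip position is $f$ and the
  modal reference-low clip position is $t$; $\Delta$ follows from the
  junction rule. Consensus ties break toward the smaller coordinate,
  deterministically, and are flagged with the competing mode. With no
  usable split reads the call degrades to window resolution (region
  midpoint, no delta). Junction-sequence evidence is taken from soft-clip
  consensus rather than local de-novo assembly; the information content is
  the same and no assembler is required.
* **Linking.** Two regions are linked when ≥ `min_link` discordant pairs
  have one mate anchored in each, stratified by the mate strand pattern —
  an inversion therefore shows two links (its +/+ and −/− pair
  populations), a three-cut event three.
* **Masking and priors.** Events anchored in a repeat/low-complexity mask
  are removed before scanning. An optional prior-regions BED restricts
  scanning to intervals where rearrangements are expected; without it the
  whole chromosome is scanned. Libraries are pooled for the window rule
  (with support reported), since the published description does not state
  a per-library threshold.

# Crossover analysis

* **Panel filters.** Heterozygous SNVs with QUAL ≥ 200 enter the panel
  (records with QUAL < 200 are filtered out; a record at exactly 200 is
  kept); indels are never considered. "Same polymorphism" means same
  (chrom, position, alternate allele); genotype phase is ignored because
  every call is heterozygous balancer/reference by construction.
* **Sharing and windows.** Each SNP's sharing count $k$ is the number of
  stocks carrying it ($k = 1$ is a unique polymorphism). The heatmap
  matrix counts, per stock, SNPs with $k \le$ `max_share` in fixed 10-kb
  windows tiled from position 1. `max_share = 5` matches the 18-stock
  panel rule; for a 3-stock panel the any-SNP-not-shared-by-all rule is
  `max_share = n - 1`. Choose `max_share` well below the smallest
  baseline sharing count your panel can produce (baseline minus a margin
  of at least two), otherwise sporadic per-stock call dropout can mimic
  rarity.
* **Tract calling.** The published analysis reads tracts off the heatmap
  visually; the calling rule here is this package's formalisation and is
  recorded in the output attributes: per stock, maximal runs of windows
  with ≥ 1 rare SNP, bridging up to `max_gap = 2` empty windows, with at
  least `min_windows = 3` signal windows. Boundaries are refined to the
  outermost rare SNPs; each boundary's confidence interval extends to the
  nearest flanking shared-by-all SNP present in that stock (or the
  chromosome end) — the true exchange point must lie in that interval.
  Tracts wholly distal to the distal-most breakpoint (or reaching a
  chromosome end outside the breakpoint span) are SCO; tracts strictly
  between two consecutive breakpoints are DCO; anything else — or
  everything, when no breakpoints are supplied — is unclassified. Exact
  coordinates are the primary output; rounded-Mb columns are display-only
  because the published tract bounds appear rounded with an unstated rule.
* **Relatedness.** Overlapping tracts from different stocks are compared
  by reciprocal overlap and by Jaccard identity of rare SNPs in the
  overlap; pairs exceeding both thresholds are flagged as likely common
  origin — the signature of stocks that inherited one historical exchange.

# The synthetic-data generator

The generator emulates the study design the analyses were built for:

* a uniform-composition random reference (any length ≥ 1 kb);
* a balancer derived by sequentially superimposed inversions, including a
  3-cut event, each junction carrying a configurable deletion or
  duplication (the default karyotype includes a −1090 bp junction, the
  size observed at the distal-most TM3 cut, plus −5/+3/−28 at the 3-cut
  event);
* balancer-lineage SNPs at 6.2 per kb by default — the density implied by
  ~43,000 informative SNPs over a 6.9-Mb distal interval;
* a stock panel in which stocks receive SCOs at uniform positions distal
  to the distal-most breakpoint (optionally excluded from a zone next to
  the breakpoint; 2 Mb mimics the observed buffer) and/or DCOs inside
  inverted segments, each replacing balancer SNPs with an independent (or
  deliberately shared) donor haplotype at the same density;
* 150-bp paired-end reads from Gaussian ~600-bp fragments and a
  large-insert mate-pair library uniform on 2–12 kb, *pre-aligned
  analytically* through the segment map: reads inside one segment become
  plain records, junction-crossing reads become primary + supplementary
  soft-clipped records, straddling pairs become discordant. Emitting
  aligned records (SAM text) rather than FASTQ removes the aligner
  dependency while preserving exactly the evidence the caller consumes;
  mate-pair orientation is a library parameter because processed
  large-insert libraries differ in convention;
* per-stock heterozygous VCFs with QUAL drawn from a log-normal model.
  The default (meanlog log 700, sdlog 0.45) describes deep-coverage
  heterozygous SNV calls: almost all records far above the 200 threshold
  with a ~0.3% low tail, so the filter boundary is exercised without
  making call dropout a dominant noise source. Indel records are
  interleaved at a configurable fraction purely to exercise the
  drop-indels filter.

Determinism is a contract: the same configuration and seed give
byte-identical FASTA/SAM/VCF/BED/GFF3/truth outputs (tested).

**What it does not emulate** — and therefore what passing tests do *not*
show about real data: mapping ambiguity in repeats (the mask is an input,
not an emergent property), indel sequencing errors, coverage
non-uniformity, PCR chimeras and duplicates, quality-score structure, and
centromeric heterochromatin. Real-data performance hinges on those, which
is why the published recovery rates (8/10, 6/8, 9/11 breakpoints) are not
reproducible at the desk and are not claimed here.

# Numerical choices and problem sizes

* Coordinates are 1-based inclusive throughout; BED interchange converts
  to 0-based half-open only at the I/O boundary.
* Ties (clip consensus, equal-position mates) break toward the smaller
  coordinate.
* Rounding of Mb spans is half-up, not banker's.
* The test and validation runs use a 5-Mb chromosome at 30× combined
  PE+MP coverage for breakpoint recovery, and a 2-Mb chromosome with an
  18-stock panel at 6 SNPs/kb for tract recovery — scales at which every
  junction collects tens of split reads and every tract hundreds of rare
  SNPs, the same signal regime as the real study's deep-coverage data.
* Degenerate inputs: zero drawn fragments yield an empty record stream
  (with a message); an all-filtered panel yields a valid empty matrix
  (with a warning); tract calling with no breakpoints yields unclassified
  tracts; refinement without split reads yields window-level calls.

# Known limitations

* The caller targets inversion-style junctions; it is not a general SV
  caller (deletions/duplications/translocations as primary targets are
  out of scope), and inter-chromosomal pairs are only set aside.
* Breakpoints inside masked or repeat-rich sequence are invisible by
  construction, as in the real analysis.
* The tract-calling rule is a formalisation of a visual procedure; its
  parameters (`min_windows`, `max_gap`, `max_share`) trade sensitivity to
  short tracts against robustness to sporadic call dropout and should be
  set with the panel's baseline sharing structure in mind.
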