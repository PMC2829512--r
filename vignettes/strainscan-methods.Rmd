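---
title: "Methods: comparing an evolved strain against its ancestor from short single-end reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing an evolved strain against its ancestor from short single-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A clone isolated from a laboratory evolution experiment differs from its
founding ancestor by a handful of point mutations and, often, by structural
rearrangements such as segmental amplifications. With short (36 bp)
single-end resequencing of both strains, three questions can be answered at
increasing resolution:

1. **Which bases changed?** Compare per-position base calls between the two
   strains.
2. **Which regions changed copy number, and by how much?** Compare read
   depth along the genome between the two strains.
3. **What is the base-resolution structure of a rearrangement?** Reads that
   span a novel junction fail to map to the reference; assembled into
   contigs, they reveal the junction sequence itself.

`strainscan` implements all three analyses plus a synthetic-data generator
that emulates the hallmark case: a five-copy *tandem-inverted* amplification
of an ~11 kb segment whose junctions are mediated by short (7 and 13 nt)
inverted repeats, alongside four isolated SNPs, sequenced at 35× (evolved)
and 28× (parent).

# Read placement and the mappable genome

The internal mapper places each read at its best ungapped location on either
strand with at most `max_mismatches` (default 2) substitutions. The search
is exhaustive: an exact pass resolves error-free reads, and
`max_mismatches + 1` trusted-band passes guarantee by pigeonhole that every
qualifying placement is found. A read with two or more equally good
placements is kept but classed `multi-zero` and excluded from all depth and
pileup computations — the analogue of discarding low mapping-quality
records; real data can be ingested from SAM, where records with mapping
quality below 10 are demoted to the same class. Ungapped placement with a
2-mismatch budget is sufficient for 36 bp reads from a haploid genome; it is
not meant for longer or indel-rich reads, which should arrive pre-aligned
via SAM.

All positional statistics are restricted to the *mappable genome*: position
$p$ is mappable iff the read-length window starting at $p$ occurs exactly
once in the genome counting both strands. The window is anchored at the
position (not centred) to match read-placement semantics; the last
`read_len − 1` positions of each chromosome are unmappable by convention.

# SNP calling

A position is called as a SNP iff it is mappable and

* the evolved pileup has depth ≥ 6 with a single base accounting for ≥ 80%
  of calls, and
* the parental pileup has depth ≥ 5 with a **different** base accounting
  for ≥ 70% of its calls.

All four thresholds are inclusive and configurable via `snp_thresholds()`.
The heuristic is purely count-based — base qualities are ignored — which is
why the simulator emits constant-quality reads. At 35×/28× with a 0.5%
error rate, a false call requires ≥ 80% concordant *identical* errors at
≥ 6× depth, with probability far below one event per genome
(< 10⁻¹⁰ per site), so an empty result on an unmutated genome is the
expected behaviour, not luck. `callable_fraction()` reports the fraction of
mappable positions at which both depth gates pass.

Small indels are screened by split-aligning unmapped reads as two ungapped,
ordered, same-strand pieces (a reference gap is a deletion, a read gap an
insertion). A candidate needs at least `min_support = 2` reads ("multiple"
read at its smallest), no wild-type-spanning reads in its own strain, and
wild-type-spanning reads in the comparison strain.

# Copy number: binned depth ratios and circular binary segmentation

Per-base depth from unique placements is averaged over the mappable
positions of 25 bp bins (anchored at position 1; a final partial bin is
kept only if at least half its width is mappable). Each strain's bin means
are normalised by that strain's total nuclear bases, and the per-bin log2
ratio evolved/parent is taken. Bins with no mappable position or zero
parental coverage are excluded rather than pseudo-counted: fabricating a
ratio where one strain has no data would bias segmentation.

**Recentring.** The usable-bin log2 ratios are recentred on their
genome-wide median. On a real ~12 Mb genome an 11 kb amplification
inflates the evolved total by < 0.5% and this correction is negligible; on
a 200 kb toy genome the same amplification inflates the total by ~22%,
which would shift every ratio by −0.29 and depress the copy-ratio estimate
to ~4.1. Median-centring restores the neutral state to 0 at any scale. It
assumes the neutral state is the majority state (amplified bins are a
minority of the genome); a genome in which most bins changed copy number
would defeat it, as it would any total-count normalisation.

Segmentation is a from-scratch circular binary segmentation: treat the
chromosome's usable bins as a circle, find the arc maximising the
two-sample t-statistic (pooled variance) between arc and complement, and
accept the split if the observed statistic is extreme at `alpha = 0.01`
under a permutation null (`n_permutations = 1000`, seeded, computed by a
deterministic internal RNG so R's global RNG is untouched). Accepted splits
recurse into the resulting parts. Every circular arc or its complement is
contiguous, so scanning contiguous arcs covers the circle; ties go to the
lexicographically smallest (start, end), which means a two-level series may
report either the elevated arc or its complement — the implied change-points
are identical. The permutation loop stops early only when the exceedance
count already forces p > alpha; significance is never declared from a
truncated null. The scan itself exploits the identity
$SSW = V - a^2\,n/(m(n-m))$ (with $a$ the centred arc sum and $V$ the total
sum of squares, which permutation leaves unchanged), so each arc width
requires only the extreme centred arc sums — the same statistic evaluated
exactly, at a cost that keeps 1000 permutations on an 8000-bin chromosome
around two minutes.

Smoothing follows segmentation: adjacent segments whose means differ by
less than 3 chromosome-wide *residual* standard deviations (the SD of bin
ratios about their segment means — the published rule does not specify the
SD's population, so the residual reading is used and exposed as
`sd_multiplier`) are merged until stable, and segments spanning under
1000 bp are absorbed into the more similar neighbour. A segment's copy
ratio is $2^{\bar{r}}$ of its mean log2 ratio, reported with the nearest
integer and the distance to it; boundary uncertainty is ± one bin width
(±25 bp at the default), the bin-width reading of the published
uncertainty.

# Breakpoints from unmapped reads

Reads spanning a novel junction are unmapped almost surely (an 18/18 bp
split read faces ~25% mismatch over half its length). They are assembled
with a deliberately small de Bruijn assembler: canonical k-mers (odd
`k = 21`) from both strands, singleton k-mers dropped (`min_kmer_count = 2`
suppresses isolated sequencing errors), and maximal unitigs emitted. At a
branch the walk continues only through a candidate whose k-mer count is at
least 4× every alternative; this resolves the branches created when two
reads happen to share the same error (expected about once per junction at
the scenario's pooled junction coverage) without any wider graph
simplification — bubbles, tips and repeat resolution are out of scope.

Contigs are aligned back to the reference as maximal ungapped local
alignments (exact 12-mer seeds, best run per diagonal, ≥ 90% identity) and
filtered by three rules: a contig explained end-to-end by a single
reference region is discarded; both end-anchoring alignments must land in
mappable positions; the retained alignments must cover ≥ 90% of the contig.
A surviving two-part contig is classified by `classify_breakpoint()`:
opposite strands ⇒ *inverted*; the micro-homology overlap is
`len(A) + len(B) − contig length`, computed from the contig intervals and
never from reference coordinates (whether published reference intervals are
closed at both ends is ambiguous; contig-interval arithmetic is not). The
micro-homologous bases genuinely belong to both pieces — that ambiguity is
the signature being measured.

The background statistic asks how likely such contigs are absent a true
rearrangement: with `n` breakpoint-like contigs recovered from the
*ancestor* data over `N` mappable nuclear bases, the probability of finding
them inside `k` windows of `w` bp around predicted boundaries is
$(nw/N)^k$, capped at 1. With the published counts (2 contigs,
N ≈ 1.132 × 10⁷, two 50 bp windows) this evaluates to ≈ 7.8 × 10⁻¹¹. The
estimate is restricted to nuclear chromosomes; mitochondrial-aligned
contigs are reported but excluded.

`infer_structure()` labels the amplification `tandem_inverted` only when
both boundary calls are inverted-class, both fall within the segment
boundaries ± uncertainty, and wild-type-spanning reads support both
boundaries — an odd-copy tandem-inverted array retains wild-type sequence
at its outer flanks, so this support is a structural prediction, not a
contradiction. Anything less is `unresolved` with the evidence attached.

# The synthetic scenario: what it emulates and what it does not

`build_demo()` generates a 200 kb single-chromosome haploid reference
(i.i.d. bases at GC 0.38), plants four transversion SNPs, and replaces an
11,038 bp segment with a five-copy alternating-orientation array. Inverted
junctions form through planted inverted-repeat arms: the proximal arm is
the terminal `h` bases of the segment and its reverse complement sits
`spacer` bases outside the boundary, so the evolved sequence runs through
the proximal arm and continues leftward from just before the distal arm.
Only the inverted alignment piece then extends through the arm, giving a
contig-interval overlap of exactly `h` — the published junction geometry.
With a spacer of zero the arms fuse into a centred palindrome and *both*
pieces extend, doubling the apparent overlap, which is why the generator
requires `spacer ≥ 1`. Defaults are `h = 7/13` with spacers 10/12 nt:
small enough that the 3× "shoulder" the inverted copies carry over the
spacer bases stays within a single 25 bp bin. At most four flank bases are
rewritten to stop the micro-homology extending by chance.

Reads are drawn uniformly from both strands at 35× (evolved) and 28×
(parent) with independent 0.5% base substitutions and constant qualities.
The generator emulates read geometry, depth asymmetry, uniform coverage and
substitution errors. It does **not** emulate GC-dependent coverage bias,
indel errors, quality-score structure, duplicated genomic repeats beyond
what random sequence provides, or library artefacts — so green tests
demonstrate the pipeline's correctness on its stated model, not robustness
to every artefact of real sequencing data. Real data should enter via SAM.

Problem sizes used by the test suite and acceptance script (chosen to
represent the scenario faithfully at desk scale): the full 200 kb scenario
for the headline copy-number, boundary and SNP checks; 20–60 kb variants
for module tests; 10 simulation seeds for junction recovery and 20 for
segmentation parameter recovery (the latter simulating per-base Poisson
depth directly, since the property under test is segmentation, not
mapping).

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere except BED output (0-based
  half-open per the standard); conversions happen only at format
  boundaries.
* A zero-variance series returns `t = 0` with a flag instead of splitting.
* A perfect two-level split has infinite t; it is significant unless a
  permutation reproduces it exactly.
* Ties in the evolved majority base can never reach the 80% gate, so no
  tie-break is needed in SNP calling.
* `k` must be odd so every k-mer has a strand-distinct canonical form.
* Even copy numbers are generated (the last inverted copy abuts the right
  flank directly) but only odd copy numbers yield the wild-type outer
  junctions that the `tandem_inverted` label requires.
* The quality-score-based SNP filter scheme that real pipelines sometimes
  layer on top is intentionally absent: its thresholds are not published,
  and the adopted heuristic is count-based by design.

# Known limitations

* The mapper is ungapped; indels in reads reduce depth rather than
  producing mis-placements, and indel discovery relies entirely on the
  split-alignment screen.
* Median-centring assumes the neutral copy state dominates the genome.
* The background statistic treats the two boundary windows as independent
  and identically sized.
* The assembler emits unitigs only; a junction flanked by genomic repeats
  longer than `k − 1` would fragment.
* `copy_ratio` is calibrated for haploid strains compared against a
  haploid ancestor; no allele-fraction model is fitted.
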