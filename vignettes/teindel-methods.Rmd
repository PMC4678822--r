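---
title: "Split-read TE insertion/depletion calling: model, parameters and validation"
author: "teindel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-read TE insertion/depletion calling: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teindel)
```

## The procedure

`teindel` calls presence/absence differences of transposable elements
between a sequenced sample and its reference assembly from single-end (or
pair-split) short reads. The information carrier is the *split read*: a
read crossing a TE junction cannot map end-to-end anywhere, but its two
22-nt termini can, and where they land tells the story.

The pipeline is a fixed cascade:

1. **Preparation.** Paired reads are split into independent single-end
   reads; reads outside ±10 nt of the nominal length `L` are dropped;
   Phred trimming removes leading/trailing bases below Q20 and discards
   reads whose remaining mean quality is below Q20. Reads shorter than
   `2k + 1` (k = 22) after trimming are routed to the length discard,
   since their termini would overlap.
2. **Subtraction.** Reads mapping end-to-end to the reference genome
   (≤3 mismatches) are removed — they are simultaneously the coverage
   source for the CR denominators (confidence contract below). Reads
   mapping end-to-end to the TE consensus library or any auxiliary set
   (viral, structural-RNA) are removed next. Every input read is thereby
   assigned to exactly one class (genome-mapped, aux-mapped, split-input,
   quality-discarded, length-discarded); the per-stage tallies go into the
   run manifest and must sum to the input count.
3. **Insertion branch.** Termini of the surviving reads are mapped to the
   TE consensus (≤2 mismatches, suppressed above 5 alignments) and to the
   hard-masked genome (≤1 mismatch, unique required). A read with exactly
   one unique genome anchor and a 1–5-hit TE terminus is a candidate; its
   full read is then scored by local alignment against the unmasked genome
   (the score/length ratio). Candidates are clustered greedily per
   (chromosome, strand, family) within a 300-nt window; clusters need ≥4
   reads, an anchor span > `L/2 − 22`, a mean score ratio ≤ 0.83, and no
   overlap with the exclusion track.
4. **Depletion branch.** Both termini are mapped to the masked genome at
   ≤3 mismatches; unique, concordant terminus pairs more than `L` apart
   become candidates, clustered jointly on both breakpoint sides. Clusters
   need ≥4 reads and must span an annotated TE copy, whose name they take.
5. **Reporting.** Coverage ratios, nearest-gene annotation, extended BED
   output, 5-kb landscape bins, ≥20-event family profiles and 1-kb-rounded
   cross-sample comparison.

## Coverage ratios

For an insertion cluster the window of anchor starts is expanded by `k`
at its lower coordinate and

$$\mathrm{CR} = \frac{n_\mathrm{split}}{n_\mathrm{ref} + 1},$$

where $n_\mathrm{ref}$ counts accepted reference alignments in the window.
For a depletion, reference support is measured in two fixed flank windows,
$[e_5 - \tfrac{2L}{5},\; e_5 + k + \tfrac{L}{5})$ around the 5'-side
cluster end $e_5$ and $[s_3 - \tfrac{L}{5},\; s_3 + \tfrac{L}{5})$ around
the 3'-side cluster start $s_3$ (fractional bounds rounded half away from
zero, everything clamped to the chromosome), and

$$\mathrm{CR} = \frac{n_\mathrm{split}}{1 + (\mathrm{RefGen}_{5p} + \mathrm{RefGen}_{3p})/2}.$$

**Counting semantics.** `coverage_in_interval()` counts alignments
overlapping the window by ≥1 base (`mode = "any"`), the default behavior
of interval-coverage tools; a `mode = "within"` variant counting only
fully contained alignments is exposed. The choice changes CR magnitudes
substantially: with overlap counting, flank reads contribute to the
denominator, so even a homozygous insertion in a deep library has CR well
below 1 (a ~150-nt window at 40× collects ~60 overlapping flank reads),
whereas containment counting leaves the denominator near zero and CR near
the raw read count. Relative comparisons — the quantity the CR exists
for — are unaffected: CR still scales linearly with the variant allele
fraction at fixed depth (validated below). Absolute CR values should only
be compared between libraries at similar depth, window size and counting
mode.

**Confidence contract.** Internally mapped coverage reads are accepted
when their best alignment is unique at its mismatch level; externally
supplied SAM alignments are accepted when MAPQ ≥ `ref_align_min_conf`
(default 10). Both express the same idea: only confidently placed reads
vouch for the reference allele.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `read_len` (L) | 100 | nt | nominal library read length |
| `terminus_len` (k) | 22 | nt | terminus size; anchors must be unique at this length |
| `cluster_window` (W) | 300 | nt | greedy clustering window, both branches |
| `min_cluster_reads` | 4 | reads | minimum cluster support |
| `blat_ratio_max` | 0.83 | fraction | cap on mean local-alignment score ratio |
| `ref_align_min_conf` | 10 | MAPQ | coverage confidence floor |
| `pseudocount` | 1 | reads | CR denominator regularizer |
| `te_mm_max` / `te_hits_max` | 2 / 5 | mm / hits | TE-terminus mapping caps |
| `genome_mm_max_ins` | 1 | mm | genome-terminus cap, insertion branch |
| `mm_max_depl` | 3 | mm | terminus cap (depletion) and full-read subtraction cap |
| `length_tolerance` | 10 | nt | band around L for length selection |
| `qual_leading/trailing/avg_min` | 20 | Phred | trimming thresholds |
| `bin_size` | 5000 | nt | landscape bin width |
| `overlap_rounding` | 1000 | nt | cross-sample locus rounding |
| `min_family_count_profile` | 20 | calls | family-profile aggregation threshold |

All thresholds live in `te_config()`; nothing is hard-coded, so the
parameter-sensitivity of any stage can be probed directly (the test suite
does this for `cluster_window`).

## Numerical and algorithmic choices

**Mapper.** End-to-end mapping is Hamming-distance only (no indels), via
pigeonhole seeding: a query allowed `m` mismatches is covered with `m+1`
disjoint exact seeds, at least one of which must be error-free; candidate
diagonals are verified exactly. This reproduces the `-v`-mode semantics of
the classic short-read mappers the thresholds were expressed in, including
`-m`-style suppression: a query with more than `max_hits` alignments
reports none, but its true alignment count is retained (it still counts as
"mapped" for subtraction). `N` never matches anything, so hard-masked
bases cannot be aligned over. The mapper is validated against a
brute-force scan of every offset on small genomes. The full-read
subtraction cap of 3 mismatches is a deliberate simplification of
score-based end-to-end mapping with indels; externally produced SAM
alignments can be supplied for the coverage source where indel-aware
mapping matters.

**Local-alignment scorer.** The score ratio uses match +1, mismatch −1,
gap open −2, gap extension −1 (a gap of length g costs 2 + g), floor 0,
best over both strands and all loci, divided by read length. The default
path seeds on exact 8-mers and runs the full affine local alignment inside
padded, merged candidate windows; `exhaustive = TRUE` aligns against whole
targets. The seeded path can in principle underestimate a similarity whose
best alignment contains no exact 8-mer, but any alignment near the 0.83
decision boundary (score ≥ 83 over a 100-nt read implies ≥ ~90 matching
bases) necessarily contains long exact stretches, so decisions are
unaffected; agreement with an independent quadratic-time aligner is
asserted in the tests on junction-like, mutated and genomic reads.

**Clustering.** Anchors are sorted (position, then read id — fully
deterministic) and grouped left-to-right: a candidate joins the open
cluster iff it is within W of the cluster's leftmost member; the depletion
branch applies the same rule jointly to both breakpoint sides. When a TE
terminus hits several families, the fewest-mismatch hit wins, ties broken
by family name. Both 5'-anchored and 3'-anchored candidates cluster
together, so a well-covered homozygous event typically yields one cluster
per read strand; consumers should deduplicate by locus when counting
events (as `evaluate_insertion_calls()` does).

**Intervals.** 0-based half-open everywhere, BED convention; strand `.`
means unstranded. Interval expansions clamp at chromosome ends. Kilobase
rounding for cross-sample comparison rounds half away from zero (base R's
`round` is banker's); nearest-kb was chosen over floor so that two calls
at, say, 10,950 and 11,050 share a key.

## Design decisions that were genuinely open

* **Cluster size** is interpreted as the anchor-start span
  (max − min): a genuine junction produces anchors tiling ~`L − 2k`
  offsets, so demanding span > `L/2 − 22` rejects PCR-stack-like pile-ups
  at a single offset.
* **Length selection precedes quality trimming** (libraries pooled from
  runs of different lengths are reduced to the dominant run first); reads
  that fall below `2k + 1` after trimming are still discarded.
* **No score-ratio filter on depletions** by default — uniqueness at ≤3
  mismatches on the masked genome is the specificity gate there; a
  `depl_blat_filter` switch enables the filter for experimentation.
* **Depletion gap** is measured innermost (end of the left terminus to
  start of the right), i.e. the putatively deleted span; cluster side
  coordinates are the innermost consensus (max of left ends, min of right
  starts).
* **CR expansion side**: the window is expanded at its lower coordinate
  regardless of strand.
* The exclusion track is user-supplied and empty by default.

## The synthetic validation worlds

`fixture_spec()` + `simulate_world()` build fully deterministic test
worlds: uniform-random chromosomes; a TE consensus library; exact
consensus copies embedded at annotated, well-separated positions; planted
novel insertions (full consensus, optional TSD, loci kept > L from
annotated copies and chromosome ends and > 2L from each other) and clean
excisions of annotated copies; uniform-start reads from two haplotypes
mixed at the allele fraction, with substitution errors and constant Q30
qualities. `make_fp_world()` additionally engineers the false-positive
mechanism the ratio filter targets: a degenerate repeat copy present in
the reference but missing from the annotation track, with the sample
carrying its own variant diverged at the same sites — reads from it evade
every mapping stage yet align locally to the genome at ratios above 0.83.

The standard validation regime, used by the acceptance tests, is a 500-kb
genome (2 × 250 kb), 4 families of 1–3 kb, 10 homozygous insertions and 5
excisions, 100-nt reads at 50× with 0.2% errors; specificity fixtures use
60-kb single-chromosome worlds at 50×, and the allele-fraction contrast
uses 80-kb worlds at 40× over 10 seeds (fraction 1.0 vs 0.5). These sizes
were chosen so that every stage sees realistic multiplicities (hundreds of
split reads, multi-family clustering, coverage in the tens) while a full
validation run stays interactive.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real libraries: indel sequencing errors and
indel-containing alignments, base-quality profiles and quality-correlated
errors, PCR duplicates and GC bias, nested/fragmented/5'-truncated TE
copies, segmental duplications, and reference assemblies with
heterochromatic repeat oceans. The substitution-only error model matches
the Hamming alignment core by construction.

On these worlds the caller attains full recall of planted homozygous
events at 50× with every cluster within one read length of a planted
breakpoint and exact family assignment, zero calls on variant-free
fixtures, and removal of all engineered degenerate-repeat clusters by the
ratio filter (re-measured on every test run; see
`tests/testthat/test-acceptance.R`).

One empirical subtlety the allele-fraction validation exposes: halving the
allele fraction halves the split-read count, but the homozygous locus also
*loses* some reference coverage in its window (junction-crossing reads
cannot map back), so the CR ratio between fraction 1.0 and 0.5 runs
slightly above the naive ×2 — the tests allow the sampling band the
contrast is specified with.

## Known limitations

* Hamming-only alignment: TE junctions combined with nearby indels, or
  libraries with high indel error rates, lose sensitivity; supply external
  SAM alignments for the coverage source where this matters.
* Breakpoints are cluster-resolution, not base-resolution; no target-site
  duplication inference, no insertion orientation within the TE, and no
  zygosity calling beyond the CR.
* A depletion is indistinguishable from an insertion private to the
  reference assembly; interpretation is the user's.
* Reported clusters are per strand; a deeply covered event appears twice.
* The greedy window clustering is deterministic but order-dependent at
  pathological spacings (anchors forming a chain longer than W); planted
  and real events are far sparser than this in practice.
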