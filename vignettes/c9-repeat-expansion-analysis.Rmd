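---
title: "Methods: methylation, length and purity of the C9orf72 repeat expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation, length and purity of the C9orf72 repeat expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the measurement
model, the synthetic cohort it is validated on, the analysis conventions,
and the choices made where the design was genuinely open.

# Measurement model

A targeted, amplification-free long-read experiment at the *C9orf72* locus
yields circular-consensus (HiFi) reads that traverse the full GGGGCC
repeat tract plus non-repeat flanks, each carrying: the consensus
sequence, the number of full passes, a predicted accuracy, and one
integer score in 0–255 per CpG dinucleotide, proportional to the
probability that the cytosine is 5-methylated (symmetric methylation of
both strands is assumed by the underlying chemistry, so hemi-methylation
is invisible).

Three derived per-read measures drive everything downstream:

* **Median methylation score**, with the median of an even number of CpGs
  taken as the mean of the two middle values (the standard convention;
  the score scale does not define another).
* **Proportion of methylated CpGs**: the fraction of CpGs with score
  ≥ 128. The inclusive comparator implements "top half of the scale". The
  alternate rule used for sensitivity is *strict*: score > 192 (the top
  quarter, 75% of 255 rounded up). The asymmetry — inclusive at 128,
  strict at 192 — is preserved deliberately from the analysis convention
  this package follows; on an integer scale `> 192` equals `>= 193`.
* **Repeat count**: the tract runs from the first base of the first exact
  GGGGCC occurrence to the last base of the last one (0-based half-open
  internally; 1-based inclusive in human-facing reports), and the count
  is `floor(span / 6)`. Span semantics mean an interrupted unit still
  contributes to length, which is what "number of repeats between the
  first and last motif occurrence" should measure. The exact
  non-overlapping match count is emitted alongside
  (`exact_motif_count`) for transparency; since GGGGCC is not
  self-overlapping at any period below 6, greedy left-to-right matching
  equals the regular-expression count.

Per sample and allele, reads are aggregated by medians, and the range
(maximum − minimum) captures within-individual variability. For repeat
length the **maximum** per sample is the primary estimate — in this
assay class the per-read length distribution is right-tailed and its
maximum tracks Southern blot sizing better than the median — while the
range is the somatic-mosaicism readout. Purity (GC% and motif%) is
computed over the tract only, never the flanks, because it asks what the
expansion itself is made of.

# Filtering and allele assignment

Two consensus profiles gate the branches: `methylation_purity` (≥ 7 full
passes, predicted accuracy ≥ 0.99) and `length` (≥ 1 pass, ≥ 0.80), both
with read length in [10 bp, 100 kb] and both flanks required, so that
only molecules containing the complete expansion are measured. All
boundary comparisons are inclusive. The two profiles run as parallel
branches of `run_pipeline()`, not one pass with two flags, mirroring the
practice of generating consensus reads separately for the two analyses.
The signal-to-noise threshold applied by upstream consensus callers is
upstream-tool territory: it is never recomputed here.

Whether a read spans the locus is decided by exact matching of two
20-base **anchors** (the outer termini of the flanks), left anchor before
right. Anchor matching, rather than alignment coordinates, lets the same
code run on plain fixtures and SAM input; it is exact because the
simulated flanks are error-free, and that is a documented limitation for
real reads (a single flank sequencing error defeats an exact 20-mer
match; real-data use should relax to approximate matching or alignment
coordinates).

Allele assignment clusters per-read k-mer count vectors with k-means
(two centroids, 10 restarts, Euclidean distance on **raw counts**).
Raw counts — not frequencies — let tract length dominate the distance,
which is the intended separator. Defaults that the procedure does not
itself determine:

* **k = 6**, the motif length, so one coordinate of the feature vector is
  literally "number of motif copies"; configurable.
* **Features are restricted to the inter-anchor segment**, the stand-in
  for a fixed genomic window around the repeat; constant flank remainders
  shift all vectors equally and cannot affect Euclidean distances.
* **Clustering is per sample.** The two alleles belong to one individual;
  pooling a cohort would let between-individual expansion-length spread
  exceed the wild-type/expanded gap and split the expanded cloud instead.
  Somatic length variation within a sample is absorbed into the expanded
  cluster.
* **Labelling rule**: the cluster with the larger mean motif-6-mer count
  is `expanded`; ties (possible only in degenerate synthetic cases) go to
  the cluster with larger mean read length, since expansion implies
  length. The rule is invariant to centroid initialisation and to
  uniform scaling of tract lengths.
* All reads identical is a hard, instructive error (single-allele mode
  must be chosen explicitly), as is a group with fewer than two reads.

# The synthetic cohort

`simulate_cohort()` generates the study conditions the pipeline is
validated under. Per individual: a wild-type allele of 2–30 repeats
(stable; no mosaicism — consistent with wild-type sizing being fully
concordant with fluorescent-PCR genotypes) and an expanded allele with a
modal length; per read, the expanded repeat count is

```
round(modal × (1 + |N(0, dispersion)|)),   dispersion = 0.4
```

a half-normal right tail. The dispersion default makes the per-sample
range roughly half the maximum at typical depths, the regime in which
range and maximum correlate strongly across a cohort, as observed for
this locus. Flanks are fixed synthetic 120-bp GC-containing sequences
with six CpGs each and no internal GGGGCC — not the GRCh38 flanks, which
keeps the repo genome-free while preserving the flank–tract–flank
structure; anchors are unique 20-mers by construction.

**Methylation.** Every CG dinucleotide of the emitted sequence gets one
score. The mean methylation fraction of tract CpGs is
`clamp(intercept + slope × repeat_count)`; flank CpGs within 35 bp of a
read end are drawn at `flank_cpg_meth_level` (0.9), other flank CpGs at
the baseline intercept — this reproduces the "highly methylated CpGs at
the beginning and end of each read" pattern without saturating the whole
flank. Scores are `clamp(round(255 × p + N(0, sd)), 0, 255)` with
`sd = 60` score units; the per-read score distribution of real data is
not published, so the Gaussian-on-mean model is an explicit stand-in.
The defaults `intercept = 0.21`, `slope = 8.5e-5` per repeat were solved
once from three published per-sample anchor points for blood cohorts of
this expansion (proportions of roughly 13%, 39% and 66% methylated CpGs
at about 330, 2,750 and 4,090 repeats respectively) under the score
model, and are not tuned thereafter. With them, a cohort whose modal
lengths span ~700–3,300 repeats reproduces the qualitative structure:
expanded above wild-type in nearly all individuals, methylation rising
with length and (through the length–age coupling below) with age.

**Interruptions.** Each repeat unit is independently interrupted with
probability `1e-3`, as a single-base substitution or single-base deletion
with equal probability — interruptions at this locus are predominantly
single-nucleotide changes. At this rate long reads almost surely carry
interruptions while short ones do not, which induces the negative
length–purity association seen in real data. Simulated tracts are
purer (motif fraction ≈ 99.9%) than published cohort medians (~90%);
matching those medians would need a per-unit rate near 0.1, which would
contradict the "few interruptions" character of the locus under this
package's span-based purity definition. The generator keeps the low
rate and this tension is acknowledged rather than hidden.

**Read metadata.** Passes follow
`max(1, Poisson(min(30, 120000 / read_length)))` — a per-molecule yield
budget, so ~25-kb expanded molecules average ~5 passes while short
wild-type molecules cap out — and predicted accuracy is
`1 − 10^−(1 + 0.35 × passes + N(0, 0.2))`, clamped to [0.5, 0.999999].
Both are invented plumbing (only the filter thresholds are given by the
assay convention), calibrated so that roughly half of expanded reads
survive the 7-pass/99% profile, as in real cohorts of this type. A read
is truncated with probability 0.15, losing the outer part of one flank
including its anchor.

**Cohort structure** (when modal lengths are not supplied): modal lengths
are uniform on 700–3,300 repeats; age at collection is
`40 + 0.011 × modal + N(0, 8)` years (longer expansions in older
carriers); diagnosis is age-driven (symptomatic above ~52 years, one FTD
case among ALS); onset precedes collection by ~1.5 years for symptomatic
carriers; promoter methylation is log-normal around a length-linked mean
with hypermethylation flagged at ≥ 10%; Southern repeat and smear
estimates are noisy transforms of the modal length (the smear missing
for six individuals). Four pedigrees embed seven paternal transmissions
with contractions of 1,300–2,100 repeats — large enough that the
offspring's methylation drops by well over the 10-point familial
threshold — and six individuals carry longitudinal draws (13 samples),
two of them drifting upward in modal length, four stable. These are the
package's fixed study conditions, not dials.

**What the generator does not emulate**, and hence what green tests do
not show about real data: sequencing errors anywhere (flanks are exact,
so anchor matching never fails spuriously); alignment artifacts and
supplementary/secondary reads; interruption hotspots or multi-motif
decomposition of the tract; realistic purity medians (above); per-CpG
score distributions beyond a clamped Gaussian; non-CpG modifications and
hemi-methylation; cell-type composition underlying blood–tissue
differences (the two-tissue contrast runs on synthetic tissues differing
only in their methylation and length parameters).

# Statistical conventions

All tests are two-sided. The paired allele contrast is the Wilcoxon
**signed-rank** test on per-individual differences (a "paired rank-sum"
test is the signed-rank test), zeros dropped, exact null for up to 25
non-zero differences without ties, otherwise the normal approximation
with continuity correction (the switchover is configurable). The
unpaired contrast is the rank-sum test with R's exact/approximate
selection. Spearman correlations use average ranks for ties; constant
input or fewer than three pairs yields an explicit `NA`-with-note row
rather than an error, so association batteries always complete. The
age-adjusted comparison is OLS of the outcome on group and age with
coefficient t-tests; a singular design is a hard error. No
multiple-testing correction is applied — raw two-sided p-values are
reported, matching the reporting convention of studies at this cohort
scale; a Benjamini–Hochberg pass can be applied downstream by the user.

The longitudinal rule classifies an individual as `stable` when the
series' total change is below 0.10; the familial rule calls a
transmission `decrease`/`increase` at a change of at least 0.10. Both
interpret "10%" as **absolute** proportion units (percentage points),
since the proportions are themselves reported on a percent scale; a
`relative = TRUE` switch offers the alternative reading. A 1e-9
tolerance absorbs floating-point noise at the boundary (0.50 − 0.40 must
count as a 10-point change).

# Numerical and engineering choices

* Scores are integers; clamped rounding happens once, at emission.
* Coordinates are 0-based half-open internally, 1-based inclusive in
  prose and reports.
* Every source of randomness flows from a single configured seed;
  per-sample clustering seeds are derived as `seed + group index` over
  the sorted group names, so results are independent of input row order.
  A missing seed in the simulator configuration is an error, not a
  default — simulated cohorts must be reproducible.
* Fixtures are plain TSV/FASTA; the modification-annotated format is
  text SAM with standard `MM:Z:C+m` delta encoding and `ML:B:C` scores,
  round-trip tested against hand-computed offsets.
* Waterfall matrices encode "read has no i-th CpG" as `NA`, distinct
  from a true score of 0; plots render missing cells as background.

# Validation strategy and problem sizes

The test suite validates by independent oracles and parameter recovery
rather than by re-asserting constants: filtering, k-mer counting, tract
location/counting, purity, per-read medians/proportions, and both
Wilcoxon tests are each checked against brute-force re-implementations
(sliding windows, explicit loops, exact enumeration of signed-rank and
rank-sum null distributions) on 10,000 random instances per operation.
Methylation recovery uses 30 individuals with true fractions on a
0.1–0.9 grid, score noise 10, ≥ 20 reads and ≥ 50 CpGs per read,
requiring mean absolute error ≤ 0.05 and Spearman ≥ 0.95 against truth.
Length recovery (interruptions and truncation off) must be exact over a
cohort spanning 64–4,088 repeats. Allele assignment must reach 100%
accuracy versus truth over 50 independently seeded cohorts with
wild-type ≤ 30 and expanded modal lengths of 64–800 repeats; the small
per-cohort size (5 individuals, 4–8 reads per allele) is the package's
chosen test size and covers the hardest separation (modal 64 versus
wild-type up to 30). Type-I error of each test is checked against a
central 95% binomial band over 500 null replicates at α = 0.05, and the
full pipeline must be byte-identical across reruns at a fixed seed.

# Known limitations

Exact anchor matching and error-free flanks overstate real-data span
detection; the purity defaults are purer than real cohorts (above); the
score-noise model is a stand-in; clustering assumes exactly two alleles
per sample (more than two somatic clusters are absorbed into the
expanded label); and the package begins at modification-annotated
consensus reads — consensus generation, alignment and 5mC calling are
upstream tools' responsibility.
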