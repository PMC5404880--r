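---
title: "Consensus binding sites and enhancer persistence: methods and design"
author: "chromPersist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus binding sites and enhancer persistence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromPersist)
```

# Overview

`chromPersist` analyses an inducible transcription factor's chromatin
footprint across an induction/withdrawal time course.  Its stages are the
ones such a study needs in order: derive a high-confidence binding-site
list from replicate peak calls; turn reads into normalized coverage and
site-centered signal matrices; classify sites by the persistence of
chromatin accessibility after the factor is withdrawn; and annotate the
classes positionally and statistically.  A ground-truthed simulator
generates every input the pipeline consumes, so all stages are tested end
to end without sequencing data.

This vignette records the model, the tunable parameters, and the design
decisions, in enough detail that a maintainer can defend or change them.

# Coordinates and interval logic

All coordinates at the package boundary are **0-based, half-open** (the
BED convention); conversion to the 1-based closed `GRanges` representation
happens only inside the I/O layer.  Two intervals *overlap* iff they share
at least one base — no reciprocal-fraction requirement, which is the common
default for peak intersection.  Consequently, intervals that merely abut
(`end == start`) do not overlap and are *not* merged by
`merge_overlapping()`.  Peaks are treated as unstranded; strand is carried
only for reads and TSSs.  Chromosome names are matched as exact strings:
no `"chr"` aliasing, so mixed naming conventions fail loudly rather than
silently mismatching.

The center of `[start, end)` is `floor((start + end) / 2)`; the floor is
the tie-break for even-width intervals and is used consistently by the
matrix, TSS-distance and proximity code.

# Consensus binding sites

Replicate ChIP-seq peak calls for the induced (treatment) and uninduced
(control) conditions enter `consensus_sites()`.  The rule: keep a region
that is found in at least `min_treatment_support` (default 2) distinct
treatment replicates and in no control replicate.

Two details make "found in" reproducible for BED3 input with no summit
information:

* **Candidate construction.**  Candidates are the merged union of all
  treatment-replicate peaks; a replicate supports a candidate when at
  least one of its peaks overlaps it.  This makes support well defined
  even when replicate peak boundaries disagree.
* **Whole-candidate subtraction.**  A control overlap removes the entire
  candidate, not just the overlapping bases — the unit being filtered is
  the peak, not the base pair.

Output is sorted and disjoint, with the replicate-support count in the
`score` column.  Adding a control replicate can only remove sites; this
monotonicity is asserted in the tests.  Note that adding a *treatment*
replicate can occasionally lower the site *count* by bridging two
candidates into one; the covered bases still only grow.

# Signal tracks and matrices

`read_records()` represents a read by its 5' end and strand — all that
extension and offset correction need.

* **Tn5 offset correction** (`tn5_correct()`): ATAC-seq reads are shifted
  +4 bp (plus strand) / −5 bp (minus strand) so the 5' end sits on the
  transposase insertion point.  Positions are clipped at 0 rather than
  dropped, preserving the read count.  Mitochondrial reads are removed
  with `filter_chromosomes()` (default `"chrM"`).
* **Fragment extension** (`extend_and_pileup()`): each read contributes
  one unit of coverage over a fragment-length window extending 3' from its
  5' end.  A minus-strand read covers the half-open interval
  `[p − L + 1, p + 1)`, so the 5' base is included and every fragment
  covers exactly `L` bases — this keeps the conservation law
  `total coverage = reads × L` exact, which the tests audit (clipped mass
  at chromosome ends is recorded on the track).  Typical fragment lengths
  are assay-specific (150–250 bp) and are plain parameters.
* **Normalization** (`normalize_per_million()`): values scale by
  `1e6 / total_reads`; the `normalized` flag makes double normalization an
  error.  Per-million scaling has a composition bias worth remembering:
  when a large share of the signal disappears (as it does after factor
  withdrawal), the surviving signal is re-inflated, and persistence ratios
  can exceed 1.  The classification below is robust to this because it
  separates classes by relative contrast, not absolute level.
* **Signal matrices** (`signal_matrix()`): rows are sites, columns are
  `bin_size` bins over `[center − window, center + window)`.  Defaults:
  window 1500 bp (the conventional metagene half-window for enhancer-scale
  structure), bin 50 bp (unstated upstream; 50 bp balances resolution and
  noise).  Bins are mean-per-base, matching reference-point matrix
  semantics of the standard metagene tooling; bases beyond chromosome ends
  contribute 0; sites on chromosomes absent from the track are an error
  naming the chromosome.  Site rows are never flipped: peak centers have
  no orientation.
* **Bimodality index** (`bimodality_index()`): mean signal in the flanks
  (`[−1000, −200)` and `[200, 1000)` bp) over mean signal in the center
  (`[−200, 200)` bp), with ε = 1e-9 guarding empty centers.  Values above
  1 indicate the flanking nucleosomal enrichment typical of active
  enhancers (H3K4me1/H3K27ac); accessibility (ATAC) profiles are
  center-enriched and score below 1.  The flank/center windows are
  declared defaults, not reconstructions of any published choice; the
  index requires `window ≥ 1000` bp.

# Site classification

The per-site accessibility scalar is the mean matrix signal over
center ± 250 bp, in normalized units.  `classify_types()` scales each
site's time-course vector by its induced baseline, clusters the scaled
vectors with seeded k-means (`k = 2` by default — two persistence classes
is the hypothesis under test; exploratory heatmaps may use any k), and
labels each whole cluster by its mean **persistence ratio** (first
withdrawal timepoint / baseline): below 0.5 → Type 1, otherwise Type 2.
Labels attach to clusters, never to individual sites, so single noisy
profiles cannot flip class.  Sites with zero baseline cannot be scaled;
they are excluded and reported as `unassigned`.

k-means uses Lloyd's algorithm on squared Euclidean distance with 10
random starts under the caller's seed (deterministic per seed).  A
degenerate input with fewer distinct rows than clusters returns a single
cluster with a warning instead of crashing.

**Accessibility calls.**  `call_accessible()` marks a site accessible at
a timepoint when its scalar exceeds the maximum of two thresholds:

1. a *background floor* — the q-th quantile (default 0.75) of scalars at
   uniform random background positions of the same track
   (`accessibility_threshold()`, seeded); and
2. a *dynamic-range criterion* — a fraction (default 0.25) of the cohort's
   median baseline scalar.

The second criterion is essential, not cosmetic: site signal is additive
over background, so in deeply covered data a site that has lost 90 % of
its signal can still sit many standard deviations above any background
quantile.  A background-only threshold would therefore call essentially
every site accessible at every timepoint and the withdrawal contrast would
vanish.  Biologically, "loss of accessibility" in a withdrawal experiment
means loss relative to the bound state, which is exactly what the
dynamic-range criterion encodes.  Both knobs are exposed
(`background_quantile`, `dynamic_fraction`).

**Chi-square test.**  `chi_square_accessibility()` is the uncorrected
(no Yates) Pearson chi-square with 1 df on a 2×2 table of
accessible/inaccessible counts in two conditions — the uncorrected form is
the default meaning of "chi-square test" and is checkable against the
closed form Σ(O−E)²/E, which the tests do on 1000 random tables.  A zero
row or column total is an error (statistic undefined), not a silent NaN.

**PCA.**  `pca_samples()` mean-centers features (sites) across samples and
projects via `prcomp`; each component's sign is fixed so its
largest-magnitude loading is positive, making coordinates reproducible.
`restrict_to` keeps only feature columns overlapping a peak set — the
device that distinguishes factor-driven structure (visible only at bound
sites) from cell-of-origin structure (genome-wide).

# Annotation

* **Nearest TSS** (`nearest_tss()`): signed center-to-TSS distance
  (positive = TSS at larger coordinate).  Center-to-TSS rather than
  edge-to-TSS keeps the convention of the matrix code; the published
  convention is unstated either way.  Ties go to the smaller TSS
  coordinate, then the lexicographically smaller gene name.  Categories:
  promoter ≤ 1 kb, distal > 5 kb, and an explicit `intermediate` band for
  1–5 kb so the three categories always partition the sites (the two
  printed classes alone do not).
* **Co-factor proximity** (`center_distance_stats()`): per peak of set A,
  the minimum center-to-center distance to set B within `max_distance`
  (default 2000 bp — the expected medians are a few hundred bp, so the cap
  is a search radius, not a claim).  Unmatched peaks are counted, and an
  empty match set yields an NA median rather than an error.
* **Expression signature** (`expression_signature()`): genes expressed in
  the satellite-like reference (`satellite > 1` normalized count) split by
  ≥2-fold change between induced and withdrawn conditions, with a
  pseudocount of 1 on both sides of every ratio.  The reference-expression
  filter applies to both the down- and up-regulated lists; the two lists
  are provably disjoint for any fold threshold ≥ 1.

# The synthetic-data generator

`sim_config()` fixes the simulated study conditions; the defaults are the
conditions the package is tested under and are not tuned per run:

| parameter | default | meaning |
|---|---|---|
| genome | 3 × 2 Mb | small enough for seconds-scale runs |
| `n_sites` | 500 | non-overlapping bound sites (≥4 kb spacing) |
| `type1_fraction` | 0.6 | share of factor-dependent sites |
| `type1_decay` | 1, 0.10, 0.05, 0.02 | accessibility vs baseline over +Dox, 12 h, 24 h, 3 d |
| `type2_decay` | 1, 0.90, 0.88, 0.85 | persistent class |
| replicates | 3 treatment / 2 control | peak-call replicates |
| `sensitivity` | 0.9 | per-replicate true-site call probability |
| `false_peak_rate_per_mb` | 2 | spurious peaks per replicate |
| `reads_per_site` | 300 | expected baseline reads per site |
| `background_per_bp` | 0.01 | genomic background coverage |
| `cofactor_offset_median` | 240 bp | co-factor center offset at Type 2 sites |
| `mark_retention` | Type1 0.2 / Type2 0.9 | post-withdrawal enhancer-mark survival |

Reads are Poisson per bin over Gaussian-shaped expected rates:
accessibility is a center Gaussian (σ = 100 bp) scaled by each site's
per-timepoint decay; H3K4me1/H3K27ac are symmetric flank Gaussians at
±500 bp (σ = 150 bp) at marked sites, so their metagene is bimodal by
construction and collapses along the Type 1 decay; H3K4me3 sits only at
planted TSSs; H3K27me3 elevates uniform blocks placed disjoint from all
bound sites (asserted at every generation).  `background_per_bp = 0.01`
reflects that a substantial share of ATAC reads is genomic background; it
also damps the per-million composition bias between timepoints.  The
co-factor offsets are folded-normal with median ≈ 240 bp — an
enhancer-scale design target, not a reproduction claim.  Every stage
derives its RNG stream from the single config seed plus a fixed
per-operation offset, so stages are individually and jointly reproducible.

The multi-sample PCA panel (`simulate_accessibility_panel()`) draws three
cell-of-origin batches (some samples factor-expressing, some not), a
batch-specific signal at every site, and a factor effect only at bound
sites in factor-on samples.  Its calibration (factor effect 8 vs batch sd
2 per site; 20 000 background sites against 500 bound, roughly the real
40:1 proportion of genome-wide accessible sites to one factor's sites)
realizes the intended structure by construction: genome-wide variance is
dominated by batch, bound-site variance by factor status, so unrestricted
PCA groups by origin while restricted PCA separates factor status.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequence content, mappability and GC bias,
fragment-size distributions, duplicate reads, peak-caller artefacts
beyond uniform false positives, correlated replicate noise, copy-number
variation, and any coupling between expression and binding beyond the
planted fold changes.  The generator demonstrates that the *analysis* is
correct under its stated statistical assumptions, not that those
assumptions hold for any particular dataset.

# Numerical and degenerate-input choices

* Interval parsers reject non-integer coordinates and `end ≤ start`,
  naming the offending line; empty files parse to empty sets.
* `overlap_fraction()` on an empty query is an error (undefined fraction),
  not NaN.
* Matrix windows must be divisible by the bin size (enforced, not
  silently truncated).
* k-means determinism comes from the caller's seed; all simulator seeds
  are derived from one config seed by fixed offsets.
* Floating-point checks in tests compare the chi-square statistic to the
  closed form at 1e-9 relative tolerance and matrices to per-base
  brute-force at 1e-12.

# Problem sizes

The test and acceptance runs use the default 3 × 2 Mb genome with 500
sites at 50 bp bins — chosen so a full end-to-end run takes seconds and
the whole suite a few minutes, while keeping ≥200 expected reads per site
so Poisson noise is realistic rather than dominant.  All sizes scale
through `sim_config()`.

# Known limitations

* Consensus candidates inherit merged-union boundaries; no summit
  refinement is attempted (BED3 input carries none).
* The accessibility call's dynamic-range criterion references the cohort
  median baseline, so it presumes the baseline condition is the bound
  state; reversed designs should swap the column order.
* `nearest_tss()` requires at least one TSS on every chromosome that
  carries sites, by design (a cross-chromosome "nearest" is biologically
  meaningless).
* Per-million normalization is kept for fidelity to standard practice
  despite its composition bias; a spike-in or quantile scheme would need
  information the inputs do not carry.
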