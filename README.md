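# chromPersist

Condition-specific consensus binding sites and enhancer-persistence
classification from chromatin profiling time courses.

## The scientific problem

When a transcription factor can be switched on and off — for example a
doxycycline-inducible factor in a stem-cell model — ChIP-seq and ATAC-seq
across the induction/withdrawal time course can ask two questions that a
single-condition experiment cannot:

1. **Which binding sites are real?**  Replicate peak calls disagree; peaks
   present without induction are artefacts.  The consensus rule implemented
   here keeps a region only if it is supported by at least *m* (default 2)
   distinct treatment replicates **and** is absent from every control
   (uninduced) replicate.
2. **Which of the factor's enhancers depend on it?**  After withdrawal,
   chromatin accessibility at some bound sites collapses within hours
   (**Type 1**: accessibility and enhancer marks strictly factor-dependent)
   while at others it persists for days (**Type 2**: maintained
   independently, typically by other factors binding nearby).

The package implements the full analysis path between those two questions:

* **Intervals & I/O** — 0-based half-open (BED-convention) peak sets as
  `GRanges`, BED/bedGraph/TSS-table readers and writers with strict
  validation; merge, overlap, center and coverage operations
  (GenomicRanges/IRanges under the hood).
* **Signal** — ATAC-seq Tn5 insertion-offset correction (+4 bp on `+`
  reads, −5 bp on `−` reads), fragment-length read extension, binned
  per-million-normalized coverage tracks, reference-point signal matrices
  (±1.5 kb around site centers by default), metagene profiles, and a
  flank/center **bimodality index** quantifying the bimodal nucleosomal
  configuration of active enhancers.
* **Classification** — per-site accessibility scalars over the time
  course, seeded k-means on baseline-scaled profiles, whole-cluster
  Type 1 / Type 2 labels from the persistence ratio
  (first-withdrawal / baseline, threshold 0.5), accessibility calls, and
  an uncorrected Pearson chi-square test for altered accessibility.
* **Annotation** — nearest-TSS signed distances with
  promoter (≤1 kb) / intermediate / distal (>5 kb) categories,
  center-to-center proximity to a second factor's peaks,
  H3K4me1/H3K27ac enhancer-signature categories and per-class retention,
  sample PCA optionally restricted to bound sites, and a ≥2-fold
  expression-signature filter.
* **Synthetic data** — a ground-truthed generator
  (`simulate_truth()` and friends) that emulates every input the analysis
  consumes, so the whole pipeline is testable without sequencing data.

## Worked example

Run the whole pipeline on the default simulated study (500 bound sites,
60 % Type 1, four ATAC timepoints, three treatment + two control peak-call
replicates):

```r
library(chromPersist)
man <- run_pipeline(list(seed = 7), out_dir = "demo_run")
print(man)
#> chromPersist run bfa826f025224bf0d3fe64b5e409b7f6 (seed 7)
#>   consensus sites: 482
#>   site classes: Type1=289, Type2=193
#>   accessibility chi-square: X2 = 300.3, p = 2.77e-67
#>   median |TSS distance|: 10268 bp
#>   co-factor median center distance: 250 bp (193 matched)
#>   expression signature: 22 down, 34 up
summary(man$typing)
#> Site typing summary
#>   timepoints: plus_dox, wd_12h, wd_24h, wd_3d
#>  cluster mean_persistence  type   n
#>        1        1.5547504 Type2 193
#>        2        0.2013647 Type1 289
```

Reading the output: 482 of the 500 planted sites survive the
two-replicate-consensus / control-subtraction rule (the binomial
expectation at per-replicate sensitivity 0.9 is 97.2 %).  K-means on
baseline-scaled accessibility profiles splits them into a cluster that
keeps ~20 % of its baseline accessibility 12 h after withdrawal (Type 1)
and one that keeps it all (Type 2; the ratio exceeds 1 because per-million
normalization re-inflates surviving signal when global signal is lost).
The chi-square test on accessible-site counts at +Dox versus 12 h is the
formal version of that contrast.  Type 2 sites sit a median of 250 bp from
the planted co-factor (MyoD-like) peaks.  Stage outputs land in
`demo_run/` as BED/TSV/YAML text files.

The same stages are exposed individually (`consensus_sites()`,
`signal_matrix()`, `classify_types()`, `nearest_tss()`, ...) and through a
thin command-line wrapper, `inst/cli/chrompersist.R`, with subcommands
`simulate`, `consensus`, `matrix`, `classify`, `annotate`, `proximity`,
`signature`, `pca` and `run`.

See `vignettes/enhancer-persistence.Rmd` for the model, the tunable
parameters and the design choices.

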