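# srnapipe

An R toolkit for analysing single-end small RNA sequencing (smallRNA-Seq)
libraries end to end: from raw FASTQ reads with 3' adapter contamination to
annotated small non-coding RNA (sncRNA) counts, no-replicate differential
expression and miRNA target-site prediction. It is aimed at transcriptomics
groups profiling miRNAs, piRNAs and other sncRNAs who need a scripted,
reproducible alternative to stitching together ad-hoc tools — including the
common situation where each condition was sequenced once and
replicate-based statistics are unavailable.

## What it computes

**Pre-processing.** Error-tolerant 3' adapter cleavage: a candidate match of
adapter length *L* with *E* edit errors (substitutions + indels) is accepted
iff *L* ≥ *o* (min overlap, default 3) and *E* ≤ ⌊*eL*⌋ (error rate,
default 0.1); ties resolve to fewest errors, then 5'-most start, then
adapter order. Mean-quality filtering (default Q20) and a ≥15 nt length
cutoff follow.

**Annotation cascade.** Unique sequences are matched (Hamming,
substitutions only) against ordered per-class reference libraries — by
default miRNA, tRNA, rRNA, mRNA, piRNA, other — and assigned to the first
library with a hit, which both quantifies every class and removes
cross-mapping artifacts from downstream classes. miRNA reads are classified
as canonical / 5p_shift / 3p_shift / both_shift isomiRs. Class totals plus
unassigned reads always partition the input exactly.

**Count statistics.** Minimum-count and nearest-rank percentile filters;
an additive correction factor *k* (median of pooled nonzero counts) that
damps low-count fold-changes:

    FC = (a + k) / (b + k),  reported signed: r if r >= 1 else -1/r

With counts 10 vs 5 and k = 30 the signed FC is **1.14** (vs **2.0**
uncorrected) — small counts no longer clear a ±1.5 threshold, while
4000 vs 2000 still reports 1.99.

**Differential expression without replicates.** Quantile normalization of
the two libraries, per-feature two-sided Fisher's exact test of
[[a, N_t − a], [b, N_c − b]] against the library totals
(minimum-likelihood two-sided summation), Benjamini–Hochberg adjustment,
and calling at |FC| ≥ 1.5, p ≤ 0.05 (raw p by default). Pearson-distance
average-linkage clustering and PCA summarize multi-sample experiments.

**Target prediction.** 3'UTR scanning for the canonical seed sites of each
miRNA (seed = nt 2–8): 8mer, 7mer-m8, 7mer-A1, with per-locus precedence
8mer > 7mer-m8 > 7mer-A1.

**Simulator.** `sim_profile()` / `simulate_experiment()` generate reference
FASTAs, FASTQ reads (fragment + adapter + errors) and exact ground truth
under a single integer seed, for validation and benchmarking.

## Worked example

```r
library(srnapipe)

profile <- sim_profile(rng_seed = 42, n_reads = 20000)
refs <- simulate_references(profile)
ex <- simulate_experiment(
  profile,
  condition_effects = stats::setNames(4, refs$libraries$miRNA$ids[1]),
  refs = refs)

spec <- adapter_spec(profile$adapter)
cfg <- cascade_config(refs$libraries)
counts <- lapply(list(test = ex$test$reads, control = ex$control$reads),
                 function(rd) {
                   pp <- preprocess_reads(rd, spec)
                   cascade_annotate(collapse_reads(pp$reads), cfg)$counts
                 })
tab <- merge_sample_counts(counts)
de <- differential_expression(tab, "test", "control",
                              de_params(correction = "auto"))
de[de$call != "unchanged", c("feature_id", "norm_test", "norm_control",
                             "signed_fc", "p_value", "call")]
summary(de)[c("n_up", "n_down", "pct_unchanged", "correction_k")]
```

prints

```
      feature_id norm_test norm_control signed_fc      p_value call
1  sim-mirna-001       113           33  2.290323 1.678812e-11   up
97  sim-mrna-017        41           17  1.521739 2.207489e-03   up

$n_up
[1] 2
$n_down
[1] 0
$pct_unchanged
[1] 98.52941
$correction_k
[1] 29
```

The planted 4-fold miRNA is recovered (raw ratio 113/33 ≈ 3.4; the
automatic correction factor k = 29 damps the reported signed FC to 2.29,
still well past the 1.5 threshold). One low-count mRNA fragment sits right
at the calling boundary — at 20,000 reads per library that is the residual
false-positive behaviour the correction factor exists to suppress; without
it (`correction = NULL`) four additional low-count features at p ≈ 0.04
would be called. `corrected_fold_change(10, 5, 30)` reproduces the 1.14
damping example above.

A thin command-line wrapper is installed as `exec/smallrna`
(subcommands `simulate`, `trim`, `annotate`, `filter`, `fc`, `diffexp`,
`cluster`, `targets`, `run`; `run` takes a YAML config and writes all stage
outputs plus a log).

## Documentation

See the vignette `vignettes/smallrna-workflow.Rmd` for the underlying
models, the meaning and defaults of every tunable parameter, the design
decisions and the known limitations.
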