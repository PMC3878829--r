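---
title: "Small RNA-seq analysis with srnapipe: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA-seq analysis with srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

# Overview

srnapipe analyses single-end small RNA sequencing libraries: reads of
15-36 nt small non-coding RNAs (sncRNAs) — microRNAs, piwi-interacting
RNAs, tRNA/rRNA/mRNA fragments — sequenced through into the 3' ligation
adapter. The workflow is the classical one for this data type:

1. **Pre-processing** — error-tolerant 3' adapter cleavage, mean-quality
   filtering, and removal of reads shorter than 15 nt (too short to map
   unambiguously).
2. **Annotation cascade** — unique read sequences are matched against an
   ordered set of per-class reference libraries; the first library with a
   hit claims the read. miRNA-assigned reads are further classified as
   canonical or 5'/3'-shifted isomiRs.
3. **Count statistics** — minimum-count or percentile filters remove
   low-information features; an additive correction factor damps
   fold-changes of low-count features.
4. **Differential expression without replicates** — quantile
   normalization followed by a per-feature two-sided Fisher's exact test
   against the library totals, BH adjustment, and threshold calling.
   Sample-similarity clustering and PCA support multi-sample overviews.
5. **Target prediction** — 3'UTRs are scanned for canonical 8mer,
   7mer-m8 and 7mer-A1 seed-match sites of the (differentially
   expressed) miRNAs.

A seeded synthetic-data generator produces reference libraries, FASTQ
reads and ground truth so that every stage is testable without any
external download.

# Adapter trimming model

A 3' adapter occurrence is searched in every read as either (a) the full
adapter as an internal approximate substring, or (b) an adapter *prefix*
overlapping the read's 3' end. Errors are unit-cost edit operations
(substitutions and indels). A candidate with matched adapter length $L$
and $E$ errors is admissible iff $L \ge o$ (minimum overlap, default 3)
and $E \le \lfloor eL \rfloor$ with error rate $e$ (default 0.1). Among
admissible candidates the winner has the fewest errors, then the 5'-most
start, then the earliest adapter in the user's list; everything from the
match start to the 3' end is removed, and the quality string is truncated
in lockstep.

Numerical choices: the floor is computed as
$\lfloor eL + 10^{-9}\rfloor$ so that products such as $0.1 \times 30$,
which binary floating point represents fractionally below 3, round the
way the rational arithmetic intends. `N` bases never match anything.
With several admissible alignments of identical (errors, start, adapter)
the longest matched adapter length is reported; the trimmed read is the
same either way.

The implementation (a banded dynamic program in C++) is validated in the
test suite against a brute-force oracle that enumerates every
(start, matched-length, segment) candidate with `utils::adist`.

Quality filtering: the source method leaves the criterion open, so the
package uses the simplest monotone rule — keep a read iff its mean
Phred score is at least `min_quality` (default 20, inclusive). Filters
are applied in the order trim, length, quality, so degenerate (empty)
reads are counted as length discards; the report partition
`n_input = n_kept + n_short + n_low_quality` holds in every run.

# Annotation cascade and isomiRs

Mapping is substitution-only (Hamming): a read hits a reference entry if
it occurs as a substring with at most `m` mismatches (default 0 for the
short miRNA/piRNA references, 1 for the longer tRNA/rRNA/mRNA/other
references). Indel-tolerant mapping is deliberately omitted: it keeps the
mapper exactly checkable against a naive scan and keeps counts integral.
Within a library a read is counted once, at its best hit
(fewest mismatches, then library entry order, then leftmost offset) —
no fractional multi-mapping, so Fisher's test downstream sees integers.

The cascade order defaults to miRNA, tRNA, rRNA, mRNA, piRNA, other —
the order in which the classes are conventionally reported — and is fully
configurable. First-match semantics mean a read is never counted in two
classes, which is the standard mitigation for cross-mapping artifacts
(e.g. piRNA candidates that are really abundant miRNAs).

isomiR classification compares the mapped read's end positions with the
canonical mature region of its reference entry: exact sequence equality
is `canonical`; a differing 5' (only) end is `5p_shift`; a differing 3'
(only) end is `3p_shift`; anything else is `both_shift`. If the mature
entries carry no genomic flanks, only 3'-trimmed isomiRs are observable
(a 5'-extended read cannot map inside the entry); libraries may therefore
carry ±5 nt flanks with the mature region marked via `canonical_start` /
`canonical_end`. One edge case is resolved by the "otherwise" rule: a
read with both ends canonical but an internal mismatch (possible only
when `m > 0`) is not exactly equal to the mature sequence and is
classified `both_shift`.

# Count filtering and the correction factor

Two filters are provided: an inclusive minimum-count cutoff and a
nearest-rank percentile cutoff computed per sample on the *nonzero*
counts (a zero means "not detected", not "detected 0 times"; a flag
restores zero inclusion). A feature row is dropped only when it fails in
every sample. Both filters are idempotent.

The correction factor $k$ is the median of the nonzero counts pooled
over the samples being compared (even pool: mean of the middle two). The
corrected signed fold-change is

$$\mathrm{FC}(a,b) = \begin{cases} r & r \ge 1\\ -1/r & r < 1\end{cases},
\qquad r = \frac{a + k}{b + k}.$$

With $a=10$, $b=5$ and $k=30$ this yields 1.14 — below a 1.5 threshold —
whereas the uncorrected ratio is 2.0; for $a=4000$, $b=2000$ the
correction is immaterial (1.99). That is the point of the device: it
suppresses fold-changes that are only large because the counts are
small. $k$ is computed automatically but can be replaced by any
user-supplied value, or disabled. Fold-changes are kept at full precision
internally and rounded to 2 decimals only for reporting.

# Differential expression without replicates

With one library per condition, variance cannot be estimated per
feature; the package implements the standard digital-expression recipe:

1. Quantile-normalize the two count columns (rank-mean algorithm; ties
   within a column receive the mean of the rank means over the tied
   ranks). Normalization on two columns mainly removes depth and global
   distribution differences.
2. Round normalized counts to the nearest integer, half away from zero
   (half-to-even would bias at .5 boundaries).
3. For each feature, a two-sided Fisher's exact test on
   $[[a, N_t - a], [b, N_c - b]]$, where $N_t, N_c$ are the column
   totals — the feature against all other reads. The two-sided p sums
   all hypergeometric probabilities no more probable than the observed
   table (minimum-likelihood summation, with a $1+10^{-7}$ relative
   guard against floating-point near-ties, as in the standard
   implementations).
4. BH adjustment is always computed, but default calling uses the raw
   p (threshold 0.05) together with |FC| >= 1.5, because the raw-p
   convention is how the thresholds for this assay are usually quoted;
   `use_adjusted_p = TRUE` switches. Whether Fisher should see raw or
   normalized counts is equally a convention; normalized is the default
   (`normalize = FALSE` reverts), since normalization and the test are
   meant to act together.

Replicate-aware modelling (negative-binomial dispersion as in DESeq) is
intentionally out of scope; a count table produced by any external
replicate-aware tool can be merged at the mid-pipeline entry point.

Clustering uses $d = 1 - r$ (Pearson) between sample columns with
average linkage, so identical profiles merge at 0 and perfectly
anticorrelated ones sit at distance 2; PCA centres features and reports
per-component variance fractions.

# Seed-match target prediction

For a mature miRNA, the seed is nucleotides 2-8. The three canonical
site types on the mRNA sense strand are: 8mer = reverse complement of
nt 2-8 followed by A; 7mer-m8 = reverse complement of nt 2-8;
7mer-A1 = reverse complement of nt 2-7 followed by A. Every UTR position
is scanned (overlapping occurrences included); each locus is reported
once with the strongest applicable type (8mer > 7mer-m8 > 7mer-A1), so a
7mer-m8 coinciding with an 8mer start, or a 7mer-A1 inside an 8mer, is
absorbed. Coordinates are 0-based on the sense strand; no reverse-strand
scanning is implied. Context/conservation scoring and hybridization
energies are out of scope by design — the output is the deterministic
site inventory that such scores are built on.

# The synthetic-data generator

`sim_profile()` fixes the study conditions; all randomness flows from one
integer seed (sub-seeds are used for the test/control libraries of an
experiment), and the generator never touches the caller's RNG state.
Defaults, chosen once as a realistic desk-scale portrait of a
proliferating human cell-line library:

* class fractions miRNA 0.570, tRNA 0.004, rRNA 0.022, mRNA 0.096,
  piRNA 0.004; the remaining ~30% are uniform random background reads
  exercising the unassigned path (real libraries contain a comparable
  share of reads from genomic loci outside the annotation libraries);
* 60 miRNAs (20-24 nt, mode 22), 20 piRNAs (26-31 nt), 20 tRNAs
  (~75 nt), 4 rRNAs, 40 mRNAs; within-class abundances are log-normal
  with sdlog 1.5 (expression is strongly skewed in real libraries);
* reads are fragment + TruSeq small RNA 3' adapter, truncated to a fixed
  36 nt read length, with 0.5% per-base substitution errors and constant
  Q40 qualities; 10% of miRNA reads carry a 1-2 nt 3' trimming to
  produce isomiRs;
* 50,000 reads per library by default; tests use 2,000-200,000 depending
  on what they measure.

Generated miRNAs are rejection-sampled to keep every pair at least 3
mismatches apart (sliding Hamming), so cascade assignment is unambiguous
at the default mismatch budgets. Ground truth (per-read class/feature
and per-feature counts) matches the emitted FASTQ exactly; with error
rate 0 the full pipeline reproduces the true counts exactly, which the
tests assert.

What the generator does *not* emulate — and hence what green tests do
not certify about real data: realistic quality-score profiles, ligation
and PCR biases, non-templated 3' additions (A/U tailing), genomic
multi-mapping structure between classes, and real sequence composition.
It validates the algorithms, not the biology of any particular library.

In the two-condition recovery experiment used by the test suite, 10% of
miRNAs carry a true 4-fold change (alternating up/down). The perturbed
features are placed at evenly spaced quantiles (0.1-0.9) of the
abundance distribution — a stratified design that measures recovery
across the dynamic range rather than only at comfortable depths.
Detection there uses no correction factor: the correction is a
fold-change damper for low-count features and would by construction
suppress exactly the low-abundance end of the planted signal; it is
exercised separately where its damping behaviour is the thing under
test.

# Known limitations

* Hamming-only mapping cannot rescue reads with indel sequencing errors;
  at the default error model this loses a small, condition-balanced
  fraction of reads to "unassigned".
* Without flanked miRNA entries, 5'-shifted isomiRs are invisible.
* Fisher's exact test on two deep libraries is sensitive to tiny
  relative differences in very abundant features; the correction factor
  and fold-change threshold, not the p value, carry the biological
  relevance judgement there.
* The percentile filter assumes at least one nonzero count per sample
  and errors otherwise.

# A worked mini-analysis

```{r mini, eval = FALSE}
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
head(de[order(de$p_value), ])
summary(de)
```

The same analysis is available from a shell via the `exec/smallrna`
script (`smallrna simulate`, `smallrna trim`, `smallrna annotate`,
`smallrna diffexp`, `smallrna run --config config.yaml`).
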