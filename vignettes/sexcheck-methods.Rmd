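---
title: "Methods: gene-expression-based sex checks for sample-identity QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-expression-based sex checks for sample-identity QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexcheck)
```

## Model and assumptions

The package infers a "gene-based sex" per sample from three marker genes
whose expression is effectively binary with respect to genetic sex in
nearly all tissues: XIST (transcribed from the inactive X chromosome,
expressed in females), and the Y-linked KDM5D and RPS4Y1 (expressed in
males). On log2 microarray intensity scales the expressed state sits
several log2 units above the silent state, with tight within-sex bands, so
a mixed-sex dataset shows two well-separated clusters in marker space.

Assumptions the method relies on:

* the dataset contains both sexes (a single-sex dataset has no second
  cluster to find; the pipeline skips such datasets with a warning);
* marker probesets behave (hence the correlation pre-filter);
* sex-chromosome aneuploidies and XIST dysregulation (as in some cancers)
  are rare enough to treat as sources of *ambiguity*, not as separate
  classes.

Because only swaps that change apparent sex are visible, the mismatch rate
this method measures is a lower bound on the true sample mix-up rate.

## The procedure and its parameters

**Preprocessing** (`log2_quantile_normalize`). Values with a maximum above
`log_detect_threshold = 30` are treated as linear-scale and
log2-transformed (log2 intensities live roughly in [0, 16]; the threshold
only needs to sit between the two regimes, and is overridable). Quantile
normalization then forces every sample onto the mean empirical
distribution. Ties receive the mean of the rank-means they span; missing
values stay missing and are mapped around by interpolation of quantile
position. Normalization is applied to the full matrix before panel
extraction, so the marker values are normalized against the whole
distribution rather than against four probes.

**Probeset filter** (`filter_probesets`, `min_r = 0.3`). All pairwise
Pearson correlations across samples are computed once for the panel, and
exclusions applied simultaneously: a probeset is dropped when its mean
correlation with same-direction probesets falls below `min_r`, or its mean
correlation with opposite-direction probesets is above zero. In a
mixed-sex dataset a healthy marker probeset correlates near +1 with its
own direction and strongly negatively with the other, so the 0.3 cutoff is
undemanding for real signal while catching dead probesets (near-zero
correlations) and inverted ones; it tolerates small-sample noise. Pearson
on log2 values is the field's standard choice. Filtering is deliberately
non-iterative: exclusions are rare, and one simultaneous pass keeps the
procedure order-independent.

**Clustering and labeling** (`cluster_samples`, `label_clusters`).
Lloyd's k-means with k = 2, Euclidean distance, probesets as dimensions,
on unscaled log2 values — the between-sex difference is an absolute
effect, and rescaling probes would equalize informative and noisy
dimensions. Initialization: best of `restarts = 25` draws of two distinct
samples as starting centers, under a caller-fixed seed (the RNG state of
the session is saved and restored, so library calls do not perturb user
code). At this dimensionality (4–8 probes) and separation, 25 restarts
make the global optimum effectively deterministic. Labels come from a
per-probeset centroid vote (female_high probeset → its higher-centroid
cluster is female; male_high probeset → its lower one); ties abstain, a
tied overall vote is an error that flags the dataset rather than emitting
calls.

**Ambiguity gate** (`median_sex_score`, `call_sample_sex`).
`D = median(XIST values) − median(male-marker values)`, with KDM5D and
RPS4Y1 pooled into one median rather than averaged per gene — the pooled
reading treats the male markers as one evidence set and is robust when a
platform carries a single probeset per Y gene. A confident call requires
cluster and score to agree in sign; `D == 0` is ambiguous by the
conservative reading that female calls require strictly positive and male
calls strictly negative D. Samples with missing marker values are excluded
from clustering and forced ambiguous.

**Corpus accounting** (`compare_annotations`, `summarize_corpus`).
"Mismatch" requires a definite call *and* a definite annotation; unknown
annotations and ambiguous calls are "unclassified". Ambiguous samples
whose cluster assignment contradicts the annotation are surfaced as a
separate sub-count (`n_ambiguous_cluster_discrepant`) but never counted as
mismatches. A dataset is "correctly annotated" only with zero mismatched
and zero unclassified samples, which gives the inclusion–exclusion
identity `correct = total − (with_mismatch + with_unclassified − both)`.
Cancer/non-cancer strata are user-supplied labels; the package does not
infer disease context.

**Prevalence bounds** (`binomial_bound`). With k affected studies of n,
the bound inverts the binomial quantile function over a grid of candidate
proportions p (step 0.01, the whole-percent resolution at which such
bounds are reported): lower = largest p with `qbinom(level, n, p) ≤ k`,
upper = largest p with `qbinom(1 − level, n, p) ≤ k`. Both equal the
beta-quantile closed forms `qbeta(1 − level, k + 1, n − k)` and
`qbeta(level, k + 1, n − k)` floored to the grid — the upper is exactly
the Clopper–Pearson one-sided upper bound, and the lower is its k+1
variant, which the tests cross-check as an independent oracle. The lower
bound is capped at k/n: for very small k and n the raw grid answer can
exceed the point estimate, which no one-sided lower bound should. Coverage
of the 99% lower bound at p = 0.46, n = 70 is ≥ 99% by simulation.

**Cross-study concordance** (`cross_study_concordance`). Over studies
sharing subjects: mismatched everywhere it appears (≥ 2 studies) →
`consistent_metadata_error`; mismatched somewhere but not everywhere →
`study_specific_mixup`; seen once → `indeterminate`. A subject in ≥ 2
studies with no mismatch anywhere is reported as `no_discrepancy` — the
three-way scheme has no slot for the (typical) clean subject, and folding
it into `indeterminate` would conflate "no evidence" with "evidence of
nothing wrong".

## What the generator emulates — and what it does not

`generate_dataset` draws each sample's true sex Bernoulli(`p_female`),
marker values Normal(`mu_on` = 10 or `mu_off` = 5 per sex and direction,
`sigma` = 0.3) and sex-independent background probes at the silent level.
The defaults reproduce the ~5 log2-unit separation and tight within-sex
bands these markers show on Affymetrix arrays; at that
signal-to-noise the misclassification probability of a clean sample is
negligible (≈ 8 sigma), which is what makes exact planted-truth recovery a
meaningful test rather than a lucky one. A heavier-tailed noise option
(scaled Student t) exists but is off by default.

Planted defects:

* **Mislabels** flip the annotation only; expression follows the true sex.
  This is the tube-swap signature the detector targets.
* **Ambiguous samples** put every marker exactly at the midpoint
  `(mu_on + mu_off)/2`, giving D = 0 exactly. The choice is deliberate: a
  midpoint sample *with* noise has its cluster assignment and its score
  driven by the same noise vector, so the two always agree in sign and the
  disagreement gate never fires. The exact midpoint is the idealized
  "mixed RNA / dysregulated XIST" sample that the D == 0 rule catches
  deterministically. Real ambiguous samples are messier — intermediate on
  one axis only, or drifting between batches — and are *not* emulated.
* **Bad probeset**: one extra XIST-assigned probe at midpoint plus noise,
  independent of sex; its mean same-direction correlation is ≈ 0, which
  the filter excludes.

Not emulated: batch effects, probe-level (pre-summarization) structure,
platform-specific intensity distributions, sex-chromosome aneuploidies,
and missing-value patterns of real repositories. A green planted-truth
test therefore establishes the *logic* of the pipeline — swaps flagged,
clean samples untouched, midpoint samples gated out, defective probes
filtered — not its operating characteristics on borderline real data.

`generate_corpus` plants ≥ 1 mislabel in exactly `affected` of
`n_datasets` datasets, with per-dataset seeds derived from one corpus seed
(multiplicative-congruential step, kept inside 32-bit integer range), so
any single dataset can be regenerated without the rest.
`generate_cohort` fixes one subject roster across studies and plants
swaps (expression follows the wrong sex in one study) and metadata errors
(annotation wrong in all studies) in disjoint subject sets, so the
concordance classes are recoverable exactly.

## Numerical choices and degenerate inputs

* Quantile-normalization reference with missing values: per-column order
  statistics are linearly interpolated onto the common length-n grid;
  exact rank-mean behavior is recovered whenever a column is complete.
* k-means restarts that draw two coincident initial centers, or that end
  with an empty cluster, are discarded; if no restart yields a valid
  2-cluster solution (e.g. all samples identical) the dataset errors out
  as degenerate — the signature of a single-sex dataset.
* `D == 0` → ambiguous; equal centroid values abstain from the label
  vote; a fully tied vote is an error, not a coin flip.
* Bound grid includes 0 and 1; `k = 0` gives a lower bound of 0, `k = n`
  an upper bound of 1.
* Report sidecars use DCF (key: value) — structured, diff-able, parsed by
  base R.

## Known limitations

* Same-sex swaps are invisible; all rates are lower bounds.
* The shipped GPL96/GPL570 panels are the standard XIST/KDM5D/RPS4Y1
  probeset sets for those platforms; other platforms need a user config.
* The single-sex guard relies on the annotations: a dataset whose
  annotations claim one sex but whose samples are mixed is skipped rather
  than audited.
* With very few samples (< 3) the correlation filter cannot run and is
  skipped; with 2 samples k-means will "find" two clusters of one sample
  each, so calls on tiny datasets rest almost entirely on the D gate.
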