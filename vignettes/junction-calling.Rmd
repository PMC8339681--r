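---
title: "Statistical splice-junction calling: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical splice-junction calling: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sjcall)
```

## The problem

Spliced aligners report every alignment whose CIGAR contains an N operator as
evidence for a splice junction, but a large share of these junctional reads —
especially in droplet single-cell data — arise from repetitive genomic
sequence, reverse-transcription and PCR artifacts (stutter, template
switching) and mapping ambiguity rather than from real splicing. Fixed
read-count cutoffs cannot separate the two regimes because artifact rates
vary by sample, lane and chemistry. `sjcall` instead fits a statistical model
*per sample* and propagates read-level uncertainty up to a single per-junction
calling decision that is consistent across all samples of an individual.

## Stage 1: read-level model

Every retained spliced alignment (one record per N operator; for multimapping
reads only the lowest-HI alignment, so a read is counted once) is described
by features computable from the alignment alone:

| feature | meaning | direction for a true splice |
|---|---|---|
| `as_norm` | alignment score AS / read length | high |
| `nh` | number of reported alignments (NH) | low |
| `nmm` | mismatches (NM) | low |
| `overlap`, `max_overlap` | shorter / longer aligned overhang flanking the junction | balanced, long |
| `softclip_s` | total soft-clipped bases | low |
| `entropy` | 5-mer Shannon entropy of the read sequence | high |

Read entropy is `-sum f_i log f_i` over the distinct overlapping 5-mers,
where `f_i` is the k-mer's frequency among all `L - 4` positions, natural
log. Normalizing by the number of k-mer *positions* (rather than the number
of distinct k-mers) is required for the frequencies to form a probability
distribution; it makes a pure repeat score near 0 and a maximally complex
60-base read score `log(56) ≈ 4.03`.

Training labels are taken from genomic co-alignment: junctional reads that
*also* align contiguously somewhere in the genome are overwhelmingly
artifacts and form the negative class; junctional reads without such an
alignment form the positive class. Two properties make this workable:
labels are available in every sample without annotation, and co-alignment is
deliberately *excluded* from the predictors, so the labels do not leak into
the model. Each class is capped at 10,000 reads, sampled uniformly under the
run seed. The model is a lasso-penalized logistic regression
(`glmnet`, `alpha = 1`) on the features above plus the
`overlap × max_overlap` product, with the penalty chosen by 10-fold
cross-validated deviance on seeded folds; features are standardized on the
training set and the standardization is frozen for scoring. For paired-end
data the mate's copies of the same features are appended together with two
indicators of fragment compatibility (R1 forward / R2 reverse on the same
reference; leftmost positions within 1 Mb by default). The fitted model
yields `p_hat` for every junctional read, clipped to `[1e-6, 1 - 1e-6]`
because later stages work on log-odds.

The label noise is asymmetric by construction — a small fraction of true
reads co-align by homology, and some artifact reads have no contiguous
alignment — but as long as the mislabeled minority is small the fitted
direction is preserved; the test suite checks coefficient-sign recovery
against simulations with a known generative direction.

## Stage 2: junction-level evidence

Reads are collapsed by junction identity `(chrom, intron_start,
intron_end)` — 1-based first/last intronic base, the STAR `SJ.out.tab`
convention — and the read scores of a junction with N reads are combined as

```
P = prod(p_i) / (prod(p_i) + prod(1 - p_i))
  = 1 / (1 + exp(sum log((1 - p_i)/p_i)))
```

evaluated in the log-odds form. Because every factor is below one, `P`
mechanically shrinks with N, so `P` is calibrated against the score of N
reads resampled (with replacement, matching the iid assumption of the
large-N branch) from the sample's full read-score pool:

* `N <= 15`: empirical null of 10,000 resampled aggregated scores;
  `P_cum` is the fraction of null scores below the observed `P`, ties
  counted half (the mid-rank rule keeps degenerate pools unbiased at 0.5).
* `N > 15`: Gaussian null for the log-odds sum via the central limit
  theorem, `P_cum = 1 - pnorm((s - N*mu)/(sigma*sqrt(N)))`. A zero-variance
  pool degenerates to a sign rule. The boundary N = 15 itself is assigned to
  the exact small-sample branch; the suite checks the two regimes agree to
  within 0.05 across the boundary on a smooth pool.

`P_cum` is then converted to an empirical p-value against junctions that are
likely artifacts *at the junction level*: those with at least 10% of reads
genomically co-aligned. With M such junctions,
`emp_p = (#{artifact P_cum >= observed} + 1) / (M + 1)`; the add-one
smoothing avoids exact zeros that would dominate any downstream median. The
artifact set includes the scored junction itself when it qualifies — the
simplest consistent definition, with vanishing effect for moderate M. When
M < 50 the sample cannot support an empirical null and the method falls back
to `emp_p = 1 - P_cum` with a warning and an output flag.

## Stage 3: cohort combination

For each junction the empirical p-values are collected across the samples of
an individual, keeping only samples where the junction passes four filters
(each one alone is strong evidence of an artifact):

* fraction of reads with a genomic co-alignment `< 0.1`;
* at least two distinct alignment start offsets (an N = 1 junction can never
  satisfy this, so singletons are ineligible);
* mean longest homopolymer run `< 11` bases;
* mean read entropy `> 3` nats.

The calling score is the median of the eligible `emp_p` values (even counts:
mean of the two central values; no eligible sample: score 1 with a reason
flag). The median is robust to a junction looking spuriously good in one
sample, and as the number of samples grows it converges to the expectation,
giving a consistent multiple-testing control without per-test correction.
A junction is called when its score is strictly below the threshold
(default 0.15); calls are monotone in the threshold and identical everywhere
the junction is reported.

## The simulator: what it emulates, and what it does not

`sim_config()` / `simulate_sample()` generate SAM files with known junction
truth on a synthetic reference, reproducing the noise structure the caller
must reject: artifact-class reads are built from short repeat units (entropy
well below 3), multimap (NH uniform on 2–12), carry more mismatches
(Poisson mean 2 vs 0.3) and soft-clipping, and receive a contiguous decoy
alignment with probability 0.8 (vs 0.02 for true reads). True junctions
draw Poisson(24) reads and artifact junctions Poisson(10) (floor 2),
reflecting that expressed genes accumulate junctional coverage while
artifact loci stay shallow. Overhangs are uniform with a 10-base minimum;
AS is generated as `read_length - 2*nmm - softclip`, a STAR-like linear
penalty whose exact form is irrelevant to the model (only ordering matters)
but documented so tests are exact. Generation is a pure function of
(configuration, sample index): the junction layout depends only on the seed,
so all samples of a cohort share one truth.

The simulator deliberately does not model base-quality errors, UMI/barcode
structure, fragment-length distributions, real genome homology or chimeric
alignments. Passing the end-to-end suite therefore shows that the
statistical machinery separates the two read-generating regimes it targets;
it does not certify performance on any particular real dataset, where the
regimes overlap more and additional artifact modes exist.

## Numerical and design choices

* Probabilities are clipped at `1e-6` before any log-odds computation.
* All randomness (training subsample, CV folds, null resampling, simulation)
  derives from explicit integer seeds; reruns are byte-identical, and output
  tables are sorted by junction key with every threshold echoed in a
  commented header.
* Training sampling is per spliced record (a read spanning two junctions can
  contribute two records); the alternative, per read, changes little at
  realistic multi-junction rates.
* The Gaussian branch estimates `mu`, `sigma` from all scored reads of the
  sample, training and non-training alike.
* Validation problem sizes: cohorts of 2 samples with 50 true + 50 artifact
  junctions, 20 seeds for the discrimination study; 10,000 replicates per
  empirical null; 10-fold cross-validation — sizes at which every
  distributional quantity in the tests is stable.

## Limitations

* Samples with no genomically co-aligned junctional reads (or none without)
  are untrainable by design and are reported as errors rather than guessed.
* The artifact-null fallback (`M < 50`) makes `emp_p` a monotone transform
  of `P_cum` and should be treated as uncalibrated.
* Strand is annotation only (from XS when present): junction identity never
  includes it, matching effectively unstranded droplet chemistry.
* UMI deduplication is out of scope; per-cell counts are raw read counts.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_cohort(cfg, "fixtures")
rc <- run_config(seed = 7)
res <- lapply(sim$sams, run_sample, out_dir = "out", config = rc)
cohort <- run_cohort(lapply(res, `[[`, "junctions"), config = rc)
evaluate_calls(cohort, sim$junctions)
```
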