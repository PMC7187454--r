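---
title: "Chromatin-state dynamics: models, tests and design choices"
author: "chromstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state dynamics: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstates)
```

This vignette explains the statistical machinery of the package, the
assumptions behind it, what the synthetic-data generator does and does not
emulate, and the design decisions taken where reasonable alternatives
existed.

## The chromatin-state model

The central object is a hidden Markov model over genome bins. A
`genome_layout` fixes ordered chromosomes, lengths and a bin size
(default 200 bp, the resolution at which histone-mark ChIP-seq is
conventionally segmented). Each bin carries a binary vector of mark
calls; a hidden state per bin emits each mark independently with a
state-specific Bernoulli probability, and states follow a first-order
Markov chain that restarts from the initial distribution at every
chromosome, so chromosomes are independent chains sharing parameters.

Assumptions worth keeping in mind:

* **Conditional independence of marks given the state.** This is the
  standard product-Bernoulli emission of chromatin-state models. It is
  wrong in detail (marks co-occur beyond what states explain) but is
  exactly the model class the field's segmentations are built on, so
  recovered states are comparable to published ones.
* **First-order dynamics.** Domain lengths are geometric per state;
  real chromatin domains are heavier-tailed. The stickiness of the
  transition matrix controls mean segment length (self-transition 0.97
  gives ≈ 33 bins ≈ 6.6 kb).
* **Binarization upstream.** The model consumes 0/1 calls. The
  `poisson_binarize()` step tests each bin's count against a Poisson
  background whose mean comes from a depth-matched input control
  (control counts scaled so total control mass equals total signal
  mass) or, without a control, from the global mean signal. This is a
  deliberate simplification of multi-scale local-background schemes:
  global scaling only, documented and bit-reproducible. No peak
  calling, duplicate filtering or mappability correction is attempted.

### Estimation and numerics

Baum-Welch EM uses scaled forward-backward recursions: each position's
forward vector is normalized and the log-likelihood accumulated from the
scaling factors, so chains of 10^6 bins pose no underflow risk. Emission
likelihoods are additionally shifted by their per-bin maximum before
exponentiation. Emission estimates are clamped to [1e-8, 1 − 1e-8] and,
when scoring, to [1e-10, 1 − 1e-10]; degenerate 0/1 emission inputs are
therefore handled without infinities. Per-iteration log-likelihood is
non-decreasing (asserted in the tests with 1e-8 slack).

EM converges to local optima, and with rare states (a strong-enhancer
state occupying 2% of bins) a single initialization can merge states.
`fit_chromatin_hmm()` therefore uses short-run multi-start by default:
three candidate initializations (k-means seeding of emissions on a
random bin subsample plus jitter; sticky uniform transitions with 0.9
self-weight; uniform initial distribution) are each advanced 15 EM
iterations and the best by log-likelihood is run to convergence
(tolerance 1e-4 on the total log-likelihood, at most 200 iterations).
All draws derive from the `seed` argument, so fits are reproducible.
Viterbi ties are broken toward the smaller state index, making decoding
deterministic as well.

### Choosing the number of states

Published state maps are grown "until states stop separating", which is
qualitative. `select_state_count()` operationalizes it: for each
candidate K it fits a model and declares states unseparated when either
(a) two emission rows correlate above 0.95 (Pearson), i.e. the
vocabulary has begun duplicating, or (b) some state's stationary
occupancy falls below 1% — in practice EM parks surplus states as
near-empty states with arbitrary emission rows, which the correlation
score alone does not catch (we observed surplus-state correlations of
0.68–0.92 on data simulated from a well-separated 3-state truth). The
recommended K is the largest candidate passing both checks; both
thresholds are exposed as parameters.

### Semantic labels

`label_states()` applies thresholded rules in priority order to the
emission matrix: promoter (TssS) when H3K4me3 ≥ 0.5; strong enhancer
(EnhS) when H3K4me1 and H3K27ac are both ≥ 0.5 without promoter-level
H3K4me3; weak enhancer (EnhW) when only H3K4me1 is high; transcription
(Tx) on H3K36me3; Polycomb repression (ReprPC) on H3K27me3; quiescent
(Quies) when every emission is below 0.2; otherwise Mixed. Labels follow
the field's `<index>_<name>` convention and are compared
case-sensitively; functions that take state labels accept either the
full `"13_EnhS"` form or the bare `"EnhS"` suffix.

## Interval algebra and epigenome similarity

Interval sets are 0-based half-open, sorted, with merge/intersect/
coverage delegated to IRanges and verified in the tests against a
per-base-pair membership oracle. `merge_intervals()` coalesces abutting
intervals (end == next start): the semantics throughout are base-pair
coverage. The Jaccard index of two empty sets is defined as 0 rather
than NaN so downstream clustering stays finite; samples with an empty
state map get similarity 0 to everything *including themselves*, with a
warning, because an empty map carries no evidence of similarity.

"Similarity converted to Euclidean distance" is implemented as the
Euclidean distance between rows of the similarity matrix (each sample's
profile of similarities to all samples); the direct d = 1 − J metric is
available as an option. A consequence, asserted as a documented
property: two samples with identical similarity profiles have distance
0 even if their interval sets differ. Linkage defaults to average
(UPGMA) and is configurable; neither choice is claimed to reproduce any
particular published dendrogram, only the analysis pattern.

## Methylation integration

CpG tables use 1-based site coordinates, converted once at ingestion to
0-based points (`pos − 1`); everything downstream is 0-based half-open,
so off-by-one drift cannot accumulate. Sites on chromosomes absent from
the layout are flagged unassigned and excluded from tables, never
errors. The per-state summary reports, per state, the share of all
assigned CpGs and the share of significantly demethylated CpGs — the
two percentages whose contrast (rare state, large demethylation share)
is the enhancer-demethylation signal.

The independence test is a Pearson chi-square on the
states × {significant, not} table with a Monte Carlo permutation null:
significance flags are permuted across sites, which for a two-column
table is exactly fixed-margin resampling — the minimal-assumption
scheme. The p-value uses the add-one estimator
(1 + #{perm ≥ obs}) / (1 + n_perm), which is slightly conservative and
never exactly zero; its floor 1/(n_perm + 1) is attained in the planted
synthetic configuration. Significance flags are *inputs* here: the
package does not call differential methylation, and the hypomethylated
direction filter only affects flag counts, never site-state
assignments.

## Overlap and motif statistics

The hypergeometric upper tail is evaluated by log-sum-exp over
log-gamma terms, exact in the 10⁻⁹⁰ regime where naive summation
underflows; `log10_p` is reported alongside. Two tail conventions
exist in the wild: the inclusive tail P(X ≥ k) (the standard enrichment
convention and the default) and the strictly-greater tail P(X > k),
which is what `phyper(k, ..., lower.tail = FALSE)` yields without the
usual k − 1 shift and which some published analyses report. The
`strict` argument selects between them; the acceptance script computes
the published osteoarthritis-enhancer overlap under the convention its
printed value used. Region-overlap counts are per query interval
(counted once when total overlap with the merged reference reaches
`min_bp`, default 1), mirroring how published region counts are
phrased; base-pair-weighted analyses can use the interval algebra
directly.

PWM scanning scores every window on both strands with
log₂((p + pseudocount·bg) / bg) summed over positions; windows
containing N are skipped, and the default hit threshold is 60% of the
PWM's maximum achievable score (scan thresholds are rarely published;
the fraction is exposed). Enrichment between sequence classes uses the
sequence-level statistic — a sequence either has ≥ 1 hit or not —
tested one-sided by Fisher's exact test, the canonical statistic family
of relative motif enrichment tools; the odds ratio gets the Haldane 0.5
correction when a cell is empty. Internal consistency holds by
construction: the one-sided Fisher p equals the package's own
hypergeometric tail on the corresponding 2×2 margins, and the tests
assert it.

## What the synthetic generator emulates

`simulation_config()` bundles the reference study conditions:

* a 4 × 10 Mb toy genome at 200-bp bins (2 × 10⁵ bins) — large enough
  for parameter recovery, small enough for desk-scale runs;
* six states (TssS, EnhS, EnhW, Tx, ReprPC, Quies) over five marks,
  with genome-like occupancies (quiescent ≈ 63%, strong enhancers and
  promoters ≈ 2% each) obtained from a "restart" transition chain
  A = s·I + (1−s)·1πᵀ whose stationary distribution is exactly the
  target occupancy (s = 0.97);
* a condition-B-given-A flow matrix dominated by persistence, with
  quiescent/repressed chromatin feeding the strong-enhancer state at
  rates scaled so condition-B strong-enhancer occupancy stays near 2% —
  the regime in which a large share of demethylated CpGs concentrating
  there is a striking enrichment;
* CpG sites placed uniformly at 1 per kb with baseline beta values from
  the bimodal mixture 0.5·Beta(0.5, 5) + 0.5·Beta(5, 0.5) (methylation
  arrays are bimodal; this is a stand-in, not a fitted noise model),
  demethylation probability 0.35 in the strong-enhancer state versus
  0.01 elsewhere, and a beta drop of 0.3 (clamped) for flagged sites;
* enhancer sequences with a SOX9-like PWM — a near-degenerate tandem
  repeat of the AACAAT HMG-box half-site (12 bp, 0.94 consensus
  weight) — planted at per-sequence rates 0.6 (new) versus 0.1
  (constant);
* a two-group epigenome family sharing ≈ 80% of enhancer base pairs
  within groups and ≈ 5% between, built from non-overlapping block
  pools sized from those target Jaccard values.

One base seed fans out to fixed per-generator substreams, so
regenerating one output never perturbs another and identical seeds give
bit-identical artifacts (the demo writes an MD5 manifest to make this
checkable).

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: read-level noise and fragment-size
effects (binarization sees clean counts), mappability and copy-number
artifacts, correlated mark noise beyond state structure, probe design
and normalization artifacts of methylation arrays, CpG clustering in
islands, sequence composition bias, and cross-sample batch structure.
Recovery results on synthetic data demonstrate correctness of the
estimators under their assumed model, not robustness to everything real
ChIP-seq throws at them.

## Problem sizes used in validation

The shipped tests validate the recursions against exhaustive path
enumeration on instances up to 8 bins × 3 states (tolerance 1e-9);
parameter recovery on a 4-state, 5-mark truth at 2 × 10⁵ bins (emission
MAE ≤ 0.03, transition MAE ≤ 0.05 after optimal state matching; typical
values are ≈ 0.001); flow recovery at 10⁶ bins (MAE ≤ 0.01);
permutation-test calibration over 500 null replicates at 200
permutations; and 100-seed power checks for motif enrichment and
two-group clustering recovery. These sizes were chosen so the whole
suite runs in a few minutes on one CPU while leaving the statistical
margins wide.

## Known limitations

* Joint multi-sample training is supported only by concatenating
  samples as additional chains; there is no tied multi-cell-type mode.
* The binarization deliberately omits local background windows; on real
  data with strong coverage waves it will call broad regions more
  liberally than multi-scale schemes.
* `select_state_count()`'s separation criterion is a heuristic; for
  publication-grade state maps one would inspect emission heatmaps
  across a K range as well.
* The similarity module compares one state at a time; no multi-state
  joint distance is provided.
* Extremely long chromosomes (≫ 10⁷ bins) are limited by the dense
  per-bin representation in memory.
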