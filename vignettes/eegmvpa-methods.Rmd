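---
title: "Methods: time-resolved decodability, selectivity and representational flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved decodability, selectivity and representational flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery the package implements,
the assumptions behind it, and the design decisions taken where more than
one reasonable construction existed. It states no empirical result beyond
what the package's own tests compute.

## The data model

The analysis operates on epoched multichannel voltage data: an array of
`channels x timebins x trials` (microvolts) with a trial table linking
each trial to a stimulus design. The reference design crosses 4 object
categories (animal, car, face, plane) x 4 exemplars with 4 variation
dimensions (size, position, in-depth pose, lighting) at 3 levels each, one
variation manipulated per image: 192 unique images, i.e. 16 objects under
12 variation conditions. With three presentations per image a subject
contributes 576 trials. At the reference resolution, 1 kHz raw recordings
spanning -200 to +804 ms are averaged in non-overlapping 5-sample blocks,
giving 201 five-millisecond bins; each bin carries its center time. A
nominal -200..+800 ms epoch at 1 kHz holds 1001 samples, which 5 does not
divide; the package therefore defines the raw epoch as 1005 samples
(-200..+804 ms), the only span consistent with both the 5 ms binning and
the 201-bin geometry. The 31 analysis channels are a 32-channel 10-20
montage minus the right-mastoid reference.

## The decodability index

Separability of two condition clusters is summarized by a projection-based
d': the trial vectors of both clusters are projected onto the line joining
the two cluster means, and

$$d' = \frac{\mu_1 - \mu_2}{\sqrt{(\sigma_1^2 + \sigma_2^2)/2}},
\qquad \mu_1 > \mu_2,$$

with means and variances of the projected points and the higher-mean
cluster labelled 1, so $d' \ge 0$. Sample variances ($n-1$) are used: the
estimator choice is not dictated by the statistic itself, and $n-1$ keeps
tiny clusters (n = 2) well-defined and matches common practice. Two
degenerate cases are handled explicitly: identical cluster means give no
projection direction and return 0 (this is the information-free limit and
occurs in permutation nulls); distinct means with zero projected variance
in both clusters raise an error, since separability is then unbounded and
the input data are degenerate. The statistic is invariant to rotation,
translation and positive scaling of the feature space, and reduces to the
classic univariate sensitivity index in one dimension; both properties are
asserted in the test suite. Unlike accuracy-based classifiers it needs no
training/test split and is robust to unequal cluster sizes.

Two clustering schemes are provided. *Pooled* clusters take every trial of
a condition regardless of the other design dimensions, so category
clusters mix all variation conditions (and vice versa); category and
variation information can then leak into each other. *Per-condition*
computes d' separately inside each stratum that holds the other dimension
fixed — each of the 12 variation conditions for category contrasts, each
of the 16 objects for variation contrasts — and averages the strata
unweighted (the design is balanced by construction, so weighting would
only matter after trial rejection; strata reduced below 2 trials per
cluster are skipped with a warning). Pair-averaged curves are pointwise
means over all condition pairs; a single condition's curve averages the
three pairs involving it.

Baseline correction subtracts the mean d' over the last 200 ms before
stimulus onset from the whole curve, per subject and per curve. Because d'
of finite noisy clusters is positively biased, this recenters the
pre-stimulus level at zero and makes post-stimulus elevations
interpretable.

## Group statistics

Significance against baseline uses each subject's *uncorrected* curve: the
per-subject reference is the mean over the baseline window, and each
post-stimulus bin is tested across subjects with a two-sided Wilcoxon
signed-rank test of the differences (two-sided because the procedure is
also applied to quantities, like sliding correlations, that can move in
either direction; the test is exact for small samples without ties, and a
bin where every difference is zero gets p = 1). The per-bin p-values are
FDR-corrected across tested bins, Benjamini-Hochberg by default. A
Storey-style positive-FDR variant (pi0 estimated at lambda = 0.5, then
pi0-scaled step-up) is available because a widely used MATLAB
implementation defaults to it; it is never more conservative than BH, and
results can differ slightly between the two.

Latency is the first post-stimulus bin whose q-value clears alpha = 0.05
(reported missing when none does), with no run-length requirement; the
peak is the argmax of the group-mean curve over post-stimulus bins, ties
broken to the earliest bin. Single-bin latency is deliberately simple and
is therefore vulnerable to isolated false positives when many truly
significant bins raise the FDR threshold — a property, not a bug, of the
definition; the calibration and recovery simulations in the test suite
quantify it under the generator's conditions.

Sliding correlations between two curves use a trailing 50 ms window (10
bins) ending at each bin — trailing so no future samples enter. Windows
with zero variance are undefined. With per-subject input the correlation
is computed per subject and group-tested per bin with the signed-rank
procedure; with plain vectors the per-window correlation-test p-value is
used.

## Information selectivity

An *aspect* is one decodable distinction taken one-vs-rest: a category
against the other three (mean of its three pairwise curves) or one level
of a variation dimension against the other two (mean of its two pairwise
curves) — 16 aspects in the reference design. One-vs-rest was chosen over
pure pairwise aspects because the index asks "which electrodes carry
information about X", and the rest-average is the natural electrode
profile of X; aspect vectors use pooled univariate d' per electrode so all
eligible trials stabilize each 31-dimensional vector. The selectivity
matrix is the Pearson correlation of all aspect-vector pairs at one time
point, and the selectivity index is the mean within-dimension off-diagonal
correlation minus the mean between-dimension correlation (range [-2, 2]).
Correlation across electrodes is not invariant to per-electrode baseline
shifts, so both raw (default) and baseline-corrected aspect vectors can be
requested.

## Representational flow

Information transfer between the 9 peri-occipital (P3, P4, P7, P8, PZ,
POZ, O1, O2, OZ) and 9 peri-frontal (F3, F4, F7, F8, FZ, AFZ, FP1, FP2,
FPZ) electrodes is measured on representational geometry rather than raw
signals. At each bin, the similarity matrix of a stimulus subset (16
objects x 3 presentations = 48 trials of one variation condition) holds
Pearson correlations between the 9-dimensional response vectors of all
trial pairs; single presentations are used, not repetition averages, which
is what makes the matrix 48 x 48. Only the lower triangle (1128 entries)
enters further computation. With $SM_{loc,t}$ the vectorized matrix of
region *loc* at bin *t* and $SM_{loc,t-past}$ its entry-wise average over
t-130..t-80 ms (11 bins, inclusive), the flow curves are first-order
partial correlations

$$FF(t) = \rho_{\,SM_{front,t}\;SM_{back,t-past}\;\cdot\;SM_{front,t-past}},
\qquad
FB(t) = \rho_{\,SM_{back,t}\;SM_{front,t-past}\;\cdot\;SM_{back,t-past}}.$$

FF > 0 means the posterior past predicts the current anterior geometry
beyond the anterior past — a simplified Granger causality with a fixed
one-window lag. The past window makes FF and FB exactly exchangeable
under swapping the two regions, which the tests assert. Flows are
computed per subject and averaged; curves start at the first bin whose
full past window is inside the epoch.

Significance comes from a permutation null: per bin, the vectorized
entries of the *time-t* matrix alone are shuffled (the tested dependence
is destroyed while the conditioning structure is preserved; shuffling all
three matrices is a config alternative), the partial correlation is
recomputed, and the observed value must exceed the 95th percentile of the
shuffled values (rank 950 of 1000 at the default). Shuffles are applied to
the vectorized triangle, not the symmetric matrix, matching what enters
the correlation. For group curves each permutation index averages one
independent shuffle per subject, giving a null for the group mean.
Operational "stage boundaries" are reported as maximal runs of bins where
the FF-FB difference is significant with one sign.

## The synthetic generator

Because the recordings the analysis was designed for are not publicly
distributable, the package generates synthetic epoched data with known
ground truth. Noise is AR(1) per channel at the raw rate (innovation SD
`noise_sd`, coefficient `ar_coeff`, stationary start), optionally plus a
shared AR(1) component across channels; autocorrelated noise matters
because white noise would make the permutation and baseline procedures
trivially calibrated. Effects are planted as
`amplitude x spatial_pattern x k(t)` on every matching trial, where
`k(t)` is a raised-cosine (Hann) bump peaking at `onset_ms` with compact
support `onset_ms +/- width_ms`. Compact support was chosen over a
Gaussian so the evoked difference is exactly zero outside the window and
detection latencies have unambiguous ground truth (a Gaussian's tails
would make "the effect starts here" ill-defined). An optional `lag_ms`
adds a second copy of the bump on a second spatial pattern at
`onset_ms + lag_ms`, which is how posterior-to-frontal propagation is
emulated for flow-direction experiments. Spatial presets "occipital",
"frontal" and "global" map onto the electrode groupings above.

Default conditions mirror the reference recording: 10 subjects, 31
channels, 1 kHz raw rate, 576 trials, innovation SD 1 microvolt and
`ar_coeff = 0.95` at 1 kHz (about 20 ms correlation time, a realistic
scalp-EEG value). Simulation-heavy validations run at 200 Hz (one raw
sample per 5 ms bin, with `ar_coeff = 0.77`, the 1 kHz value compounded
over 5 samples), on design subsets (two categories for null calibration,
one variation condition for flow runs) and single presentations; these
reduced problem sizes — stated in each test — change none of the analysis
geometry. What the generator does *not* emulate: volume-conduction mixing
beyond the optional shared component, non-stationary alpha rhythms, eye
or muscle artifacts, inter-subject topography differences, and overlapping
responses from consecutive stimuli. Passing recovery tests therefore
show the estimators are correct and calibrated under plausible
autocorrelated noise, not that real recordings meet their assumptions.

## Numerical choices and limitations

* Ties in peak finding go to the earliest bin; latency needs exactly one
  significant bin.
* The permutation threshold uses the order statistic at
  `ceiling(0.95 * n_perm)`, so "significant" means strictly exceeding at
  least 95% of the null draws.
* Zero-variance representations, aspect vectors or windows yield NA with
  a warning rather than silently propagating.
* Seeds: every stochastic operation takes an explicit integer seed;
  per-subject streams fold the subject id into the seed so group datasets
  are reproducible subject-by-subject. All derived seeds stay below
  2^31 - 1.
* The layer-profile module applies the identical d' code path to
  arbitrary feature matrices; a scheduled synthetic cascade stands in for
  a real hierarchical model and is labelled synthetic throughout. Real
  model activations, image rendering and recording preprocessing
  (filtering, ICA) are out of scope.
* The package provides functions, not a shell executable: the analysis
  surface (`run_pipeline()` plus the per-stage functions) is the intended
  interface for R users, and `scripts/acceptance.R` shows the scripted
  entry point.
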