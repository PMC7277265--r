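---
title: "Methods: decoding, informational connectivity and encoding of ROI fMRI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding, informational connectivity and encoding of ROI fMRI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roimvpa)
```

This vignette is the package's own account of the analyses it
implements: the models and their assumptions, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The experimental design being modelled

The pipeline targets event-related word-processing experiments: in each
of 8 runs a participant sees 36 words (18 living, 18 non-living, one
trial per word) and, depending on the run's condition, either mentally
simulates the word's referent ("deep" processing) or covertly reads it
("shallow"). A trial is fixation (250 ms), blank (500 ms), the word
(1 s) with a 4 s post-onset delay, and a jittered inter-trial interval
drawn from a pseudo-exponential distribution on 6–8 s in 0.5 s steps
with probabilities 50%, 25%, 12.5%, 6.25%, 6.25% (the two tail masses
split the residual so the distribution sums to one within the stated
range). Volumes arrive every 0.85 s (TR), 520 per run, the first 9
discarded for steady-state magnetization. Up to two catch trials
showing number words are inserted per run; they are flagged and excluded
from analysis.

**Trial spacing.** Successive word onsets are separated by
`fixation + blank + delay + jitter` = 10.75–12.75 s, i.e. the word's
1 s display overlaps the start of the delay period. This is the only
reading of the design under which 36–38 trials fit inside a
520 × 0.85 s = 442 s run; spacing that additionally summed the word
duration would overrun the scan in essentially every run. Because the
jittered schedule length is still stochastic, `generate_schedule()`
rejection-samples: a drawn schedule whose last trial does not complete
within the usable scan time is redrawn (bounded retries); a design that
cannot fit at all fails every draw and raises a configuration error
naming the run.

## Preprocessing

Invariant voxels (zero variance within a run) are removed first; the
default scope is *per run* (a voxel invariant in any run is dropped from
all runs), with a `stacked` alternative, because z-scoring a constant
series is undefined and a voxel dead in one run is untrustworthy in the
others. Each voxel is then run-wise linearly detrended and z-scored, in
that order: scaling after detrending is what makes the output satisfy
the unit-variance contract exactly (mean 0 ± 1e-10, sd 1 ± 1e-10 per
voxel per run). A voxel whose residual variance is zero after
detrending (e.g. a pure trend) is set to all zeros and reported, never
silently rescaled.

Trial examples account for haemodynamic lag: the example window is the
first six volumes acquired at or after onset + 3.4 s (3.4–8.6 s; at
TR 0.85 s the closed interval would contain seven grid points, so the
six-volume count is taken as the defining property), and the classifier
feature vector is the mean of the volumes acquired no later than
onset + 6.8 s — five volumes at this TR. Both the five-volume mean and
the full six-volume stack are exposed (`feature_window = "sub"/"full"`),
since different analyses may want either. Onsets are interpreted on the
post-discard grid (volume k at time k·TR); a shift argument covers
events recorded on the pre-discard clock. Trials whose window runs past
the end of the run are dropped and reported rather than raised as
errors.

## Decoding model

Per cross-validation split, PCA is fitted on the training examples with
as many components as training examples (capped at the voxel count).
Since no component is discarded this is an information-lossless change
of coordinates into the subspace spanned by the training data — a test
verifies that decoding with and without the rotation agrees within
Monte-Carlo error — and it equalizes the dimensionality across ROIs of
different sizes. The classifier is a linear max-margin (soft-margin
support-vector) rule with l2 penalty, C = 1.0 and tolerance 1e-4, via
libsvm (`e1071::svm`, linear kernel, no rescaling); the implementation
variant beyond those constants is recorded in the result object's
`classifier` field.

Split schemes:

* `make_stratified_splits()`: per-class test count
  `round(n_class × 0.2)` with ties broken toward the smaller test set
  (144 per class gives 29 + 29 test trials); both sides of the split are
  class-balanced, the stricter reading of "balanced".
* `make_run_splits()`: leave-one-run-out; with few runs the estimate is
  unstable and the function warns below six folds.
* `make_word_pair_splits()`: one split per (living, non-living) word
  pair, all 324 by default (`n_pairs` subsamples for speed); held-out
  words never appear in training, so accuracy measures category-level
  generalization rather than word memorization.

Group-level inference: one-sample t against 0.5 per ROI within each
condition, and paired deep−shallow t per ROI; each family is
FDR-corrected separately (Benjamini–Hochberg at q = 0.05 by default,
Benjamini–Yekutieli by flag).

**A calibration fact worth knowing.** On signal-free data the pipeline
is calibrated (grand-mean accuracy 0.50) when trials are pooled across
all 8 runs. Decoding a single 4-run condition with within-run random
splits shows a small positive bias (~ +0.01 in our simulations): run-wise
z-scoring forces each voxel's run mean toward zero, anti-correlating
same-run trials, and a held-out trial is anti-correlated with slightly
more other-class than same-class training trials. This is a property of
within-run cross-validation after run-wise normalization, not of the
simulator; leave-one-run-out does not suffer from it. The package's
chance-calibration check therefore pools runs, matching its definition.

## Informational connectivity

For each trial in turn, the classifier is trained on the individual
volumes inside all remaining trials' 3.4–6.8 s windows (each volume a
sample labelled with its trial's category, PCA as in decoding) and
applied to every volume of the left-out trial, recording the estimated
probability of the trial's true category. Concatenated in volume order
this gives a per-ROI discriminability time series; informational
connectivity is the Pearson correlation between ROIs' series, computed
separately per condition from that condition's runs only. Volumes before
the first trial onset belong to no trial and are excluded.

The linear classifier has no native probabilities. The default is
Platt-style calibration — a logistic regression of training labels on
training decision values, applied to test decision values — with a plain
`1/(1+exp(-dv))` sigmoid as the alternative mode; the mode travels with
the result. On separable training data the logistic fit diverges toward
a step function; probabilities remain valid and near 0/1, so the
divergence warning is suppressed deliberately.

The functional-connectivity control replaces pattern discriminability
with the ROI-mean BOLD time course. Because the simulator's planted
patterns are zero-mean across voxels, gating fluctuations leave ROI
means untouched: a gating-coupled ROI pair shows an IC condition
contrast but no FC contrast, and the suite verifies this dissociation.

The permutation effect size shuffles one series (default 10,000 times;
fewer than 100 warns), re-correlates, and reports
`(r_true − mean(null)) / var(null)`. Division by the *variance* is the
stated formula and the default; `use_sd = TRUE` gives the conventionally
scaled variant. Because the null is built by exchangeability, the
statistic does not depend on the absolute discriminability level — but
note that two ROIs recorded in the *same* session share trial timing and
labels, so their probability series share an event-locked envelope and
are genuinely non-null even without gating coupling. Calibration of the
statistic is therefore checked on series from independently simulated
sessions (no shared trial structure), where effects fall within null
bounds at any planted accuracy level; within-session uncoupled pairs
keep a stable positive baseline whose *sign* does not change with
accuracy.

## Encoding model

Word-level feature vectors are expanded to trials, standardized per fold
using training-row means and standard deviations (scoping the moments to
the training rows avoids test-set leakage; the alternative was
unscoped), and mapped to voxel responses by the closed-form ridge
solution `(XᵀX + αI)⁻¹XᵀY` with α = 100, targets centred on training
means. Per-voxel variance explained on the held-out rows is the
coefficient of determination around the test-sample mean (matching the
convention in which the best score is 1 and worse-than-mean predictions
go negative), averaged over folds (default 300 stratified 80–20 folds;
category labels are used only to stratify, never in fitting). Voxels
with positive average VE form the reported set; the headline aggregate
is their mean, with the mean over all voxels also reported, since the
choice of voxel set for averaging was open. The empirical chance level
reruns the identical pipeline with training-fold feature rows shuffled
against intact targets.

The ridge penalty interacts with the design's spectrum: with 36 unique
word rows in a 300-dimensional feature space the design matrix's nonzero
eigenvalues are large relative to α = 100, so a noiseless planted linear
map is recovered with aggregate VE above 0.9 (shrinkage costs a few
percent); with many dimensions but few, noisy trials the same α shrinks
much harder. Fold-wise predictions are verified against the closed form
to 1e-8.

RDMs mean-centre each word vector across words and use correlation
distance (1 − Pearson r) by default, cosine by option; zero-variance
word vectors yield flagged NA entries, never silent zeros. Model
comparison runs within-family one-way ANOVAs (FDR over ROIs within
condition), all vision−embedding pairwise one-sample t-tests against
zero (FDR), deep-vs-shallow paired contrasts of the mean family
difference (FDR), and percentile bootstrap 95% CIs of mean VE over
1,000 iterations.

## The simulator: what it emulates, and what it does not

Each ROI×run BOLD matrix is
`baseline + linear drift + low-frequency cosine drift + white Gaussian
noise + HRF-convolved trial signal`, the HRF a canonical double-gamma
(peak 6 s, undershoot 16 s, ratio 1/6) sampled on the TR grid and the
trial signal
`gating × (condition gain × category pattern + word gain × word pattern)`.
Patterns are zero-mean unit-norm voxel vectors, so pattern information
and ROI-mean signal are decoupled by construction. Gating is a per-trial
multiplier in [0, 1] obtained by a Gaussian copula; for a coupled ROI
pair the latent correlation is `2·sin(πs/6)`, the value whose
pushed-forward Pearson correlation between the uniform gating series is
exactly the configured strength `s` (strength 1 gives identical series).
A coupling may be restricted to runs of one condition, which is how a
deep-only information-sharing effect is planted. The generator returns
the full ground truth (patterns, gating, couplings) for recovery tests.

Deliberately *not* modelled: spatial autocorrelation and smoothing,
physiological (cardiac/respiratory) noise, motion, multi-subject
anatomical variability, and surface anatomy — the package consumes
already-preprocessed, ROI-extracted data, and the simulator emulates the
output of such a chain, not the scanner. Consequently, passing tests
show that the *analysis chain* recovers what was planted under its own
assumptions; they cannot certify behaviour under realistic spatial or
temporal noise structure.

Default amplitudes were chosen once, as plausible magnitudes on the
z-scored scale: noise sd 1 (the natural unit), category gain 1 deep /
0.3 shallow (a strong but not saturating condition effect), word gain
0.5, drift amplitude 0.5 so detrending and z-scoring are genuinely
exercised.

## Validation-study conditions

The package's acceptance suite runs five simulated experiments whose
parameters were fixed by power analysis at design time:

* *Chance calibration*: 20 subjects, full default design, all gains 0,
  noise sd 1, one 50-voxel ROI, 50 stratified splits over the pooled
  288 trials; grand mean within 0.50 ± 0.01.
* *Generalization dissociation*: word gain 0.6, category gains 0,
  30 voxels, 8 runs; word-specific signal drives in-sample decoding
  (mean ≈ 0.59) while word-pair generalization stays within
  [0.48, 0.52] — the per-simulation spread of the word-pair estimate is
  dominated by the draw of the 36 word patterns (effective n is the word
  count, not the trial count), which is why the band is checked on the
  mean of 20 simulations.
* *IC recovery / FC invariance*: 10 subjects, 3 ROIs of 12 voxels,
  4 runs × 24 trials, category gain 2.5 (moderate, so probabilities do
  not saturate and gating fluctuations survive into the series),
  coupling 0.8 planted deep-only for one pair.
* *Permutation-effect calibration*: gains 1 and 2, coupled
  within-session pair versus cross-session pairs, 1,000 permutations.
* *Encoding recovery*: 36 words × 300 dimensions, 20 voxels, 288
  trials, α = 100, 50 folds, noiseless linear map (VE > 0.9, max ≤ 1),
  null targets (mean VE ≤ 0), shuffled-feature chance (≤ 0), and exact
  agreement with the closed-form ridge on 10-trial instances.

Problem sizes throughout (50 folds instead of 300, 10–20 simulated
subjects, reduced ROI sizes) are the package's chosen validation scale:
large enough for the planted effects to be decisive under the power
analysis above, small enough to run routinely.

## Known limitations

* The discriminability series inherits an event-locked envelope shared
  by all ROIs of a session; raw IC values are therefore positively
  offset, and only condition contrasts (or cross-session comparisons)
  are interpretable as coupling evidence. This mirrors real data, where
  all ROI pairs show positive IC.
* Platt calibration on small, separable training sets is effectively a
  step function; the sigmoid mode gives smoother series at the cost of
  uncalibrated scale.
* The ridge α is fixed (no cross-validated search, by design); results
  at very different trial/dimension ratios are not comparable across α.
* Leave-one-run-out decoding with four runs per condition is unstable;
  the function warns, and the repeated-split scheme is preferred.
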