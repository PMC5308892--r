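---
title: "Methods: ensemble selectivity analysis for dual trace eyeblink conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble selectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In dual trace eyeblink conditioning a rat learns, in the same daily
session, two associations that share a *relational* structure (a
conditioned stimulus predicts eyelid stimulation across a 500 ms
stimulus-free trace interval) but differ in a *physical* feature (the CS
is an auditory tone in one epoch and a blinking light in the other).
Each 100-trial epoch opens with 20 CS-alone trials followed by 80 CS-US
paired trials, so a trial's position in the block carries its pairing
status. The analytical question is how prefrontal population activity
weights these two stimulus dimensions as learning proceeds and
consolidates: does the ensemble keep coding the sensory identity of the
CS, or does it come to emphasize the abstract CS-US relationship shared
by both memories?

`ensemblecode` implements the complete analysis chain for this question:
conditioned-response (CR) scoring from eyelid EMG, segmentation of
training days into learning stages, population-vector similarity with
permutation inference, support-vector-machine population decoding
calibrated against label-shuffled chance, and single-neuron selectivity
statistics. Because the underlying recordings are not publicly
deposited, the package also ships a synthetic-data generator that
emulates the trial structure and the neural coding classes the analyses
assume; every statistical procedure in the package is validated against
this generator.

## Behavioral scoring

The instantaneous EMG amplitude is the magnitude of the analytic signal
(the FFT construction of the Hilbert transform). Per trial, three window
means of this envelope are taken: the **Pre-Value** over the 300 ms
immediately before CS onset, the **CR-Value** over the 200 ms
immediately before US onset, and a pre-CS-phase control value over a
200 ms window centered 0.9 s before CS onset, fixed here to
[-1000, -800) ms since only the center is conventionally stated. The
session **Threshold** is the mean Pre-Value across trials plus two
standard deviations. A trial contains a CR iff its CR-Value exceeds both
its own Pre-Value and the Threshold; a trial whose Pre-Value exceeds the
Threshold is *hyperactive* (grooming, teeth grinding) and is excluded
from CR% denominators. Threshold estimation is single-pass: it pools all
trials of the session, including those later flagged hyperactive.
Iterative re-thresholding would create a circular dependency between the
threshold and the trials it excludes; with hyperactive rates around 5%
the difference is negligible and the single pass keeps the estimator
simple and reproducible.

Days are segmented into five stages from the daily CR% on paired trials:
**Before learning** covers the days preceding the first day at or above
30% CR; the first two consecutive days at or above 60% close the
**Learning** stage (the two trigger days themselves remain Learning —
the post-learning weeks begin on the day *following* the trigger pair);
**Post 1W/2W/3W** are the subsequent 7-day blocks, and days beyond the
third week are excluded. CS-alone trials are not used for staging: CR
expression on unpaired trials stays at the detector's false-positive
floor throughout training, so including them would only dilute the
criterion. If the 60% criterion is never met, all non-Before days are
labeled Learning and a warning is recorded rather than guessing an
asymptote.

## Firing-rate tensors

Unit quality control requires fewer than 1% of inter-spike intervals
inside a 2 ms refractory period and strictly more than 1500 spikes per
session (read literally from "more than 1500"). Rates are binned into
half-open `[a, b)` windows aligned to CS onset — a spike exactly on a
bin edge belongs to the right-hand bin, and the convention is applied
uniformly because no edge rule is conventionally fixed. Three
normalizations are provided: raw Hz; division by the unit's maximum
across the four *condition-mean* rate matrices (display-matrix
normalization; single-trial maxima are used only inside the decoder,
which normalizes by the unit's maximum over its 80 sampled trials); and
standard scores against the mean and SD of the 1 s pre-CS baseline
pooled over trials. Silent or zero-variance units are emitted as
all-zero with a warning instead of being dropped, keeping tensor shapes
stable across analyses.

## Population-vector similarity

Per 50 ms bin, the Pearson correlation across units is computed between
condition-mean population vectors of the relational pair (ACS-US vs
VCS-US) and the physical pair (ACS-US vs ACS-alone). The difference of
the two correlations is tested by randomly re-assigning the pooled
trials of the involved conditions to conditions (relative counts
preserved) in one shared re-labeling per permutation, recomputing both
correlations and their difference 1000 times, and locating the observed
difference in the permutation distribution with the `(b+1)/(n+1)`
convention, so p-values are never exactly zero. The re-labeling is
shared between the two pairs deliberately: both observed correlations
contain the same ACS-US condition mean, and a null that shuffles the
pairs independently destroys that dependence, inflates the null
variance of the difference, and makes the test conservative (about half
the nominal size in calibration runs). Significance uses α = 0.05/10 split equally
across the two tails, Bonferroni-adjusted for the ten bins covering
0-500 ms after CS onset. A literal reading of the printed tail
probability for this test ("0.0025%") is unreachable with 1000
permutations; it is treated as 0.25% per tail (0.05/10/2), which is the
only resolution-consistent interpretation. Max-normalization constants
are computed once from the observed data and held fixed during
permutation, the conventional choice for permutation inference on
normalized data. Trial-by-trial structure is examined by correlating
every trial's trace-interval population vector with a template averaged
over the 10th-80th ACS-US paired trials; template-member trials are
included in the comparison (a leave-one-out variant is available but
off by default). The confidence band is a Fisher-z interval over units
by default, with a unit-bootstrap alternative — the original band
construction is not stated, so both are offered and the output records
which was used.

## Population decoding

One decoding run samples 20 trials per condition without replacement,
divides each unit's rates by its maximum over the 80 sampled trials (a
unit silent in all sampled trials contributes zeros), splits each
condition 10/10 into train and test halves, selects RBF-kernel SVM
hyperparameters by grid search with 5-fold cross-validation on the
training half, refits, and scores the held-out 40 trials. The default
grid is the standard libsvm practice grid (cost 2^-5..2^15, gamma
2^-15..2^3, steps of 2 in the exponent); ties break toward the smallest
cost, then the smallest gamma, for reproducibility. Chance is calibrated
by repeating the identical procedure 50 times with labels randomly
re-assigned, each repetition scoring its 40 held-out readouts; the
cutoff is the 95th percentile of the 50 repetition accuracies.
Because the construction of the pooled 2000-readout chance distribution
admits two readings, the pooled-readout variant (binomial on the pooled
Bernoulli rate) is also computed and reported alongside; the
per-repetition percentile is the default. **Relative accuracy** is raw
accuracy minus this cutoff. Stage comparisons run 20 sets of 150 units
sampled from the stage's pool, assembling pseudo-populations by
re-pairing trials uniformly at random within condition per unit (units
recorded in different sessions carry no usable noise correlations, so
none are modeled). Binary relational (alone vs paired) and physical
(auditory vs visual) decoders are trained after collapsing labels;
trials are still sampled per original four-way condition so the
collapsed classes stay balanced across modalities.

## Single-neuron selectivity

The magnitude of differential firing between two condition groups is
the differentiation index `(Fr1 - Fr2)/(Fr1 + Fr2)` on mean
trace-interval rates, used downstream as `|index|`. Its consistency is
the plug-in mutual information between condition and the trial firing
rate discretized into 10 equal-width bins over the neuron's observed
rate range (right-closed last bin); MI is reported in bits — the base
cancels from both the normalized value and the permutation p-value.
Significance comes from 1000 label permutations with the upper-tail
`(b+1)/(n+1)` p-value; the normalized statistic is the observed value
minus the null mean over the null SD. Trial-count imbalance (20 alone
vs 80 paired) is left as-is: permutations preserve group sizes, so the
null absorbs the imbalance without subsampling. Responsiveness is a
permutation test of the CS + trace window rate against equal-duration
windows placed 6 s before each CS onset (at least 5 s from any
stimulus), at α = 0.05 per condition; the comparison is named in the
source methodology but the statistic is not, so the same two-group
permutation machinery is reused. Responsive neurons are categorized
from the relational and physical mean-rate contrasts at α = 0.05:
RELATIONAL if only the relational contrast rejects, PHYSICAL if only
the physical one, CONJUNCTIVE if both, NONSELECTIVE otherwise. An
alternative reading of conjunctive coding — one condition differing
from the other three — is available behind `rule = "one_vs_rest"`; the
both-contrasts rule is the default because it is the only definition
consistent with the two binary contrasts the rest of the analysis uses.

## The synthetic-data generator

The generator is first-class, tested code: every calibration and
direction-of-effect claim in the test suite runs on its output.

* **Schedule.** Two epochs per daily session, 20 CS-alone then 80 CS-US
  trials per epoch, 100 ms CS, 500 ms trace, 100 ms US, ITIs uniform on
  20-40 s, epoch modality order pseudorandomized per session.
* **EMG.** Gaussian baseline noise whose amplitude jitters log-normally
  (log-SD 0.15) from trial to trial — real eyelid EMG baselines
  fluctuate with tonic muscle activity, and a session-level 2-SD
  threshold is only meaningful against such spread. CR trials carry a
  150 Hz burst (8 noise-SD) in the 200 ms before US onset, with a
  per-session CR probability following a logistic learning trajectory;
  hyperactive trials (probability 0.05) carry a pre-CS burst; paired
  trials end in a railed US artifact. The artifact uses a band-limited
  150 Hz carrier with 10 ms raised-cosine edges: a naive square-wave
  artifact leaks through the global analytic-signal envelope into the
  adjacent CR window (a property of the synthetic signal, not of the
  scoring rule) and would flip paired trials wholesale. EMG is
  synthesized as peri-trial segments covering [-1.2 s, US offset +
  0.1 s]; the scoring windows need nothing outside this span, and
  inter-trial EMG carries no analysis content.
* **Spikes.** Inhomogeneous Poisson trains: baseline rate everywhere,
  and over the CS + trace window a condition gain scaled by a
  per-stage magnitude schedule, with multiplicative log-normal
  (mean-1) per-trial noise scaled by a per-stage consistency schedule.
  The mean-1 noise law is the key design choice: it degrades the
  consistency of differential firing without moving mean rates, so
  magnitude (differentiation index) and consistency (mutual
  information) can be manipulated independently, mirroring the
  magnitude/consistency decomposition the analysis tests. Evoked gain
  is a single boxcar over CS + trace; diverse peristimulus shapes are
  deliberately out of scope since every statistic here integrates over
  the window. A 2 ms dead-time is imposed after the Poisson draw:
  pure Poisson trains above ~5 Hz would fail the ISI refractory
  criterion that real, well-isolated neurons satisfy by biology.
  Rates have no stated empirical distribution, so baselines default to
  log-normal with median 4 Hz — a typical cortical regular-spiking
  range. Coding classes (relational / physical / conjunctive /
  non-selective / unresponsive) impose the corresponding gain
  symmetries; mixture proportions default to the reported composition
  of the recorded population (65.1% responsive; 10.5% / 13.7% / 17.6%
  of those relational / physical / conjunctive).

What the generator does **not** emulate: correlated variability between
simultaneously recorded neurons (the decoding analyses explicitly ignore
it), cross-day unit identity beyond re-instantiating the same specs each
session, biophysical EMG or LFP structure, multi-animal heterogeneity,
and non-boxcar response dynamics. Green tests therefore demonstrate that
the statistical machinery is correct and calibrated under the assumed
generative structure — not that real recordings satisfy that structure.

## Numerical choices and degenerate inputs

* Permutation p-values use `(b+1)/(n+1)` everywhere; permutation counts
  below 100 are refused where tail resolution matters.
* Zero-variance population vectors yield `NA` correlations with a typed
  warning; zero-SD permutation nulls flag the normalized statistic as
  undefined while the p-value stays valid.
* Both rates zero makes the differentiation index undefined (`NA`),
  excluded from rank comparisons.
* Grid-search ties and all sampling steps are deterministic under a
  seed; `generate_dataset()` and `run_pipeline()` reproduce outputs
  exactly for a fixed configuration.

## Validation scale

The test suite validates calibration at sizes chosen to estimate each
error rate with useful precision while remaining a routine desk run:
1000 synthetic neurons for the MI permutation test (binomial 95% CI of
about ±1.4 percentage points around the nominal 5%), 100 independent
null datasets of 150 units for the decoding pipeline (reduced 2x1
hyperparameter grid; the procedure is otherwise identical), 200 null
ensembles x 10 bins for the similarity-difference test with 199
permutations per test (chosen so the two 2.5% tails are exactly
attainable), and two-session staged ensembles of 100 units for the
direction-of-effect checks. The pipeline smoke test uses shortened
sessions (4 + 12 trials per epoch, 2-4 s ITIs) with proportionally
reduced decoder splits (2 train / 2 test per condition, 2-fold CV).

## Known limitations

* The stage-wise omnibus statistics (ANOVA/Friedman F and chi-squared
  values) of the original study depend on the unreleased recordings and
  are not reproduction targets; the package reports its own rank tests
  verbatim from standard routines.
* Template-correlation confidence bands assume unit exchangeability
  (Fisher z) or rely on unit resampling; neither is exact under strong
  across-unit rate heterogeneity.
* The one-pass threshold interpretation and the [-1000, -800) ms
  pre-phase window are documented interpretations of under-specified
  constants; both are configuration-exposed.
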