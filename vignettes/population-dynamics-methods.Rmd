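---
title: "Methods: population dynamics of goal-directed visual search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population dynamics of goal-directed visual search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

popdyn analyzes multi-area extracellular recordings from a free-gaze visual
search task in which a subject fixates centrally (400 ms), sees a face or
house cue (500–1300 ms), holds fixation through a 500-ms delay, and then
searches an 11-item array (two same-category targets among distractors on
20 fixed locations, 5°–11° eccentricity) with up to 4 s of free gaze,
holding the chosen target 800 ms. This vignette explains the models and
procedures each module implements, the parameters that matter, and what the
synthetic-session tests do and do not establish.

## Spike-density estimation

All rate measurements come from a forward ("EPSP-like") kernel,
$K(t) \propto (1 - e^{-t/\tau_g})\,e^{-t/\tau_d}$ for $t \ge 0$ and zero
otherwise, with growth $\tau_g = 1$ ms and decay $\tau_d = 20$ ms. The
kernel is normalized to unit area so that convolution conserves spike
count, and it is causal: a spike influences the rate estimate only forward
in time, so discrimination latencies cannot precede response latencies (a
known artifact of symmetric Gaussian kernels). The exact algebraic form of
the kernel is a package choice: the two time constants and the forward-only
support are the constrained features; area (rather than peak)
normalization affects absolute but not baseline-normalized rates.

Windowed mean rates are computed from the closed-form integral of the
kernel, which is exact and fast; full traces are evaluated on a 1-ms grid,
either by direct per-spike summation (exact for arbitrary spike times) or
by FFT lattice convolution (identical for grid-aligned spike times, which
the FFT path enforces by quantization with a warning).

Every rate entering a population analysis is divided by the unit's mean
baseline rate (−150–0 ms before cue onset, averaged over trials). Division
rather than z-scoring is the convention; units with zero baseline cannot be
normalized and are excluded from normalized analyses with a logged message.

## Unit selection

Receptive fields are classified from rank-sum tests of the 50–200-ms
post-onset response against the −150–0-ms baseline, separately for cue and
array onset: cue-only responders are *focal foveal*, cue-and-array *broad
foveal*, array-only *peripheral*. Peripheral units are *localized* when a
per-location occupancy test (response vs. location occupied, rank-sum,
Bonferroni over 20 locations) finds spatial structure — the significant
locations double as the unit's RF location set — and *unlocalized*
otherwise.

Category selectivity is scored outside the search epoch (cue responses for
foveal units, single-item-in-RF array responses for peripheral units) to
avoid contamination by attentional gain: a rank-sum test at
$\alpha = 0.05$ plus the selectivity index
$\mathrm{SI} = (R_\text{face} - R_\text{house}) /
(R_\text{face} + R_\text{house})$ on baseline-subtracted responses,
clamped to $\pm 1$ when the two responses have opposite signs and
thresholded at $|\mathrm{SI}| > 0.13$ (the "at least 130%" rule).
Significant units that fail the SI threshold are labelled *undefined*.

Attention selectivity compares fixation responses 150–225 ms after
fixation onset between targets and distractors. The signed-rank pairing
the test requires is not inherent in free-gaze data; the package pairs
per-exemplar mean responses (the same stimulus as target vs. as
distractor), falling back to a rank-sum over fixations when fewer than five
exemplars are shared. The attentional effect is the mean paired difference.

The overlap between selective populations is tested with the standard 2×2
independence chi-square of the two memberships; the reported proportions
are "share of B within A" versus "share of B overall", which are equal
exactly under independence.

## State space and demixed PCA

Condition-averaged, baseline-normalized rates in 10-ms bins form a
$(T\cdot C) \times N$ matrix (cue and delay: 0–500 ms, face vs. house cue;
search: 0–225 ms from fixation onset, fixated target vs. distractor). dPCA
is solved in its least-squares form: the matrix is decomposed into
marginalizations (condition-independent dynamics; time-averaged condition
effects; their interaction, pooled into the condition marginalization by
default), and each marginalization is regressed on the full data with a
reduced-rank ridge fit, giving encoder/decoder axis pairs. The ridge
strength defaults to a small fixed fraction of the data's total variance
($10^{-6}\,\overline{X^2}$ per column); at the population sizes used here a
cross-validated choice is noise-dominated and the recovery contracts are
insensitive to the value, so the simpler rule is preferred. Axis signs are
fixed so the first condition projects positively on its leading axis.

Per-bin condition separation is tested by shuffling condition labels at the
trial/fixation level (preserving within-trial autocorrelation), refitting
the projection per shuffle (the conservative choice), and comparing per-bin
mean pairwise distances to the null; Benjamini–Hochberg controls the false
discovery rate across bins at 0.05 with 1000 shuffles by default.

## Parallel axis and orthogonal plane

For the 16-stimulus (eight face, eight house) × 2-attention-state
analysis, per-unit PSTHs span −60–210 ms around fixation onset in nine
30-ms bins centered at −45 … 195 ms. Stimuli are chosen greedily by
balanced target/distractor coverage. The 3-D space is the top-3 PCA of the
parameter-averaged condition means — it must contain the shared dynamics,
otherwise the population-average-rate axis does not live inside it. That
axis is $\tau_i = \sum_n w_{i,n}$ (the per-component sums of unit
coefficients): a uniform rate change moves the projected point along
$\tau$. Each point decomposes exactly into a signed parallel coordinate
along $\tau$ and two signed coordinates in the orthogonal plane through
the origin (x axis seeded from projecting $[10,0,0]$, with $[0,10,0]$ as
the logged fallback when collinear; y axis $= \tau \times \hat x$).
Linear discriminant classification is run separately on the 1-D parallel
and 2-D orthogonal coordinates; because no cross-validation scheme is
canonical for condition-level points, both stratified leave-one-out and
in-sample accuracies are reported.

Note one property that does *not* hold: per-component accuracies are not
invariant to orthogonal rotations of unit space, because the coefficient
sum defining $\tau$ is basis-dependent (a rotation redefines which
direction is "uniform"). The projected coordinates themselves are
rotation-equivariant, and the test suite checks exactly that.

## Representational geometry

Neuronal vectors are per-condition population patterns (time-averaged
rates or regression coefficients). Geometry is quantified by Euclidean
distance (or its mean over condition pairs) and by the angle
$\arccos(a\cdot b / \lVert a\rVert\lVert b\rVert)$ in degrees. Subspace
layouts are aligned by orthogonal Procrustes with isotropic scaling
("rotated PCA"); reflections are disallowed unless enabled, and a needed
reflection is flagged with its residual. The category/attention hyperplane
angle trains linear maximum-margin classifiers (features standardized
internally for optimizer stability, weights back-transformed to rate
space) on 100 balanced subsamples per scheme, averages weights and
intercepts, and takes the angle between the averaged weight vectors; the
label-shuffle null retrains with a smaller subsample count per shuffle
(default 5) because retraining the full 100-subsample average 1000 times
costs ~2×10⁵ fits for no change in the null's location.

## Peripheral encoding model

Each fixation of a localized peripheral unit is coded by a 12-component
indicator: six stimulus types (face/house targets and distractors —
"target" meaning the trial's cue category — plus flower and hand
distractors) crossed with the current foveal fixation type (on-target
block first). Indicators are set for every RF-resident array item; empty
RFs leave all-zero rows. The response is the mean rate 0–250 ms after
fixation onset. The lasso penalty is selected once per unit by 10-fold
cross-validated Gaussian deviance and held fixed across 100 random
half-splits (200 fits), whose averaged coefficients are the reported
response strengths. Population geometry per attentional state compares the
six coefficient vectors across units; the paired test runs over 15
resampled unit subsets (80% of units each) — the subset count is
configurable and mirrors the 15-fold resampling implied by the t₁₄
statistics this analysis traditionally reports.

## Spatial RSA

Fixations are grouped by fixated location; per 50-ms window (0–200 ms
after fixation onset) the per-location mean population vectors give a
20×20 neural dissimilarity matrix (1 − Pearson r), compared to the
physical distance matrix by Spearman correlation over the lower triangle.
Locations with fewer than 5 fixations are dropped from both matrices. The
null shuffles location labels 1000 times; significance requires exceeding
the 1 − 0.05/4 null quantile (Bonferroni over the four windows). Layouts
(2-D PCA of location vectors) are Procrustes-aligned to the physical
coordinates and summarized by the normalized alignment residual.

## Efficiency and LFP

Per-unit Pearson correlations relate windowed mean rates (cue: 0–500 ms
after cue onset; delay: 0–200 ms after delay onset) to the trial's
eventual fixation count over correct trials; units are classed
positive/negative by the delay-window result, and both trial-level and
group-mean (seven lowest fixation counts) correlations are reported
because the figure-level statistic is ambiguous between them. Theta power
(4–12 Hz) is estimated by Welch's method — 200-ms Hann segments, 50%
overlap, implemented directly on the FFT since no installed package
provides it — integrated over the band, averaged across channels, and
correlated with fixation count per epoch. End-of-search divergence
compares face- vs. house-cue population vectors 0–200 ms after array onset
and after the final fixation's onset, with paired tests over 15 resampled
unit subsets and a cue-label shuffle null. Note that paired tests across
overlapping unit subsets measure the *consistency* of a difference, not
its chance level — any systematic difference, however small, reaches
significance — so the shuffle null carries the calibrated inference and
the subset test is reported as an effect-consistency statistic.

## The synthetic-session generator

The generator is first-class, tested code; its defaults are the study
conditions. Trials follow the task timeline exactly; fixation durations
are log-normal with mean 208 ms and SD 150 ms (the task's 800-ms target
hold is a rule, not part of that law); fixation counts are
1 + Poisson(1.6); the per-fixation refixation probability 0.09 is derived
analytically from 1 − exp(−1.6 p) = 0.1346, the target share of correct
trials containing a return fixation. Units are inhomogeneous-Poisson with
piecewise-constant rates: baseline (gamma across units, mean 10 Hz),
multiplicative visual gain 2.5 on the preferred epoch, category gain
$g$ vs. $1/g$ (face vs. house), attention gain on fixated targets,
maintenance units carrying $\sqrt{g}$ through the delay, refixation
attenuation 0.85 on foveal units, and cue/delay rates scaled by
$1 \pm 0.12$ per fixation-count step for efficiency-coding units (set by a
pre-hoc power calculation targeting reliable detection at 300 trials).
Peripheral units respond additively to RF-resident items through their
planted 12-coefficient vectors (on-target block spread ×1.5). Half the
foveal units carry Gaussian gaze-position gain fields (gain 0.8, σ = 3°),
the structure spatial RSA recovers. Foveal search responses follow the most
recently fixated item until the next fixation's response takes over; gating
by fixation offset instead would let the shorter distractor fixations leak
baseline into the 150–225-ms window and bias the attention contrast under
the null (the package's calibration tests guard exactly this). LFP traces
are 1/f noise plus an 8-Hz sinusoid whose cue-epoch amplitude rises
(+0.12/fixation) and delay-epoch amplitude falls (−0.12/fixation) with the
trial's fixation count.

Every stochastic draw comes from a substream keyed by (session seed,
stream tag, unit/trial id), so sessions are bit-reproducible and adding
units never perturbs existing trials.

What the generator does **not** emulate: refractoriness or any ISI
structure beyond Poisson (the analyses consume rates), saccade kinematics
and eye-position noise, retinotopic RF remapping with gaze (item positions
are screen-fixed), spike-waveform or sorting artifacts, cross-area
synchrony, and non-stationarities such as drift or adaptation. Passing
tests therefore establish that the analysis code recovers the structure
its statistics assume — not that real cortex contains that structure.

## Problem sizes and numerical choices

Default sessions use 100 units (40/25/20/15 across V4/IT/OFC/LPFC) and 200
trials; the full pipeline runs in ~2 minutes on one CPU and is
byte-reproducible given the seed. Tests and calibration runs use 100–200
units and 150–300 trials, 150–1000 permutations, and 100 null simulations
for the FDR calibration; each choice is stated where it is used. Singular
value decompositions fall back to a symmetric eigendecomposition on the
rare LAPACK convergence failure; rank-sum/signed-rank tests use the exact
or normal approximation as chosen by `stats::wilcox.test`; degenerate
cases (zero baselines, constant dissimilarities, empty RFs, single-class
labels) error or exclude with explicit messages rather than producing
silent numbers.
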