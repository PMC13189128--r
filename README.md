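# popdyn

Population-dynamics analyses for multi-area extracellular recordings from a
free-gaze visual search task, together with a ground-truth synthetic
session generator that makes every stage of the pipeline testable end to
end.

In the task, a subject fixates centrally (400 ms), sees a face or house cue
(500–1300 ms), holds fixation through a 500-ms delay, then freely searches
an 11-item array — two targets matching the cue category among distractors
on 20 fixed locations at 5°–11° eccentricity — and holds the chosen target
for 800 ms. The package asks how neural populations across V4, IT, OFC and
LPFC encode the cue, maintain it, and guide the search:

- **Spike density**: forward EPSP-like kernel,
  $K(t) \propto (1-e^{-t/1\,\text{ms}})e^{-t/20\,\text{ms}}$, unit area,
  causal; rates normalized by each unit's pre-cue baseline.
- **Unit selection**: receptive-field classes (focal/broad foveal,
  localized/unlocalized peripheral); category selectivity by rank-sum test
  plus the selectivity index
  $\mathrm{SI} = (R_f - R_h)/(R_f + R_h)$ with the $|\mathrm{SI}| > 0.13$
  rule; attention selectivity by signed-rank test on target vs. distractor
  fixation responses (150–225 ms).
- **State space**: demixed PCA (least-squares formulation) over
  condition-averaged population tensors; per-bin condition separation
  tested against 1000 trial-level label shuffles with FDR correction.
- **Orthogonal subspace**: decomposition of 3-D state-space points into the
  population-average-rate axis $\tau_i = \sum_n w_{i,n}$ and its orthogonal
  plane; linear-discriminant classification from each component.
- **Representational geometry**: Euclidean distances and cosine angles
  between neuronal vectors; classifier hyperplane angles with balanced
  subsampling and shuffle nulls; Procrustes ("rotated PCA") subspace
  alignment; first-fixation/refixation and before/after-target context
  comparisons.
- **Peripheral encoding**: 12-indicator (6 stimulus types × 2 fixation
  types) lasso regression per peripheral unit, split-half averaged over
  200 fits.
- **Spatial RSA**: 20-location neural dissimilarity matrices (1 − Pearson
  r) vs. physical distances, Spearman correlation with permutation nulls,
  Bonferroni over four post-fixation windows.
- **Efficiency & LFP**: per-unit firing-rate correlations with the trial's
  fixation count (cue and delay windows), selective-population overlap
  (chi-square), end-of-search representational divergence, and Welch
  theta-band (4–12 Hz) LFP power correlates.

The synthetic generator plants all of this structure — tuned
inhomogeneous-Poisson units, realistic task and fixation statistics
(log-normal 208-ms fixations, return fixations in ~13.5% of correct
trials), gaze-position gain fields, and LFP with an efficiency-dependent
theta component — and records the ground truth in the session container, so
recovery, calibration and false-positive rates can all be measured.

## Worked example

```r
library(popdyn)

s <- simulate_session(sim_config(seed = 1))     # 100 units, 200 trials
s <- classify_units(s)
tab <- unit_label_table(s)
table(tab$rf_class)
#>           broad_foveal           focal_foveal          nonresponsive
#>                     30                     32                     11
#>   peripheral_localized peripheral_unlocalized
#>                     15                     12

ps <- build_psth_matrix(s, tab$rf_class %in% c("focal_foveal", "broad_foveal"),
                        epoch = "cue", conditions = "category")
tst <- trajectory_separation_test(ps, n_perm = 1000, seed = 1)
sum(tst$significant)
#> [1] 45
```

45 of the 50 cue-epoch 10-ms bins separate face- from house-cue population
trajectories after FDR correction — the bins before ~50 ms (the planted
response latency) stay at the null, as they should. Running the whole
pipeline:

```r
res <- run_pipeline(pipeline_config(seed = 1))
#> classify: 28 category-selective, 34 attention-selective of 100 units
#> state_space cue (category): 45/50 significant bins
#> state_space delay (category): 50/50 significant bins
#> state_space search (attention): 22/22 significant bins
#> subspace: attention accuracy parallel 0.69 orthogonal 0.65
#> geometry: refixation t = 9.38; hyperplane angle 98.2 deg
#> encoding: 15 units; distance target 61.37 vs distractor 46.91
#> rsa: rho = 0.15, 0.33, 0.47, 0.52
#> efficiency: 20% pos, 13% neg; theta r cue 0.79 delay -0.64
```

Reading the log: cue identity is decodable from population dynamics in all
three epochs; the category/attention hyperplanes are near-orthogonal
(98°, consistent with the independently planted tunings); foveal attention
spreads the peripheral stimulus-type code (distance 61 vs. 47); population
activity mirrors array geometry from the second post-fixation window on
(ρ up to 0.52); and theta power rises with fixation count during the cue
but falls during the delay, as planted. The run takes ~2 minutes and is
byte-reproducible given the seed.

The same analyses are available as a step-by-step workflow under
`analysis/` (`01_simulate.R` … `08_efficiency_lfp.R`), each writing its
tables to `results/`.

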