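# isfcr

Isolating stimulus-locked brain-network correlations from multi-subject
fMRI-like time series with **inter-subject functional correlation (ISFC)**.

## The problem

Within-subject functional connectivity (FC) — the Pearson correlation
between two regions' BOLD time courses in the same brain — mixes three
signal sources: stimulus-induced responses *S* shared by everyone
experiencing the same stimulus, intrinsic neural fluctuations *I*
specific to each subject, and non-neuronal noise *N* (respiration,
cardiac, motion), also subject-specific. During naturalistic stimulation
(a story, a film) FC is dominated by *I* and *N*: default-mode-network FC
looks nearly identical at rest and mid-narrative, so FC cannot tell you
what the network is doing with the stimulus.

ISFC correlates regions **across brains**. With `k` subjects'
region-by-time matrices `X_i` (rows z-scored), the subject-level matrix
correlates subject `i` against the average of everyone else,

    ISFC_i(a, b) = corr( X_i[a, ·],  mean_{j≠i} X_j[b, ·] ),

and the group matrix is the Fisher r-to-z average of the `k` subject
matrices, symmetrized as `(C + Cᵀ)/2`. Since `I` and `N` are uncorrelated
across subjects, only the stimulus-locked covariance survives; the
diagonal is each region's inter-subject correlation (ISC).

The package implements the full analysis stack around that estimator:

- **Data**: parcellated TSV I/O, z-scoring, DCT high-pass, nuisance
  regression, 4-D volume → ROI extraction (`RNifti` adapter).
- **Estimators**: `group_isfc()`, `group_fc()`, `isc()`, `seed_isfc()`.
- **Inference**: phase-randomization surrogates, max-statistic
  family-wise-error thresholds `R*`, permutation p-values
  (`max_null()`, `fwer_threshold()`, `perm_corr_pvalue()`).
- **Dynamics**: sliding-window ISFC, connectivity fingerprints,
  split-half reliability, segment reordering for history-dependence
  analyses, behaviour coupling with loess-style smoothing, cross-network
  summaries, graph export (`sliding_isfc()`, `fingerprint()`, ...).
- **Decoding & clustering**: nearest-template condition and
  story-interval classification, k-means network discovery with
  Sørensen-Dice split-half model selection, neighbourhood-correlation
  declustering (`classify_conditions()`, `select_k()`, `decluster()`).
- **Simulation**: a generator for the three-component model — shared
  stimulus covariance (optionally piecewise states), per-subject
  intrinsic covariance, white noise, per-subject global confounds, and
  leaky context integration with idiosyncratic context breaks under
  segment scrambling (`simulate_group()`, `sim_config()`).

## Worked example

Two simulated groups of 18 subjects (10 regions, 400 TRs): one listening
to a "story" (stimulus share 0.2 on a uniformly coupled stimulus
network), one at rest. Every subject carries an idiosyncratic intrinsic
network and a respiration-like global confound.

```r
library(isfcr)

C_S <- cor_constant(10, 0.4)
C_I <- lapply(1:18, function(i) random_cor(10, strength = 1.5, seed = 100 + i))
story <- sim_config(k = 18, p = 10, n = 400, C_S = C_S, stimulus_share = 0.2,
                    C_I = C_I, noise_share = 0.2, confound_sd = 0.5, seed = 7)
rest  <- sim_config(k = 18, p = 10, n = 400, stimulus_share = 0,
                    C_I = C_I, noise_share = 0.2, confound_sd = 0.5, seed = 8)
ds_story <- zscore_subjects(simulate_group(story)$dataset)
ds_rest  <- zscore_subjects(simulate_group(rest)$dataset)

mean_edges(group_fc(ds_story));  mean_edges(group_fc(ds_rest))
mean_edges(group_isfc(ds_story)); mean_edges(group_isfc(ds_rest))

nd <- max_null(ds_rest, "isfc", n_iter = 1000, seed = 9)
rstar <- fwer_threshold(nd, q = 0.01)
sum(threshold_map(group_isfc(ds_rest)$values, rstar)$mask)
```

Output:

```
mean edge  FC   story: 0.277  rest: 0.226
mean edge  ISFC story: 0.137  rest: -0.012
R* (q = 0.01): 0.052
suprathreshold rest ISFC entries: 0 of 100
suprathreshold story ISFC entries: 100 of 100
```

FC barely distinguishes the conditions (0.277 vs 0.226 — its mean edge
reflects the intrinsic networks and the confound, present in both).
ISFC shows the stimulus-locked network during the story (0.137, close to
the analytic expectation `isfc_expected(0.2, 0.4, 18)` ≈ 0.16) and
nothing at rest: after family-wise error correction at `q = 0.01` the
rest ISFC map is empty while the story map is fully suprathreshold.

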