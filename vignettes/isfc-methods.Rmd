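---
title: "Inter-subject functional correlation: model, statistics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject functional correlation: model, statistics, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isfcr)
```

## The signal model and why FC is not enough

The measured BOLD signal in a region of subject $i$ is modelled as a sum of
three components: a stimulus-induced component $S$ that is time-locked to
the external stimulus and therefore shared by every subject experiencing
it; an intrinsic neural component $I_i$ (spontaneous fluctuations,
stimulus-unrelated cognition) that is specific to the subject; and
non-neuronal noise $N_i$ (respiration, cardiac pulsation, head motion),
also specific to the subject. Within-subject functional connectivity (FC)
— the Pearson correlation between two regions' time courses in the same
brain — mixes all three: intrinsic covariance and subject-wide noise such
as respiration inflate within-brain correlations no matter what the
stimulus is doing.

Inter-subject functional correlation (ISFC) breaks the mixture by
correlating *across* brains. For subject $i$ with region-by-time matrix
$X_i$ ($p$ regions, $n$ timepoints, rows z-scored within subject), the
subject-level ISFC matrix correlates each row of $X_i$ with each row of
the average of all other subjects,
$\bar{X}_{-i} = \frac{1}{k-1}\sum_{j \ne i} X_j$:

$$\mathrm{ISFC}_i(a, b) = \mathrm{corr}\!\left(X_i[a, \cdot],\; \bar{X}_{-i}[b, \cdot]\right).$$

Because $I_i$ and $N_i$ are uncorrelated across subjects, only the shared
stimulus-locked covariance survives in expectation. The $k$ subject
matrices are averaged entrywise after Fisher's r-to-z transform and the
result is symmetrized as $(C + C^\top)/2$, treating region coupling as
undirected. The diagonal of the group matrix is the inter-subject
correlation (ISC) of each region; a single row is the seed-based ISFC map.
`group_fc()` computes the conventional within-subject counterpart
(per-subject correlation matrices, Fisher-averaged, unit diagonal) so the
two estimates can be contrasted on identical data.

Under the simulator's variance-budget model (below), the population value
of an ISFC edge with stimulus share $s$ and stimulus edge correlation
$\rho_S$ is

$$\frac{s\,\rho_S}{\sqrt{s + (1-s)/(k-1)}},$$

implemented in `isfc_expected()`: the numerator is the shared covariance;
the denominator reflects the unshared variance that leave-one-out
averaging shrinks by $1/(k-1)$ but cannot remove. This expression is the
package's own derivation and is verified empirically by the test suite at
large $n$.

## Preprocessing

`zscore_subjects()` standardizes each region time course to zero mean and
unit *sample* ($n-1$) standard deviation. Pearson correlations are
invariant to the denominator choice; the sample convention is fixed so
that stored intermediates are comparable across tools. Zero-variance rows
cannot be standardized: they are set to zero, flagged, and excluded from
every correlation average downstream — never silently imputed.

`highpass()` removes slow scanner drift by projecting out a discrete
cosine basis containing all components with period at or above the
cutoff (140 s reproduces the conventional choice); `nuisance_regress()`
projects out arbitrary nuisance series (e.g. high-variance out-of-brain
voxels, cerebrospinal-fluid and white-matter means) by least squares.
The two are plain matrix-to-matrix operations, so either order can be
composed; filtering before nuisance regression is the recommended
default since drift in the regressors themselves is then harmless.
`extract_roi_timeseries()` adapts 4-D volumes (arrays, or NIfTI files via
RNifti) to the parcellated representation by averaging voxels within
disjoint ROIs.

## Surrogate statistics

Correlation p-values that assume independent samples are invalid for BOLD
series, whose long-range autocorrelation makes spurious correlations
common. The package's null model is phase randomization: each series'
Fourier amplitudes are kept and its phases rotated by independent
Uniform$(0, 2\pi)$ draws, mirrored conjugate-symmetrically so the inverse
transform is real. The surrogate has exactly the original amplitude
spectrum — hence mean, variance and autocorrelation — but no preferred
alignment with anything else. The DC bin is untouched; for even $n$ the
Nyquist bin is also untouched, since a real signal constrains its phase
to $0$ or $\pi$.

Family-wise error control uses the max-statistic resampling scheme: on
each of `n_iter` iterations every series of every subject is replaced by
an independent surrogate, the full ISFC (or FC) map is recomputed, and
its maximum recorded. The threshold $R^*$ returned by `fwer_threshold()`
is the $(1-q) \cdot 100$th percentile (linear interpolation between order
statistics) of these maxima; declaring only entries above $R^*$
significant bounds the probability of *any* false positive at $q$. For
the ISFC statistic the maximum is taken over the full symmetrized matrix
including the ISC diagonal; for FC the structural unit diagonal is
excluded. The maximum is taken per analysis map; windowed analyses can
either pool windows into one map or threshold each window's map, and the
package applies the procedure to whatever map it is given.
`perm_corr_pvalue()` applies the same surrogate logic to a single pair of
series, with the $(b+1)/(m+1)$ estimator so p-values are never zero.

Numerical conventions: correlations are clipped to $\pm(1 - 10^{-7})$
before `atanh`, so $r = \pm 1$ averages to a finite value with negligible
bias; all resampling functions accept an integer seed and are then
bit-reproducible.

## Dynamics, fingerprints, reliability

`sliding_isfc()` recomputes the group matrix in half-open windows
$[t, t+w)$ labelled by start TR. Window length is a per-analysis choice
with no single default: 60 TRs (90 s at TR 1.5 s) suits slow narrative
dynamics, 30 TRs (45 s) faster contrasts. The `fingerprint()` of a
matrix is its $p(p-1)/2$ lower off-diagonal entries in a fixed row-major
edge order, serialized with `"regionA-regionB"` labels so fingerprints
are comparable across runs; `mean_edges()` is the scalar network
coupling. `split_half_reliability()` repeatedly splits the subjects into
random halves and correlates the halves' windowed fingerprints — high
values demonstrate that the momentary network configuration is
stimulus-locked, since idiosyncratic dynamics cannot replicate across
disjoint subjects. With an odd subject count the function errors unless
explicitly told to drop the last subject.

`reorder_segments()` re-concatenates measured responses segment-wise,
which turns a scrambled-presentation run back into the intact timeline;
comparing the reordered run's windowed ISFC against the intact run's
separates history-dependent regions (which differ) from history-free
regions (which match). `behavior_coupling()` smooths sparse behavioural
ratings with a local linear tricube-kernel regression whose span is
expressed in TRs (the standard "loess" construction, written out so the
span unit is explicit), evaluates the smooth on the window grid, and
tests the correlation against phase surrogates of the behavioural series.
`cross_network_isfc()` summarizes between-network blocks of the windowed
matrix; `export_graph()` applies the drawing conventions (node diameter
proportional to ISC, edge width $60 r$, small negative edges
$-0.1 < r < 0$ zeroed).

## Decoding and clustering

`classify_conditions()` and `classify_intervals()` use a deliberately
minimal classifier: nearest template by Pearson similarity between
Fisher-z fingerprints, leave-one-subject-out, ties resolved to the lowest
class index. The test subject's ISFC fingerprint is computed against the
remaining group of its acquisition run; templates are built from the
remaining subjects only. The choice is isolated behind the `method` /
`feature` arguments so alternatives can be swapped without touching the
evaluation loop.

One property of this construction deserves emphasis: under a null with no
shared signal, interval decoding sits a couple of percentage points
*above* nominal chance (about 9% against 7.1% with 14 intervals at the
suite's problem sizes), because the true-interval template and the test
fingerprint both depend on the remaining group's realized data in that
interval, aligning their variances. This is a property of
nearest-template LOSO decoding generally, not a label leak; accuracies
should therefore be compared between methods or against a no-stimulus
control rather than against the nominal chance line alone. Relatedly, a
stimulus with a *stationary* generating covariance still supports
interval decoding, because what is shared across subjects is the realized
stimulus trajectory, not merely its distribution.

`kmeans_networks()` partitions correlation-map rows with k-means (squared
Euclidean objective, best of `n_restarts` starts, seed-deterministic).
`select_k()` chooses the cluster count by split-half reproducibility: for
each candidate $K$ the two halves are clustered independently and scored
by the worst-matched cluster, $\min_i \max_j D_{ij}$, with the
Sørensen-Dice overlap $D_{ij} = 2|X_i \cap Y_j| / (|X_i| + |Y_j|)$; ties
prefer the smaller $K$. Note that on perfectly separated data a merged
solution can be exactly as reproducible as the true one, in which case
the tie rule keeps the smaller count — the criterion is informative
precisely when noise makes wrong counts unstable. `decluster()`
agglomerates elements into contiguous ROIs by repeatedly merging the most
correlated adjacent pair (ties to the lowest-index pair, deterministic),
replacing the pair's series by their average, until no merge fits the
`target_size` cap, which is a required parameter.

## The synthetic generator

`simulate_group()` draws data directly from the three-component model:
one stimulus matrix $S$ with inter-regional correlation $C_S$ (optionally
a different correlation state per stimulus segment, switching
instantaneously at boundaries so that windows spanning a boundary mix
states, as real sliding windows do); per-subject intrinsic components
with correlation $C_I$ — a single matrix, or one per subject, the
realistic case in which each individual has an idiosyncratic intrinsic
network; white noise; and per region the mixture
$\sqrt{s}\,S + \sqrt{1-s-\eta}\,I_i + \sqrt{\eta}\,N_i$, so shares are
exact variances. An optional per-subject scalar confound series, added to
all regions with region-specific gains, is the minimal model of
respiration- or motion-like noise: it inflates FC and leaves ISFC nearly
untouched. Defaults follow the study geometry: TR 1.5 s, groups of 18
subjects where group size matters, 10-region networks (45 edges),
paragraph-scale segments of tens of TRs and word-scale segments of a few
TRs, and weak stimulus shares (0.1-0.3) where realism matters, consistent
with observed inter-subject correlation levels in high-order cortex.

Context integration is realized as a leaky accumulator:
$y_t = e^{-1/\tau} y_{t-1} + x_t$, with $\tau$ in TRs per region
(`memory_tau`; `apply_memory()` exposes the operation). The generative
subtlety is what happens under scrambling. A linear integral of a shared
scrambled stimulus would still be shared across subjects, so scrambling
alone would not reduce integrator ISFC. The generator therefore breaks
*context* at segment boundaries of a scrambled presentation: the
integrator state carried into each segment is drawn per subject from the
stationary state distribution — each brain bridges an incoherent junction
with its own context. The variance bookkeeping stays exact (shared
within-segment integral plus idiosyncratic decaying carryover sum to the
stationary variance), and the shared fraction falls as segments shorten
relative to $\tau$: word-scale scrambling damages integrator ISFC more
than paragraph-scale, intact presentations not at all, and instantaneous
regions are untouched. This mechanism is the package's own modelling
choice for a phenomenon whose generative form is not prescribed by the
analysis method itself.

What the generator does *not* emulate: haemodynamic convolution (analyses
operate on measured-signal timescales; an HRF would only smooth all
components alike), spatially structured noise fields, voxel-level
geometry (regions only), subject-specific response latencies, and
non-stationary physiological noise spectra. Passing tests therefore show
that the estimators behave as designed under the stated signal model —
they cannot certify performance on real recordings, where idiosyncratic
stimulus-locked responses, latency differences and shared artefacts
(e.g. stimulus-correlated breathing) violate the model in ways the
statistics section of any applied study must address.

## Problem sizes and numerical choices in the test suite

The suite validates each claim at desk scale: oracle equivalence on
$k=3, p=4, n=8$ toys against a direct-summation reference implementation
(tolerance $10^{-12}$); family-wise error calibration on 200 null
datasets ($k=6, p=10, n=300$, $q=0.05$, 1000 surrogate iterations per
dataset — the measured false-positive rate is 0.035-0.065); the
rest dissociation at $n=2000$; the coherence gradient, decoding
superiority and reliability scaling over 20, 20 and 8 replicates
respectively; and permutation calibration over 200 AR(1) pairs. These
sizes are the package's validation design: large enough that every
qualitative claim is resolved with margin, small enough that the full
suite runs on a laptop core in well under half an hour.
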