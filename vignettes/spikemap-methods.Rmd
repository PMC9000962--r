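---
title: "Mapping spike-train dynamics with spikemap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spike-train dynamics with spikemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemap)
```

## The problem

Small central pattern generators such as the crustacean pyloric circuit
produce a stereotyped rhythm — in the two identified neurons analyzed here,
the pyloric dilator (PD) and lateral pyloric (LP) neurons burst in strict
alternation — but under perturbation (temperature, pH, high extracellular
potassium, decentralization, neuromodulators) the circuit visits a wide range
of atypical and dysfunctional states: skipped or weakened bursts, irregular
tonic spiking, one-neuron silence, and complete silence. `spikemap`
implements a pipeline that turns long paired spike-time recordings into a
categorical description of these dynamics:

1. split the recording into nonoverlapping 20 s windows;
2. summarize each window as a fixed-length statistical feature vector;
3. embed all windows into a 2-D map with t-SNE;
4. assign dynamic-state labels by cluster boundary polygons;
5. analyze the resulting categorical time series: state probabilities,
   transition matrices against a resampling null model, burst metrics, and
   within- versus across-animal variability.

Every stage is driven by plain CSV/JSON files and fixed seeds, so any run is
exactly reproducible.

## The feature vector

A window can contain anywhere from zero to thousands of spikes, so the raw
spike times are not a usable basis. Instead each window is reduced to 48
numbers:

* **ISI deciles** (10 per neuron). The first-order interspike intervals of
  each neuron are summarized by their 10th–100th percentiles with linear
  interpolation. Percentiles convert a variable-length set into a fixed
  vector while retaining the strongly bimodal shape characteristic of
  bursting (short intra-burst ISIs, long inter-burst intervals).
* **Spike-phase deciles** (10 per ordered neuron pair). The phase of spike
  $t_i^X$ of neuron X relative to neuron Y is
  $(t_i^X - t^Y_{i,-}) / (t^Y_{i,+} - t^Y_{i,-}) \in [0, 1]$,
  where $t^Y_{i,-}$ and $t^Y_{i,+}$ are the flanking Y spikes; X spikes with
  no Y spike on one side are omitted. Phases capture the coordination between
  the two neurons, which ISIs alone cannot.
* **Scalars** (2 each): firing rate (spike count / bin width); the ratio of
  the maximal second-order to maximal first-order ISI,
  $\max I(2) / \max I(1)$, which distinguishes single-spike "bursts" from
  true bursts; the ratio of the largest to second-largest ISI; and a
  burstiness statistic $\max \mathrm{diff}(s) / s_{max}$, where $s$ is the
  ascending sorted ISI vector and $s_{max}$ the upper element of its maximal
  gap — near 1 for bimodal (bursty) ISI distributions, 0 for tonic firing.

Undefined features (e.g. phases in a window where one neuron is silent) are
replaced by *fillers* placed well off each feature's defined range: 20 s (the
bin width) for ISI deciles, 2 for phase deciles (above the maximum of 1), 0
for the two ratios (below their minimum of 1), −1 for burstiness (below its
minimum of 0). Firing rate is always defined. The exact filler values are
configurable, and the property tests confirm that class recovery in the map
is insensitive to ±50% changes of all fillers simultaneously. The total
dimensionality is 48 (4 decile blocks + 8 scalars); the percentile grid is
likewise configurable.

Each column is finally z-scored across the entire dataset using the
population standard deviation (divisor $n$); zero-variance columns map to 0.
The per-column statistics are stored so held-out windows can be projected
into the same space.

## The map

The z-scored matrix is embedded in two dimensions with t-SNE. Defaults:
perplexity 100 (capped at $\lfloor (N-1)/3 \rfloor$), 1000 gradient
iterations, learning rate $N/12$, early exaggeration 12 for the first 250
iterations. Below $N = 5000$ points the exact gradient is used; larger
problems fall back to Barnes–Hut. The backend (`Rtsne`) and all settings are
recorded in the result object, and a fixed seed plus fixed settings gives
bit-identical coordinates on reruns.

Random t-SNE initializations scatter clusters arbitrarily, so the default
initialization is deterministic and interpretable: the x-axis is each
window's shortest ISI (the minimum over neurons of the 10th-percentile ISI
feature, before z-scoring) and the y-axis the maximum over neurons of the
second-to-first-order ISI ratio. Both columns are centered and rescaled to
SD $10^{-4}$, the standard small-norm t-SNE initialization. PCA and
seeded-random initializations are available for comparison.

Two diagnostics ask whether the map is *useful*:

* **Smoothness.** A Delaunay triangulation is built over the embedded
  points; for each triangle the *triadic difference* is the maximum pairwise
  difference of some burst metric across its three vertices. If the metric
  varies smoothly over the map, triadic differences are small. They are
  compared against a PCA projection and against the same map with metric
  values shuffled, using one-sided two-sample Kolmogorov–Smirnov tests
  (map differences stochastically smaller). Windows with undefined metric
  are dropped before triangulation rather than filled; duplicate coordinates
  are collapsed to their first occurrence.
* **Class recovery.** On a synthetic benchmark with known classes, per-class
  10-nearest-neighbor purity in the map must beat a seeded random 2-D
  projection of the same features. For degenerate classes (e.g. silent
  windows, whose feature rows are identical) any projection reaches purity
  1, so only a tie is possible there.

## Labels and state dynamics

Cluster labels are assigned by polygons drawn in map coordinates
(even-odd rule, boundary points inside; overlapping polygons are rejected
when the file is loaded). Polygon files carry an MD5 hash of the embedding
they were drawn on, so stale files are rejected after the map changes. A
k-nearest-neighbor label propagator is provided as a convenience for
held-out points, in place of re-drawing polygons or re-inspecting new data
by hand.

The labeled windows of each preparation form a categorical time series.
Contiguous segments are delimited by timestamp gaps larger than one bin
width, condition changes, or preparation changes; no statistic ever counts a
pair across a segment boundary. A window spanning a condition switch is kept
under the condition at its start and flagged.

* **Transition matrices** count within-segment consecutive label pairs, zero
  the diagonal (self-pairs are dwell, not transitions) and row-normalize,
  giving a right-stochastic matrix. Significance of each cell is assessed
  against a resampling null in which each initial state's $n_i$ outgoing
  transitions draw destinations i.i.d. from the pooled marginal distribution
  of post-transition states, restricted to destinations other than the
  initial state and renormalized. The restriction matters: in a two-state
  system every transition is forced and no cell should ever be flagged.
  Cells are annotated "more", "less", or "never-but-expected" from the two
  one-sided tail probabilities, matching the three-way annotation
  convention. Unlabeled windows break runs and contribute no transitions.
* **State probabilities** are computed per preparation and averaged with
  equal weight per preparation (not pooled counts), so a long recording
  cannot dominate the population estimate. Fold changes between conditions
  are likewise per-preparation ratios; undefined ratios (a state absent
  before the manipulation) are flagged rather than imputed.
* **The paired permutation test** for condition effects flips the sign of
  each preparation's probability change at random; when $2^{n} \le$
  `n_perm` the null is enumerated exhaustively, otherwise Monte Carlo with
  the add-one estimator. Raw and Bonferroni-corrected p-values are both
  reported so the caller can apply whichever convention a figure requires.
* **Variability before transitions**: for windows in the regular state, the
  time to the next within-segment transition is computed; windows in the
  200 s before a transition are binned at the bin width, the per-window CV
  of the burst period (SD/mean over cycles) is averaged per bin, and a
  Spearman rank correlation between bin time and mean CV tests for a rising
  trend.
* **Within- vs across-animal variability**: within = mean over animals of
  the per-animal CV of a metric; across = CV of the per-animal means. Both
  are dimensionless and directly comparable. Their difference is tested by
  shuffling the animal assignment of windows (1000 draws); significance uses
  $\alpha = 0.05$ divided by the number of metrics tested.

## Burst metrics

Bursts are detected by ISI thresholding: bursty trains have bimodal ISI
distributions, so the default threshold is the geometric mean of the two
sorted ISIs flanking the maximal sorted-ISI gap — this adapts across rhythm
periods from roughly 0.5 to 2 s without tuning, and a fixed threshold in
seconds can be supplied instead. Trains with burstiness below 0.5 (no clear
bimodality) or fewer than 4 spikes yield no bursts, and a burst needs at
least 2 spikes. From the burst trains the package computes the PD burst
period (mean start-to-start interval), burst durations, duty cycles
(duration over the same neuron's cycle period), and the LP neuron's on/off
delays and phases relative to the most recent preceding PD burst start;
phases are wrapped to $[0, 1)$, delays reported unwrapped in seconds.
Undefined metrics are missing rows, never fillers — burst metrics are only
computed on windows labeled regular, where they are meaningful. Bursts
straddling window edges are truncated to the window; the resulting bias is
less than one cycle per window.

## The synthetic generator

The generator exists so that every pipeline stage can be validated against
known ground truth without recorded data. Its defaults encode a canonical
slow pyloric rhythm: period 1 s, PD duty cycle 0.2, LP duty cycle 0.3 with
onset at 0.45 of the cycle, intra-burst rates 40 Hz (PD) and 30 Hz (LP),
period jitter CV 0.05, and 5% within-burst spike-timing jitter. The twelve
classes modify this scheme: weak-skipped classes skip one neuron's burst
with probability 0.3 or reduce it to a single spike with probability 0.2;
irregular-bursting raises the jitter CV to 0.35 and drops 20% of cycles;
irregular and sparse-irregular are homogeneous Poisson trains at 8 and 1 Hz;
the one-neuron-silent classes zero one train (with the partner either tonic
or bursting, as the class name states); aberrant-spikes superimposes 0.5 Hz
stray Poisson spikes outside bursts; silent emits nothing. These parameters
are this package's own choices, fixed once so that classes are separable but
adjacent (regular and irregular-bursting differ mainly in jitter), and they
are deliberately not adjusted thereafter.

What the generator does *not* emulate: slow drift of burst parameters within
a recording, measurement noise in spike sorting, correlated jitter between
the two neurons, and gradual (rather than windowed) state changes. Passing
tests on synthetic data therefore demonstrate that the machinery measures
what it claims under known conditions; they do not certify performance on
any particular recorded dataset.

## Numerical choices and degenerate inputs

* Times are 64-bit doubles in seconds; comparisons use a 1e-9 s tolerance.
  Bins are half-open $[kw, (k+1)w)$: a spike exactly on a boundary belongs
  to the later bin. Trailing data shorter than one bin is discarded.
* Burstiness ties (two equal maximal sorted-ISI gaps) resolve to the gap
  with the larger upper element, the smaller and more conservative value.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7).
* Empty inputs: an empty spike table with a declared duration yields empty
  windows; an empty state sequence yields an all-zero transition matrix;
  degenerate test groups are dropped with warnings rather than silently.
* Exact duplicate map coordinates (common for silent windows, whose feature
  rows are identical) are collapsed before triangulation.
* Monte-Carlo p-values use the add-one estimator $(1 + \#\{null \ge
  obs\})/(n+1)$ except where the null is enumerated exhaustively.

## Problem sizes used in the checks

The validation suite runs at sizes chosen to make each statistical check
informative while staying desk-sized: the class-recovery benchmark uses 12
classes × 200 windows (2400 windows, embedded with the exact gradient); the
smoothness test uses 500 regular windows with periods graded from 0.6 to
1.4 s; burst-metric recovery uses 1000 cycles; null calibrations use 200
replicates; the variability power analysis uses 20 animals × 50 windows.
Full experimental datasets of this kind reach ~10^5 windows from hundreds of
animals; at that scale the approximate t-SNE backend (Barnes–Hut here) is
the appropriate choice, and any headline statistics are properties of the
particular dataset rather than of the method.

## Known limitations

* Phases are computed within a window only; flanking spikes across bin edges
  are not used. Windows stay independent at the cost of losing a handful of
  phases per window edge.
* Cluster boundaries for a real dataset must be drawn by an expert for that
  dataset's map; validation here therefore relies on synthetic classes with
  known ground truth.
* No continuous-time Markov modeling or dwell-time survival analysis is
  attempted; transition statistics are conditional on the 20 s bin size.
* The feature set is spike-based by construction: subthreshold/slow-wave
  structure is invisible to it.

## A minimal run

```{r example, eval = FALSE}
bench <- benchmark_dataset(n_per_class = 100, seed = 1)
fm <- zscore_features(assemble_features(bench$store))
emb <- embed_map(fm, perplexity = 100, seed = 1)
knn_purity(emb, bench$truth$class, k = 10)

# polygon labels, then state dynamics
polys <- read_polygons("polygons.json", coords = emb)
labels <- label_by_polygons(emb, polys)
seq <- state_sequence_from_store(set_labels(bench$store, labels))
tm <- transition_significance(transition_matrix(seq), seed = 1)
```
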