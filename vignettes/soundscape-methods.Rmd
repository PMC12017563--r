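---
title: "Soundscape mapping methods: from WAV campaigns to stable acoustic metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soundscape mapping methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

reefscape turns a passive-acoustic monitoring campaign — a directory of
mono WAV files plus a metadata table of start times and categorical
labels — into quantitative descriptions of the soundscape: how well the
labels (site, replicate, day/night) separate the sounds, what acoustic
clusters exist without reference to labels, and how each site's
soundscape moves through acoustic space over a recording day.  This
vignette explains the model behind each stage, the parameters that
matter, and the numerical conventions the package commits to.

## The analysis model

### From waveform to acoustic space

Each recording is high-pass filtered as a whole (8th-order zero-phase
Butterworth, cut-off 70 Hz by default) to remove flow and handling
noise, and then cut into contiguous one-second segments; a trailing
remainder shorter than one second is dropped.  Filtering precedes
cutting so that no segment carries a filter edge transient.

Each second is projected into an initial acoustic space.  Two built-in
embeddings are provided:

* **mel-spectrum** (64 dimensions): natural-log energies of 64
  triangular mel bands spanning the analysis band (70–2000 Hz by
  default), computed from the power spectrum of the whole second;
* **mel-spectrogram** (6400 dimensions): the same mel bands over a
  short-time Fourier transform with a 2048-sample Hann window and a
  0.01-s hop; at 44.1 kHz the hop is 441 samples and one second yields
  exactly 100 frames, hence 64 × 100 = 6400 log-energy values.

A third route, `cnn_embed()`, feeds the first 0.96 s of each second's
mel-spectrogram to a user-registered adapter (for example a pretrained
audio CNN).  No network weights ship with the package; the adapter
interface only enforces the declared output dimensionality.

Consecutive seconds are averaged, without overlap, into windows of the
**integration time** (default 15 s, i.e. 4 samples per one-minute
file): long enough to describe the ambient background, short enough to
retain punctual events such as boat passages.  Dimensions that are
constant over the whole dataset carry no information and are removed;
the survivors are robust-scaled (median/IQR per dimension) so that
no band dominates the distance computations through its variance.

The default stage order is aggregate → prune → scale.  The reverse
order (prune and scale the per-second embeddings, then aggregate) is a
defensible alternative and is available through
`build_features(order = "prune_scale_first")`; the two orders are not
numerically equivalent, and a regression test pins that fact.

### The projection ensemble

The scaled feature matrix is reduced to `n_components` dimensions
(default 3) with UMAP.  UMAP is stochastic: two runs differ, and any
metric read off a single embedding inherits that run's noise.  The
package therefore repeats the projection `n_repeats` times (default
100) under seeds `base_seed + 1, …, base_seed + N`, computes each
repeat's pairwise Euclidean distance matrix, and averages the matrices
elementwise.  Every downstream metric — silhouettes, clustering,
trajectories — consumes this **averaged distance matrix**, not any
single embedding.  A deterministic PCA projection is available as an
alternative (`projection = "pca"`), in which case a single repeat
suffices and the ensemble collapses to it.

Diagnostics quantify when the average has stabilised and what the
reduction preserved:

* the **convergence series**: relative mean and maximum absolute
  elementwise differences between consecutive running averages
  (normalised by the mean off-diagonal entry of the previous running
  average — the notion of "relative" is a package convention, stated
  here because it fixes the scale of the series).  For independent
  repeats these decay like $1/\sqrt{n}$;
* the **IQM** (interquartile range of the pairwise distances divided by
  their median), a scale-free measure of distance contrast; comparing
  the IQM of the averaged matrix with the IQM of the raw
  high-dimensional distances shows whether the projection relieved the
  concentration of distances that high-dimensional spaces suffer from;
* **DLP** (degree of local preservation): the mean fraction of
  k-nearest neighbours shared between the feature space and the
  embedding.  The package defines it as
  $\frac{1}{n}\sum_i |kNN_{high}(i) \cap kNN_{low}(i)|/k$ with
  Euclidean neighbourhoods and the point itself excluded — the name is
  used in the dimensionality-reduction literature without a canonical
  formula, so this definition is declared, not inherited;
* **RTA** (random triplet accuracy): the fraction of uniformly sampled
  triplets $(i; j, k)$ whose ordering
  $\mathrm{sign}(d(i,j) - d(i,k))$ agrees between the two spaces;
  deterministic given a seed.  Identity embeddings score 1.0 on both;
  independent random embeddings score $k/(n-1)$ and 0.5 respectively,
  which the test suite checks by Monte Carlo.

### Label separation: pairwise silhouettes

For a categorical label, every unordered pair of categories receives a
silhouette index computed on the averaged distance matrix restricted to
the two categories: for sample $i$, $a(i)$ is the mean distance to its
own category (self excluded), $b(i)$ the mean distance to the other
category, $s(i) = (b - a)/\max(a, b)$, and the index is the mean of
$s(i)$ over the samples of **both** categories (the literature also
contains one-sided variants; the symmetric mean is the package's
choice, and makes the matrix exactly symmetric).  Values near 1 mean
the two categories occupy distinct regions of acoustic space; values
near 0 mean they are indistinguishable.  Slightly negative values can
occur and are reported unclamped.  Ties with $a = b = 0$ (duplicate
points) score 0.

### Unsupervised structure: HDBSCAN and contingency

HDBSCAN runs directly on the averaged distance matrix: core distances
at the `min_samples` neighbour rank, mutual-reachability graph, minimum
spanning tree, single-linkage hierarchy, condensation at
`min_cluster_size` (default 100), and cluster selection by excess of
mass (`"eom"`, coarser) or hierarchy leaves (`"leaf"`, finer).  Samples
too isolated for any cluster keep the label −1.  `min_samples` defaults
to `min_cluster_size`, the convention of the reference implementations
of the algorithm, and is recorded in the result.  Cluster ids are
renumbered by descending size for stable reporting.  On the example
campaign the two selection modes illustrate their intended trade-off:
leaf reliably resolves all three planted site types, while excess of
mass, optimising stability mass, sometimes reports the two quiet-like
sites as one cluster; site-recovery summaries therefore read the leaf
classification.  Each clustering is
compared with each predefined label through a contingency matrix of row
percentages: the composition of every unsupervised cluster in terms of
the label's categories.

### Temporal trajectories

Within each embedding of the ensemble, a group's (typically a site's)
**reference point** is the centroid of its first-time-window samples
pooled across replicates — a shared per-site anchor, computed
independently inside every repeat because absolute UMAP coordinates
carry no meaning across repeats.  Each sample's Euclidean distance to
the reference is divided by the mean distance from the reference to its
`k` nearest sample points (default `k` = 100, reduced and recorded when
fewer samples exist).  This ratio is scale-free: multiplying an
embedding's coordinates by any constant leaves it unchanged.  Per time
point, the median and the first and ninth deciles over the `N` repeats
are reported.  Trajectories start near zero by construction, hover
around one while the soundscape resembles its starting state, and
spike when it departs — a rain shower or a passing boat pushes the
excursion well above the band.

## The synthetic reef generator

Because no public reef recordings ship with the package, a synthetic
campaign generator provides ground truth.  It emulates, at the level
of their spectral signatures rather than of any species' call: snapping
shrimp (Poisson trains of ≤2-ms broadband transients, default 50
snaps/s, tripled at night), fish choruses (pulse trains of 3–8 short
tone bursts confined to a sub-kilohertz band), boat passages (broadband
noise plus engine harmonics over declared intervals), rain (broadband
masking noise), and a permanent low-level water background.  Scenes are
additive, peak-normalised, and fully deterministic per seed; campaigns
follow the canonical duty cycle — one 1-minute file every 10 minutes
from 12:05 to 12:05 the next day inclusive, 145 files per site-day —
with site/replicate/period labels written to a metadata CSV the reader
consumes verbatim.  Day/night is a fixed 06:00/18:00 split; real
campaigns would use actual sun times, but for synthetic truth the fixed
split is sufficient.

`example_reef_campaign()` is the packaged study system: a `quiet`
reference site, a `quiet_variant` site representing a nearby reef in a
similar state (about twice the snap rate and a slightly shifted fish
chorus band — different enough to cluster apart, far more similar to
`quiet` than a motorised site is), and a `boat` site identical to
`quiet` but under continuous motor noise.  A rain shower occupies the
middle third of the last day at the quiet site.  These parameters were
fixed once, at design time, to realise that intended ordering of
contrasts; the reduced default (one simulated hour per site-day, 7
files each) keeps a full pipeline run on the three sites within a few
minutes on one CPU.

What the generator does **not** emulate: propagation and depth effects,
realistic species call libraries, tides, wind, chorus seasonality, or
recorder self-noise.  Passing tests on synthetic campaigns therefore
demonstrate that the pipeline recovers planted structure of the kinds
listed above — not that any particular field dataset will organise as
cleanly.

## Numerical conventions and edge cases

* Mel scale: HTK formula $m = 2595\log_{10}(1 + f/700)$; triangular
  unit-peak filters; Hann window; frames left-aligned at hop multiples
  with the final window zero-padded.  These are declared conventions —
  several dialects exist and band energies are only reproducible
  bit-exactly under a stated one.
* Log energies are floored at $\varepsilon = 10^{-12}$ (relative to
  full-scale-1 waveforms) before the natural log, so silent segments
  map to $\log \varepsilon$ rather than $-\infty$.
* Quantiles everywhere (robust scaling, IQM, trajectory deciles) are
  linear-interpolation (type 7) quantiles; IQR values depend on the
  convention, so it is pinned.
* Robust scaling falls back to range scaling for a non-constant column
  whose IQR is zero (e.g. a heavily floored band), and flags it.
* The high-pass filter runs as a cascade of four second-order sections
  with steady-state initial conditions; a single direct-form
  realisation of order 8 at 70 Hz / 44.1 kHz is numerically
  ill-conditioned.  Forward-backward application squares the magnitude
  response and cancels the group delay.
* UMAP hyperparameters other than the dimensionality keep the
  underlying implementation's defaults (`n_neighbors` 15, capped at
  n−1; `min_dist` 0.1) and are recorded in the ensemble object.
* Recordings shorter than one segment yield no samples (not an error);
  mixed sample rates, non-mono files and missing paths are errors that
  name the offending row.
* HDBSCAN on fewer samples than `min_cluster_size` returns all −1.
* Problem sizes in the test suite are chosen for depth per second of
  runtime: oracle checks run on ≤10-point hand instances, Monte-Carlo
  anchors on a few hundred points, and the end-to-end check on the
  reduced example campaign (63 one-minute files, 252 samples, 20 UMAP
  repeats, minimum cluster size 20).

## Known limitations

* The averaged distance matrix is an average of metrics and hence a
  metric, but it is not in general realisable as a point configuration
  in the projection dimensionality.
* Silhouette indices are computed pairwise on the two categories in
  isolation; they do not account for the remaining categories'
  geometry.
* The trajectory reference pools replicates; a site whose replicates
  start in genuinely different acoustic states will show an inflated
  starting spread rather than separate anchors.
* The CNN adapter route truncates each second to 0.96 s by design;
  the residual 0.04 s is ignored, matching the common pretrained-CNN
  framing convention.
* `run_soundscape()` holds all `N` embeddings in memory
  (`n × n_components × N` doubles) plus one `n × n` matrix; campaigns
  of several thousand samples fit comfortably, but the per-repeat
  distance computation is O(n²).
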