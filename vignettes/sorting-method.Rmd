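---
title: "How rastermapr sorts neural population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How rastermapr sorts neural population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rastermapr)
```

## The problem

A raster plot of a large neural recording is only as informative as its row
order. `rastermapr` computes a one-dimensional embedding of the rows
(neurons, or trials) of an activity matrix such that neighboring rows have
similar activity, so that population patterns — sequences, co-active
ensembles, stimulus responses — appear as contiguous structure. The same
machinery doubles as a benchmarked 1-D embedding method: the package ships
synthetic populations with known latent structure and metrics that score
any ordering against that ground truth.

## The model, step by step

**Normalization.** Each neuron's trace is z-scored so the embedding fits
trace *shape* rather than firing-rate statistics; the across-neuron mean at
each timepoint is then projected out (`mean_time`), removing global
co-fluctuations (skip this when the population average is itself of
interest, or when sorting trials). An optional `time_bin` averages
consecutive timepoints; it is worth using whenever single-bin counts are
low, because Poisson noise attenuates all pairwise correlations
multiplicatively. z-scoring uses the population (1/T) variance so that the
zero-lag similarity of two z-scored traces is exactly their Pearson
correlation.

**Reduction.** The normalized matrix is reduced to its top `n_PCs` left
singular vectors, each scaled by its singular value, which preserves
inter-neuron inner products up to truncation. The decomposition is exact:
direct SVD when the smaller dimension is at most 512, otherwise an
eigendecomposition of the smaller cross-product matrix, which is orders of
magnitude cheaper than a full SVD at recording scale and fully
deterministic. 100–400 components are typical; the truncation acts as
denoising.

**Scaled k-means.** Neurons are grouped into `n_clusters` (default 100)
clusters under the model `x_i = lambda_i * mu_{sigma_i} + noise`: each
neuron carries an amplitude `lambda_i`, so membership reflects trace shape,
not gain — neurons lying on a common direction with different amplitudes
share a cluster, which plain k-means would split. Assignment uses the
per-pair optimal scale, centers are re-estimated as scale-weighted
least-squares means; both steps are exact coordinate descent, so the summed
squared residual never increases. Initialization is k-means++ under a user
seed (the only stochastic element of the whole pipeline); an emptied
cluster is re-seeded from the worst-explained neuron. With fewer than 200
rows and `n_clusters = NULL` clustering is bypassed and rows sort directly.

**Asymmetric similarity.** Cluster traces (z-scored means of member
activity) are compared by lagged cross-correlation over non-negative lags
`0..time_lag_window`, keeping the maximum. `S[i, j]` is large when trace
`i` *leads* trace `j`; the asymmetry is what lets the sorter lay sequences
out in temporal order. Lags use truncated overlap with a fixed `1/T`
normalization (no wraparound), so a trace delayed by `d` peaks at
`(T-d)/T`. The matrix diagonal is ignored by the sorter.

**Matching matrix.** The target pattern for the sorted similarity mixes a
global term `-log(|x_i - x_j| + 0.001)` (`x_i = i/N`), whose eigenvalues
decay approximately as a power law with exponent 1 — matching the
long-tailed correlation spectrum of cortical population activity — and a
local Gaussian term with sd `1/(2N)`, essentially a travelling-salesman
bonus for placing the most-correlated clusters adjacent (its first
off-diagonal is `exp(-2)`, second `exp(-8)`). Both terms have zero
diagonal, their strictly lower triangles zeroed (forcing forward
sequences), and are normalized by their mean over all `N^2` entries (the
upper-triangle mean is available as an option). The `locality` weight `w`
mixes them; 0.75–0.8 suits task data with sequences, 0 favors global
structure. Callers may supply their own matching matrix; it only needs to
be strictly upper triangular.

**Sorting.** The cluster order maximizes
`sum M[i, j] * S[perm[i], perm[j]]` by greedy ascent over moves of
contiguous segments: all moves of length-`L` segments to every other
position are evaluated (starting `L = 1`), the single best improving move
is applied and `L` resets; when no length-`L` move improves, `L` grows.
Every such move is a swap of two adjacent blocks, which the implementation
(C++) evaluates with an incremental scheme: sliding a fixed-shape swap one
position changes the candidate positions of exactly three nodes, so each
candidate costs O(N) after the first on its diagonal, O(N^3) per sweep in
total. Two design points were settled empirically:

* *Reversed insertions.* With forward-only moves the greedy stalls in
  genuine local optima on roughly a quarter of small random instances
  (verified by exhaustive neighborhood checks). Testing each moved segment
  in both orientations removes most stalls; it is enabled by default when
  at most 30 positions are movable, and worth enabling (`reverse_segments
  = TRUE`) up to a few hundred clusters — a reversed sub-chain cannot
  otherwise rejoin its parent chain in the correct orientation.
* *Multi-start.* When no initial ordering is supplied, the optimizer runs
  from the identity, from the ordering by the leading eigenvector of the
  symmetrized similarity, and from its reversal, keeping the best final
  score. All three starts are deterministic. In the pipeline the start is
  the first-singular-vector ordering of the cluster centers.

For `N` clusters a coarse pass first sorts every `(skip+1)`-th node of the
initial ordering (`skip = floor(N/30)`), with the matching matrix
subsampled at the same stride; skipped nodes re-enter next to their nearest
sampled neighbor and a full-resolution pass refines. Sorting 100 clusters
takes a few seconds on one core. The optimizer is deterministic given its
inputs, never returns a score below its start, and verifies every applied
move against a full rescore (so accumulated floating-point drift cannot
push the score downward).

**Upsampling and item positions.** The sorted centers are upsampled 10x by
weighted locally linear regression: at each position on the fine grid a
linear map from sorted index to feature space is fitted over the 50
nearest clusters with Gaussian weights (sd `1/sqrt(2)` index units) and
evaluated there. Each neuron is then assigned to the upsampled node whose
feature vector correlates best with its own (ties to the lower index;
zero-variance feature vectors fall back to dot products), giving a
continuous position in `[0, 1)`; the row order is the stable sort of the
positions. Assignment uses feature space rather than raw traces — features
preserve activity correlations up to truncation and the comparison costs
`n_PCs` rather than `T` per pair.

**Splitting.** For data whose latent dimensionality exceeds 1, a 1-D
embedding follows a space-filling curve, and resolution can be raised by
`n_splits` rounds of refinement: the sorted cluster sequence is cut into
four contiguous blocks, each block's neurons are re-clustered into twice as
many clusters, and each block is re-sorted with up to 25 flanking context
clusters on each side held fixed, so block boundaries stay continuous
(three splits: 100 -> 800 clusters). Block sorts cap the tested segment
length at 30 — moves longer than the block core are already covered by the
coarse pass — and derive their seeds from the pipeline seed. Splitting
improves neighbor preservation at small neighborhood sizes and leaves large
ones unchanged; it does not make the space-filling curve itself more
interpretable.

**Superneurons.** For display, consecutive groups of `bin_size` sorted
rows are averaged; adjacent rows are similar by construction, so the
averages denoise without blurring structure. A trailing remainder smaller
than the bin is dropped.

## The synthetic benchmarks

Three generators produce populations with known ground truth; all
randomness derives from a single integer seed and the same seed reproduces
a dataset bit-for-bit.

**Multi-module benchmark** (`generate_benchmark_simulation`). Five
one-dimensional modules: two *sequence* modules (1,000 neurons each at
full scale) whose neurons activate at latent positions along a repeating
traversal — repetitions of 350–700 timepoints, gaps of 100–200, per-repetition
variable velocity (unit base velocity plus Gaussian noise smoothed with a
30-timepoint Gaussian, amplitude 0.5), and a 50% chance per repetition of a
50–150 timepoint mid-sequence pause; a *tuning* module (1,000) with
Gaussian tuning on a 1,500-position axis, 15 equally spaced stimuli, 500
presentations 100 timepoints apart, responses decaying with a 25-timepoint
timescale; a *sustained* module (1,000) responding to a single stimulus
with difference-of-exponentials filters whose 100 timescale pairs
interpolate geometrically from (25, 5) to (304, 61), inter-stimulus
intervals exponential (decay 750, minimum 2,000); and a *power-law* module
(2,000) built from cosine spatial modes `cos(pi k x)` in a per-neuron
latent `x` with covariance eigenvalues `k^-1.5` and temporal factors made
from a sparse Boolean sequence smoothed by a 25-timepoint exponential. The
power-law activity is added to *every* neuron with weight 0.75, rates are
scaled per neuron by an exponential draw, spikes are Poisson, and
independent Poisson noise of mean 0.03 per bin is added. Full scale is
6,000 neurons by 50,000 timepoints (fixed by the 500 x 100 stimulus
schedule); `scale` shrinks both proportionally while preserving the
1:1:1:1:2 module ratio.

Constants the construction leaves open were calibrated once, against the
qualitative target that the modules are recoverable by the method at its
standard parameters, and then frozen: sequence place-field width 0.05 and
tuning-curve sd 0.15 (both in axis units — narrower fields make the
similarity range shorter than the inter-cluster spacing, leaving the module
chains without glue at any noise level); Boolean density 0.03; power-law
amplitude anchored so the mean per-neuron peak is 1 before the 0.75
weight, putting it on the same unit-peak scale as the module responses;
and a peak spike count of 6 per bin for a unit-amplitude response (a
place-field peak of a few spikes per 100–300 ms bin). All are exposed in
`params`.

**Power-law-only benchmark** (`generate_powerlaw_simulation`): the same
power-law construction with exponent 1, 6,000 neurons at full scale; the
ground truth is each neuron's `x`, so recovery is summarized by the
absolute Spearman correlation between embedding and truth.

**2-D place fields** (`generate_2d_simulation`): each neuron gets `(x, y)`
in the unit square; left singular vectors are the 900 products
`cos(pi kx x) cos(pi ky y)` over a 30 x 30 frequency grid, singular values
`(kx^2 + ky^2)^-0.5`, temporal factors white Gaussian, additive noise
`5e-3`, no spiking step. This is the stress test where a 1-D sort must
follow a space-filling curve.

What these simulations do *not* emulate: calcium-indicator dynamics and
deconvolution artifacts, behavioral covariates, non-stationarity, or
correlated (non-Poisson) noise. Passing the benchmarks shows the machinery
orders latent 1-D structure correctly under Poisson noise and a shared
low-dimensional background; it does not certify performance on any
particular real recording.

## The quality metrics

* `triplet_score` — fraction of within-module item triples whose relative
  order matches the ground truth; orientation-invariant by default (an
  embedding has arbitrary sign), so a random ordering scores 1/3. The
  strict variant is returned as an attribute.
* `contamination_score` — for within-module pairs, the percentage of items
  strictly between them in the embedding that belong to another module;
  0% means contiguous modules, perfectly interleaved modules give ~50%.
* `knn_preservation_score` — fraction of each item's k nearest neighbors
  in ground-truth space (1-D or 2-D, Euclidean) kept among its k nearest
  embedding neighbors, on a subsample (default 2,000) for tractability; a
  random embedding scores about `k/(n-1)`.
* `embedding_quality_scores` — ground-truth-free scores on the sorted
  similarity matrix: the fraction of first-off-diagonal entries that are
  their row's off-diagonal maximum (local), and the upper-triangular dot
  product with the matching matrix normalized by the matching matrix's
  upper-triangular mean (global). "Largest possible" is read row-wise;
  the global-maxima reading is available via `local_mode`.
* `groundtruth_correlation` — |Spearman| against a scalar latent, for
  single-module data.

Orderings produced by other tools (t-SNE, UMAP, ...) can be scored by
reading them with `read_external_ordering`; the package deliberately does
not run those methods itself.

## Numerical choices and degenerate inputs

Zero-variance rows z-score to all-zero rows (guard `1e-10` on the sd);
filtering silent neurons is the caller's job. Empty clusters re-seed from
the worst-explained item during fitting and yield all-zero traces (with a
warning) during trace extraction. Ties in item assignment break toward the
lower node index, and the final row order is a stable sort, so equal
positions preserve input order. The optimizer applies a move only if a
full rescore confirms improvement, and move-gain ties break toward the
first candidate in a fixed enumeration order — with a fixed seed the whole
pipeline is bit-reproducible. Matching-matrix construction requires
`N >= 2`; the lag window must be shorter than the trace; brute-force
ordering refuses more than 9 nodes (9! permutations).

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at desk scale: the multi-module
benchmark at scale 0.3 (1,800 neurons x 15,000 timepoints, three seeds),
the power-law benchmark at 1,000 neurons x 10,000 timepoints (three
seeds), the 2-D benchmark at 3,000 neurons x 5,000 timepoints with zero
and three split rounds (three seeds), and the composition of the
full-scale (6,000 x 50,000) multi-module dataset. Those sizes keep a full
run in the tens of minutes on a single core while leaving every
qualitative conclusion (sequence recovery, module contiguity, power-law
ordering, splitting benefit) intact.

## Known limitations

One-dimensional sorting cannot represent intrinsically higher-dimensional
structure except as a space-filling curve; splitting sharpens local
neighborhoods but does not change that. The greedy optimizer, though
rarely, can stall short of the global optimum. Orientation of the final
embedding is arbitrary (use `flip_if_reversed` with a covariate when a
canonical direction matters), and the benchmark metrics are accordingly
orientation-invariant. The scaled k-means initialization is the single
seeded step: different seeds can yield visibly different (similarly
scoring) sortings on real data.
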