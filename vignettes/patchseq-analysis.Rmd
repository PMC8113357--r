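---
title: "Multimodal Patch-seq analysis: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal Patch-seq analysis: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchseqr)
```

Patch-seq characterizes the same neuron three ways: current-clamp
electrophysiology, single-cell RNA-seq, and a biocytin-based
morphological reconstruction. `patchseqr` implements the analysis chain
that links these modalities and ships synthetic generators for all
three, so that every quantitative step can be validated against planted
ground truth. This vignette records the models, the parameters that
matter, and the design decisions taken where the methodology left
genuine freedom.

## Electrophysiological feature extraction

### The recording model

A cell is represented as a `sweep_set`: one voltage trace per injected
current step of a square-pulse protocol. The default
`stimulus_protocol()` uses a 600-ms pulse with onset at 0.1 s, currents
from −200 pA upward in 20-pA increments, and at least 0.3 s of recorded
time after offset (the rebound analysis window). Voltages are in mV,
currents in pA, resistances in MΩ (so R = ΔV/I needs a factor 10³),
time constants and widths in ms.

### Detection criteria

Spike detection is threshold-based: an AP is a local voltage maximum
above −20 mV whose preceding 10 ms contain a depolarization faster than
20 V/s; the AP threshold is the nearest upward crossing of that dV/dt
criterion before the peak. These two constants are the conventional
defaults for current-clamp analysis of cortical neurons at room
temperature; both are exposed as arguments of `detect_spikes()`. The
fast trough is the voltage minimum within 5 ms of the peak (or up to
the next AP threshold, whichever comes first); the afterdepolarization
is a bump above the fast trough within 10 ms that is followed by a
decline, with a 0.2-mV detectability floor so that sampling noise does
not register as an ADP.

### Features and their edge rules

Passive features (resting potential, input resistance, time constant)
are medians over all hyperpolarizing sweeps, repeats included as
separate observations. The time constant comes from a nonlinear
least-squares fit of $V(t) = A e^{-t/\tau} + C$
(`minpack.lm::nlsLM`, analytic starting values from the 1/e crossing)
between stimulus onset and the first local minimum of the 5-ms-smoothed
trace; when the trace has no interior minimum (no sag) the fit window
extends to the offset. Note that on sweeps with a pronounced sag the
single-exponential model is only an approximation over that window —
this is inherent to the definition, not a numerical artifact.

Rheobase fits spike count against current over the five lowest spiking
currents. The robust fit is an exhaustive consensus variant: every
pair of points defines a candidate line, lines are scored by their
inlier count at a 1-spike residual threshold, and the best consensus
set is refit by least squares. With at most five points this is
exact, deterministic, and needs no random sampling. The x-intercept is
clamped to the interval between the highest zero-spike current and the
lowest spiking current, falling back to the latter when the line
crosses outside.

Zeroing rules produce *exact* zeros, never small floats: sag time and
area are 0 when trough and steady state differ by less than 4 mV;
rebound is 0 when the voltage never regains the resting potential
within 300 ms of offset; wildness is 0 when no sweep fires outside the
stimulation window. All other undefined features propagate as `NA`.
The sag trough index is taken as the midpoint of the arg-min set, so a
flat trough is measured at its centre rather than its edge.

Burst analysis classifies each inter-spike interval as *detour* (the
preceding AP has a non-zero ADP, or the voltage falls at least 0.5 mV
below its fast trough before the next AP) or *direct*, with *pauselike*
intervals — longer than 3× the trace median ISI, a configurable
multiple since the upstream convention is not pinned numerically —
disqualifying a burst. A burst begins at a detour→direct transition and
spans the following run of direct ISIs.

The 17-feature analysis vector retains resting potential, input
resistance, rheobase, AP threshold/amplitude/width, AHP, latency, UDR,
ISI and amplitude adaptation, maximum AP count, τ, sag ratio, rebound,
and the ISI and AP CVs, log-transforming (natural log) the AP CV, ISI
CV, ISI adaptation index and latency to make their distributions more
Gaussian. Cells with any missing or non-positive-before-log entry are
flagged incomplete and excluded from analyses that need full vectors.

### The synthetic trace generator

`generate_sweep_set()` composes, per current step: a single-exponential
charging response with the planted τ; on hyperpolarizing steps an
alpha-function sag excursion (peaking at `sag_tau_ms`) and a
post-offset exponential relaxation to a rebound plateau, both scaled
linearly with the current so the most negative step carries the full
planted amplitude; stereotyped AP waveforms at planted spike times;
and white Gaussian noise. The AP template is piecewise analytic —
linear upstroke at the planted dV/dt, linear downstroke through the
fast trough, optional ADP bump, exponential relaxation — so that each
shape feature has a closed-form true value. Two consequences worth
knowing:

* With linear up- and downstrokes, the half-width is a deterministic
  function of amplitude and the two slopes. `ap_template()` therefore
  derives the downstroke slope when a half-width is requested (and
  vice versa); the two cannot be planted independently.
* Between spikes the trace relaxes to a plateau 1 mV above the fast
  trough, holds it for 100 ms, and then decays back to the passive
  baseline. This keeps the inter-spike minimum at the planted trough
  (so AHP and direct/detour classification see the planted shape) and
  lets long ISIs dip below the trough, which is exactly what makes
  them classify as detour — mirroring the sagging inter-burst
  trajectories of bursting neurons.

The generator emulates feature geometry, not biophysics: there are no
conductances, no threshold dynamics, no spike-rate adaptation emerging
from the model. Passing tests therefore certify the *extraction
machinery* (windows, medians, fits, zeroing rules, tie-breaks), not the
behaviour of the extractor on pathological real recordings (electrode
drift, seal degradation, partial spikes), which it does not simulate.
Ground-truth tests run at 20 kHz with template breakpoints on the
sample grid; tolerances are one sample period for widths and latencies,
2% for fitted time constants, and exact equality for ratios and
zeroing rules.

## Transcriptomic t-type mapping

### Normalization and gene selection

Read-based counts are normalized as
$\log_2(\mathrm{exon}/\ell_e + \mathrm{intron}/(\ell_i + 10^{-6}) + 1)$
with lengths in kb; the 10⁻⁶ guards intronless genes. UMI counts are
log-transformed without length normalization. Variable-gene selection
excludes genes with counts ≥ c_min in fewer than 10 cells
(c_min = 32 for read-based data, 0 for UMI), computes per gene the mean
log₂ expression μ over counts above c_min and the near-zero fraction τ,
and binary-searches the offset *b* for which exactly the requested
number of genes satisfies τ > exp(−1.5 μ + b) + 0.002. Because the
selected count is monotone in *b*, 200 bisection steps over
b ∈ [−60, 60] resolve the boundary far below the spacing between genes;
when ties make the exact target unattachable the nearest achievable set
is returned with a warning. Both boundary clauses are inclusive as
written (a count equal to c_min is "near-zero" and also satisfies
"at least c_min" for eligibility).

### Two-round assignment

Round 1 maps every query cell against a combined annotated atlas
(centroids = mean log expression per type over that atlas's variable
genes) by Pearson correlation and applies three exclusions: best
correlation below 0.4; best-correlated type non-neural; margin over the
best correlation in each other transcriptomic group (CGE, MGE,
excitatory) below 0.02. Round 2 maps each passing cell to every
reference atlas, restricted to the t-types of the cell's group and that
atlas's 500 most variable genes for the group, and derives a confidence
vector from 100 gene bootstraps (resampling genes with replacement at
full set size). Per-atlas confidences are averaged unweighted into the
consensus; the cell takes the arg-max type. All arg-max ties break
toward the first type in atlas order — a deterministic convention that
matters only for exactly tied correlations, which occur with duplicated
centroids but not in practice. Each cell draws its bootstrap stream
from an independently derived seed, so cells can be processed in any
order (or in parallel) without changing results.

The round-1 margin rule is evaluated on the same variable-gene set used
for the round-1 correlations, the natural reading since all round-1
correlations come from one combined atlas.

### The synthetic expression generator

`atlas_spec()` plants per-type centroids in log₂ space (a shared
baseline plus type-specific shifts of magnitude `type_separation`),
negative-binomial counts with per-cell log-normal library-size scaling,
a per-gene binomial exon/intron split, and family/group/neural
annotations; `generate_expression_bundle()` draws reference atlases and
read-based query cells from them. It emulates overdispersed counts and
the exon+intron normalization path; it does not emulate batch effects,
contamination, platform-specific gene detection biases or dropout
beyond what the NB model produces. Parameter-recovery tests plant a
between-centroid correlation distance of at least three times the
within-type noise — verified inside the test — and require ≥95%
assignment accuracy under those conditions.

## Morphology

SWC trees are validated (single root, acyclic, connected),
soma-centred in x (slice width) and y (slice depth), and aligned so
z = 0 is the pia, with the soma placed at its measured normalized
depth; nodes below the white-matter border are kept with a warning.
Neurites are smoothed in y only, with a Savitzky–Golay filter of order
3 and window 21 applied to each unbranched path after resampling to
≤ 1 µm spacing; shorter paths are mirror-padded (the filter is defined
only for window-length signals), and smoothed values are mapped back to
the original nodes by arc-length interpolation, leaving the topology
and the x/z coordinates bit-identical.

The z-profile is the 20-bin histogram of the compartment's resampled
point cloud over normalized depth [0, 1] (half-open bins, last bin
closed, depths clamped), normalized to unit mass. Mass is point-count
weighted; since points are resampled to ≤ 1 µm spacing this
approximates arc-length weighting to within the resampling tolerance,
and the vectorized binning is tested for exact equality against a
per-point loop. Morphometrics are computed per compartment from a
registered catalogue (total length, branch points, tips, branch order,
path/Euclidean extents, width/height log-ratio, branch-length
statistics, tortuosity, bifurcation angles, somatic features, apical
subtree statistics for excitatory cells — apical being the dendrite
with the longest total path length — and axon–dendrite overlap for
inhibitory cells). The catalogue is a representative set, deliberately
pluggable so an authoritative feature list can replace it; no feature
measures the y direction, where slice shrinkage (not corrected for)
would distort values. The CV filter drops features with coefficient of
variation below 0.25 among all-positive features only. Layer
boundaries default to 0.07 / 0.29 / 0.73 with boundary ties going to
the deeper layer.

The synthetic generator samples node depths directly from a planted
20-bin profile and links them into branches attached at the
nearest-depth interior node. Realized profiles match the planted ones
up to binning error plus the mass of the connecting edges — for
profiles with disjoint lobes, a tree must cross the gap, so a small
amount of planted-zero mass appears between lobes; tests budget for
this explicitly.

## Sparse reduced-rank regression

The model predicts the 17 standardized electrophysiological features Y
from standardized log-CPM expression X of the most variable genes
(1,000 by default, selected on raw exonic counts):
$Y \approx X W V^\top$ with $V^\top V = I_r$ and an elastic-net penalty
on rows of W, so that whole genes are selected. Fitting alternates two
exact subproblems: for fixed V, W solves a multi-response elastic-net
regression of YV on X (glmnet's grouped multi-Gaussian family,
per-observation penalty normalization, `thresh = 1e-12`; at λ = 0 the
subproblem is solved by exact least squares instead); for fixed W, V is
the orthogonal Procrustes solution from the SVD of $Y^\top X W$. The
penalized loss is non-increasing across iterations; iteration stops at
a relative loss change below 10⁻⁶ (tightenable) or 100 iterations. V is
initialized from the top right singular vectors of $Y^\top X$, with a
seed-controlled jitter only when the trailing singular values are
degenerate. α = 1 is pure lasso. At λ = 0 and full rank the fit agrees
with the closed-form reduced-rank solution (OLS projected on the top
principal axes of its fitted values) to 10⁻⁶, which the tests verify
against `rrr_closed_form()`. An unpenalized refit on the selected
support is deliberately not performed by default; `rrr_tune_lambda()`
implements the convention of tuning λ to a target gene count by
bisection. Cross-validation reports test R² = 1 − ‖Y − XWVᵀ‖²/‖Y‖²,
mean selected-gene counts and per-component test correlations over 10
folds. Biplot correlation tables mask variables whose correlation
vector with the first two latent dimensions is shorter than 0.4 — the
circle-radius display convention.

## Representations, embeddings and classification

The electrophysiological representation standardizes the complete
17-feature vectors, applies PCA (signs fixed so each loading's
largest-magnitude entry is positive, making results reproducible), and
divides all PCs by the standard deviation of PC1. The full 17 PCs are
kept for electrophysiology-only analyses and 16 for the combined
morpho-electric stack; the retained count is a parameter because the
two usages differ, and the combined convention of 48 + 16 = 64 columns
is preserved. The morphological representation is built per cell class
(dendritic z-profiles for excitatory cells, axonal for inhibitory):
20 morphometric PCs scaled by sd(PC1) plus z-profile PCs 2–5 scaled by
sd(PC2) — PC1 is discarded as a soma-depth surrogate — assembled
block-diagonally into 48 columns with +0.25 added to the excitatory
block to separate the populations. The combined representation
multiplies the electrophysiological block by √2 so its total variance
matches the two morphological PC sets.

t-SNE is consumed as an external optimizer with a pinned contract
(perplexity 30 by default, early exaggeration 4, learning rate n/12,
scaled-PCA initialization at sd 10⁻⁴, fixed random seed); the default
engine shells out to scikit-learn's implementation through the `python`
interpreter, and any function with the same signature can be
substituted. Query cells are positioned on a reference embedding
without running an optimizer: each lands at the coordinate-wise median
of its ten nearest reference neighbours by Pearson correlation
distance in the shared log-expression space. Family classification is
leave-one-out kNN with k = 10 and Euclidean distance; majority ties
break to the single nearest neighbour's family (deterministic, and the
natural limit of shrinking k). Confusion matrices are row-normalized
to percentages.

## Within-type variability

The normalized total variance of a type T is

$$\frac{\sum_j \frac{1}{|T|}\sum_{i \in T}\bigl(X_{ij} - \bar X_{\cdot j}^{T}\bigr)^2}{\sum_j \frac{1}{n}\sum_i \bigl(X_{ij} - \bar X_{\cdot j}\bigr)^2},$$

with population (1/|T|, 1/n) normalization: exactly 0 for a type of
identical cells and exactly 1 when the type is the whole data set, both
verified to 10⁻¹². As a homogeneity baseline, k-means (10 restarts,
seeded) partitions the same cells into K clusters — K the number of
qualifying types — and the min–max band of per-cluster normalized
variances is reported. Leiden clustering of the kNN graph (k = 10,
modularity quality function, equivalent to the RB-configuration
quality up to scaling) provides per-type entropies of cluster
membership after subsampling each type to ten cells, repeated 100
times; the resolution is binary-searched to a target cluster count ± 1
since the convention is a manually tuned resolution. Within-family
type-pair tables use 1 − Pearson r between centroid log expressions as
the transcriptomic distance — the correlation phrased as a distance
requires this conversion, which only matters up to monotone
transformation for the correlation analyses — Euclidean distance
between mean feature vectors, and absolute differences of mean
normalized soma depth, over types with at least five cells; pooled
Pearson correlations are reported with per-family values alongside,
and pooling uses raw (not family-standardized) distances.

## The pipeline

`run_patchseq_pipeline()` chains the stages on synthetic data from a
single seeded config: atlas and query generation, two-round mapping,
per-cell sweep synthesis and feature extraction, morphology synthesis
and profiling, representation building, kNN family classification and
variability statistics, with a provenance record (package version,
seeds, parameters). One master seed fans out to per-stage streams
through a fixed affine counter scheme, so reruns are bit-identical and
stages are independent of each other's consumption of random numbers.
Disabled modalities are skipped without affecting the others.

## Problem sizes and numerical tolerances

The test suite runs at deliberately desk-scale sizes chosen to exercise
every code path while keeping the full suite fast: sweep sets at 20 kHz
over ~26 current steps; atlases of 6–10 types × 25–30 cells × 400–800
genes; gene-selection clouds of 2,000 genes × 500 cells; RRR recovery
at n = 500 cells × 1,000 genes with a planted 10-gene support over 20
seeds; 100 random morphologies for the binning-oracle equivalence.
Scale-dependent statistics (bootstrap confidences, CV R², entropies)
are asserted with tolerances that reflect their sampling noise at
these sizes; analytic anchors (zeroing rules, variance statistic
anchors, oracle equivalences) are asserted exactly or to 10⁻⁶–10⁻¹².

## Known limitations

* The trace generator is phenomenological; extraction robustness to
  recording artifacts is untested by construction.
* NWB/HDF5 electrophysiology containers are not read directly; sweeps
  enter through the documented CSV sweep-table dialect or in-memory
  construction.
* The morphometric catalogue is representative, not authoritative;
  downstream PCs depend on which features are registered.
* Gene identity is matched by exact symbol; orthology or alias
  resolution is out of scope.
* The t-SNE engine is external; without a `python` interpreter the
  embedding step requires a user-supplied engine (all other stages are
  unaffected).
* Contamination modelling, manual curation of mis-assigned cells
  (supported only as a user-supplied exclusion list) and statistical
  tests of phenotypic continua are out of scope.
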