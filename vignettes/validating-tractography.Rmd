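---
title: "Methods: validating tractography connectomes against tract tracing"
author: "conntracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating tractography connectomes against tract tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conntracer)
```

## The measurement model

Two modalities observe the same underlying inter-areal connectivity over a
fixed, ordered set of cortical regions.

Retrograde tract tracing injects a tracer into a target area; the tracer
travels from axon terminals back to the cell bodies of projecting neurons,
which are then counted per source area. The raw observable is a *directed*
integer matrix `N` of labeled-neuron counts, one column per injection.
Because injections differ in uptake and size, counts are only comparable
after per-injection normalization: the fraction of labeled neurons

FLN(i, j) = N(i, j) / Σ_{i' ≠ j} N(i', j),

which makes each injected column sum to one over extrinsic sources
(`computeFLN()`). Self-connections are excluded everywhere. When a
direction-blind comparison is needed, FLN is symmetrized by averaging the
two directions (`symmetrize()`), which deliberately gives up column
stochasticity.

Tractography counts streamlines between region pairs. Streamline counts
scale with the seeding budget and with regional size and connectedness, so
they are normalized by fractional scaling: the fraction of streamlines

FS(i, j) = S(i, j) / (Σ_{k ≠ i} S(i, k) + Σ_{k ≠ j} S(j, k)),

symmetric and invariant under `S → cS` (`fractionalScaling()`). The
denominator follows the definition literally: both regions' totals are
summed, so the pair's own count appears twice. Some fractional-scaling
implementations subtract the shared count once; that variant is available
as `subtractShared = TRUE` and changes nothing qualitatively.

## Association analyses

Connectivity weights are approximately lognormal in both modalities, so
`conntracer` quantifies agreement in two robust ways (`edgeSpearman()`,
`edgePearsonLog()`): midrank Spearman correlation of the paired edge
weights, and Pearson correlation of log-transformed weights. Absent
connections matter — a connection tracing finds but tractography misses is
evidence, not missingness — so zero-weight edges are retained; under
Spearman they form a tied block at the bottom of the ranking, and for the
log pathway every raw count is incremented by one *before* normalization
(`pseudocountLog()`), keeping all logs finite. The order
(pseudocount → normalize → log) is fixed; ranks need no pseudocount, so
Spearman analyses use the unperturbed normalized weights.

P-values use the t approximation (df = n − 2) appropriate for tables of 28
(symmetric) or 56 (directed) edges. An exact permutation p-value by full
enumeration is offered for very small tables (≤ 8 edges; enumeration is
factorial, and 8! = 40,320 keeps it instantaneous).

Confidence intervals come from a percentile bootstrap over edges
(`bootstrapCI()`): paired `(x, y, dist)` records are resampled with
replacement B = 10,000 times (default), and the interval is the empirical
2.5–97.5% range. Resamples with a degenerate (constant) vector are redrawn
and counted. The resampling unit is the edge; resampling regions instead
would be defensible but couples edges sharing a node, and with n = 8
regions leaves too few jackknife units to be useful. BCa corrections were
considered and rejected: at 28 edges the acceleration estimate is itself
noisy, and the package's own coverage simulation (500 bivariate-normal
tables, population Spearman 0.7, n = 28) shows the plain percentile
interval already attains nominal-range coverage.

Distance is the dominant shared confound: connection strength decays with
inter-areal distance in both modalities, so part of any raw correlation
reflects geometry, not fidelity. `partialSpearmanDistance()` regresses the
log weights of each modality on the Euclidean distance between region
centroids (OLS, intercept + slope), then Spearman-correlates the
residuals; its p-value uses df = n − 3. When distances are constant the
regression reduces to exact centering — computed directly as `x − mean(x)`
rather than through the QR decomposition, whose per-element rounding would
split exactly tied values and perturb ranks.

## Robustness and detection

`removalCurve()` ranks edges by the tracing weight only and drops the top
(or bottom) `ceiling(f · E)` edges from both modalities at each removal
fraction f (default grid 0–0.5 by 0.05, bracketing the 25%-removal
landmark usually inspected). A flat curve under strongest-removal means
the association is not carried by a few dominant, short connections; a
flat curve under weakest-removal means it is not degraded by noisy small
ones.

`detectionSweep()` asks the binary question: does tractography *find* the
connections tracing considers real? The tracing matrix is thresholded at
each density p ∈ {0.1, …, 0.9} (keeping `ceiling(p · E)` strongest pairs).
Two scoring modes are reported, because the natural recipe is genuinely
ambiguous: *matched* binarizes the prediction at the same density and
records one confusion tuple, while *sweep* thresholds the prediction at
every distinct predicted weight and averages sensitivity, specificity and
precision over the resulting ROC/PR series. Neither is privileged; both
appear in every report, and all underlying confusion tuples are stored so
the defining identities can be checked exactly.

Ties deserve a word: thresholding integer counts routinely puts tied
weights (especially zeros) on the cut. Ties are resolved by sorted
region-label pair — a fixed, documented order with no statistical content
— which also makes every downstream statistic invariant to the region
order of the input files. Edge tables are likewise emitted in canonical
label order, so even seeded bootstrap intervals do not depend on how the
input rows were sorted. A warning flags any cut that actually splits a
tied block, and the realized density is reported beside the requested one.

## The synthetic generator

`syntheticConfig()` / `generateGroundTruth()` / `sampleTracer()` /
`sampleTractography()` simulate the paired experiment. The ground truth
places n centroids uniformly in a cube and draws directed weights
w(i,j) = exp(N(μ, σ²)) · exp(−λ d(i,j)) for connected pairs: lognormal
strength with exponential distance decay, the two regularities both
modalities are believed to share. Observation then mimics each technique:
tracer counts per injection are multinomial with size M over incoming true
weights (a fixed number of labeled neurons per injection; columns sum
exactly to M), and streamlines are allocated multinomially over unordered
pairs with intensity ∝ w̄ · exp(−γ d) + ε · mean(w̄) — direction-blind,
attenuated with distance at rate γ (path-following failure accumulates
with length), with a unit-free false-positive floor ε. A Poisson
allocation mode replaces the fixed budget with independent counts of the
same means when budget exactness is not wanted.

Defaults live in one file (`inst/extdata/synthetic-defaults.yaml`) and
were chosen once as a realistic small inter-areal study: n = 8 regions
(an edge-complete visual-cortex subnetwork), μ = 0, σ = 1.5 (about three
orders of magnitude of weights), a 20 mm box with λ = 0.2/mm (three orders
of decay across the box diagonal), edge density 0.85 with reciprocity 0.8
(dense, highly reciprocal cortico-cortical connectivity), M = 10,000
labeled neurons per injection, T = 10⁶ streamlines, γ = 0.05/mm and
ε = 0.002 as mild observation noise.

What the generator does *not* emulate: spatial extent of injection sites,
laminar origin of projections, geometric fiber crossing (γ is a one-knob
abstraction of every length-dependent tracking failure), atlas
segmentation error, and any correlation between a pair's false-positive
propensity and its anatomy (ε is flat). Tests passing on this generator
therefore certify the statistical machinery, not tractography itself; the
false-positive floor in particular is an artifact construct for exercising
specificity, not an estimate of real tractography behavior.

## Reproducibility and numerical choices

Every stochastic stage takes a seed; the pipeline fans one top-level seed
out to fixed per-stage offsets, so `runValidation()` and
`simulateAndValidate()` are bit-reproducible and leave the caller's RNG
state untouched. Matrix orientation is fixed (rows = source, columns =
target/injected) and recorded in every file header. Nonzero diagonals are
zeroed with a warning rather than rejected, since both normalizations
exclude self-connections. An isolated region pair (both totals zero) gets
FS = 0 with a warning; an injection with zero labeled neurons is an error,
because FLN is uninterpretable there.

## A known ceiling, and other limitations

The package's own noise-free experiments expose a structural property
worth knowing: even with no observation noise at all (γ = ε = 0, exact
probabilities in place of sampling), the Spearman correlation between
symmetrized FLN and FS does not approach 1 — it plateaus around 0.92
under the default conditions. The reason is the normalizations themselves.
FLN divides by per-injection column totals; FS divides by the sum of both
regions' totals. The two implied node factors differ, and they permute the
ranks of edges whose weights are close. The effect *grows* with weight
heterogeneity (σ), because node totals become more variable. Agreement
between a tracing-normalized and a tractography-normalized connectome is
therefore bounded below 1 by construction, independent of data quality —
useful context when interpreting high-but-imperfect correlations on real
data, where the best achievable values sit in the same range. The
acceptance suite states the idealized ρ ≥ 0.99 recovery expectation
explicitly and records its failure; the unit suite verifies the true
property, that sampled estimates converge to this deterministic limit.

Other limitations: the distance regression is linear in distance on the
log scale (an exponential distance rule); no multiple-testing correction
is applied (raw p-values are reported); detection is defined over
unordered pairs only, since tractography carries no direction; and the
removal and density grids resolve to whole edges via `ceiling`, so on
small networks adjacent grid points can coincide.

Problem sizes used by the test suite — 28- and 56-edge tables, 500-table
coverage simulations at B = 1,000, 3×3 noise grids with 50 worlds per cell
— were chosen as the smallest sizes at which the distributional checks
have stable expectations; the shipped defaults (B = 10,000) are meant for
real analyses.
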