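---
title: "Merging small-wedge diffraction data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging small-wedge diffraction data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wedgemerge)
```

# The problem

Microcrystals tolerate only a short rotation range before radiation
damage destroys them, so a complete dataset is assembled from many
small wedges (1–30°), each integrated independently. The merging engine
must decide which wedges describe the same lattice, make their indexing
conventions consistent, identify which are isomorphous enough to merge,
put them on a common scale, and remove the frames and crystals that
would degrade the result. This vignette documents the models behind each
stage, their assumptions, the defaults, and the numerical choices.

# Lattice comparison

Every cell is reduced to its Niggli form with the Krivý–Gruber
algorithm, run on the metric tensor with comparisons stabilised by a
relative epsilon (`eps_rel = 1e-6`); the accumulated basis transform `M`
satisfies `t(M) %*% G %*% M = G_reduced`. Reduced cells are compared
component-wise: edges within `tol_len = 0.1` (relative) and angles
within `tol_ang = 3` degrees draw an edge in the similarity graph, and
connected components, sorted by population, become lattice groups.
Components below `min_group_size = 2` are reported separately — isolated
cells usually mean a misindexed wedge. The thresholds are deliberately
generous: cells from different microcrystals of one form scatter by a
few tenths of a percent, while truly different lattices differ by far
more than 10%.

Metric symmetry is found by searching integer matrices with entries in
[−2, 2] and det = +1 that preserve the reciprocal basis-vector lengths
(relative tolerance `tol`) and the cosines of the reciprocal angles
(absolute tolerance `tol`); the result must close into a group, which is
then labelled by its abstract structure (order and element orders). The
±2 entry bound covers all crystallographic reindexing operators for
reduced bases; the tests verify the search against an exhaustive
enumeration oracle. At `tol = 0.005` the cell (38.3, 78.6, 79.6, 90, 90,
90) supports only 222; at `tol = 0.02` the *b*/*c* pseudo-symmetry adds
the exchange axes and the order doubles.

# Indexing ambiguity

When the merging point group *H* is a proper subgroup of the metric
symmetry *G*, the |G|/|H| right cosets of *H* in *G* are the
inequivalent indexing conventions. `ambiguity_operators()` returns one
representative per coset, identity first; within a coset the
representative with the fewest negative entries (ties broken by
flattened lexicographic order) is chosen, which yields the conventional
"−h,l,k" form for the orthorhombic *b* ≈ *c* exchange.

Two resolvers make the conventions consistent:

* `resolve_by_reference()` assigns each wedge the operator maximising
  its Pearson correlation with reference intensities over common unique
  reflections (at least `min_common = 3`).
* `resolve_selective_breeding()` needs no reference: starting from
  all-identity plus three seeded random restarts, each wedge in id order
  is reassigned the operator maximising its summed CC against all other
  wedges under their current operators, until a cycle changes nothing.
  The total-pairwise-CC objective is non-decreasing (strict-improvement
  reassignment with ties toward the lower operator index), restarts
  guard against local optima, and the best objective wins. The solution
  is defined only up to one global operator applied to everything —
  evaluation against ground truth therefore maximises accuracy over the
  cosets.

CC is computed on intensities as-is over the full resolution range, with
per-wedge duplicate observations pre-averaged. All pairwise CCs are
obtained in one call by assembling a unique-reflection ×
(wedge, operator) matrix and using `cor(..., use = "pairwise")`, so
cycles of the ascent are cheap table lookups.

# Clustering

The intensity-based distance is d(i,j) = √(1 − CC(i,j)) (optionally
√(1 − CC²)), with pairs sharing fewer than `min_common = 3` reflections
excluded; undefined distances between retained wedges are set to the
maximum √2. Trees use Ward linkage (`hclust` method `ward.D2`).
Intensities can enter raw, scaled toward the cohort's median Wilson B
(multiplying by exp(+2ΔB s²)), or as |E|² — intensity divided by its
per-dataset resolution-shell mean, which removes the overall falloff
(the per-shell mean of |E|² is 1 by construction). The Wilson B itself
is −slope/2 of ln⟨I⟩ versus s² over the high-resolution fit region
(d < 4 Å when the data reach past 4 Å, else the higher-resolution half
of the s² range).

Cell-based clustering embeds each reduced cell as (a, b, c, three face
diagonals), standardised across the cohort, under Ward linkage; every
node is annotated with the linear cell variation — the maximum over the
three face diagonals of their relative spread (max−min)/min across the
member cells, in percent. The face diagonal of the (x, y) face with
included angle θ is √(x² + y² − 2xy cos θ).

Cluster candidates are internal nodes whose pooled members reach
completeness ≥ 0.9 and multiplicity ≥ 2 (both configurable), sorted by
descending size; a node and its qualifying ancestor are both kept, so
the "all data" cluster competes against its subclusters.

A caveat on |E|²: normalisation removes exactly the per-dataset falloff,
so classes that differ *only* by Wilson B carry no class signal
afterwards. What |E|² buys — and what the tests assert — is robustness:
when real intensity classes coexist with a broad B spread (0–30 Å²
across wedges), the raw-CC distance conflates the two effects while the
|E|² distance still recovers the true classes.

# Scaling

The observation model is I_obs ≈ g·I_true with g = k·exp(−2Bs²) per
scaling batch, s = 1/(2d); the scaled value entering the merge is
I_obs/g. A batch is a contiguous frame run: a fixed frame count, a
rotation width in degrees (e.g. `degrees_per_batch = 1` to track strong
radiation damage), or one batch per dataset (default). Parameters are
fit by alternating least squares on the log scale over strong
(I > 3σ) observations: given batch parameters, the reference intensity
of each unique reflection is the mean of ln I_obs − ln k + 2Bs²; given
reference intensities, each batch's (ln k, −2B) comes from a linear
regression on s². Iteration stops at a relative objective change below
1e-6 (cap 50). The reference dataset's batches are pinned at (k = 1,
B = 0): scales are identifiable only relative to it. Early cycles use
the wedge with *median* Wilson B as reference (an extremely sharp wedge
is often itself an outlier); the final cycle uses the *smallest*-B
wedge, so the least-damaged crystal defines the target falloff.

# Error model

Counting sigmas understate the true error of merged intensities; the
per-dataset model σ′² = a(σ²_counting + bI²) (a ∈ [0.25, 100],
b ∈ [0, 0.25]) inflates them so that the normalised deviations
χ = (I − ⟨I⟩_others)/√(σ′² + se²_others) have unit variance in ten
equal-count intensity bins (objective Σ(var_bin(χ) − 1)²). Three
numerical choices matter:

* **Fixed exclusion set.** Gross corruption (a bad frame can sit at
  hundreds of sigma) is excluded *before* optimisation, judged by a
  fixed screening model with an intensity-proportional floor
  (σ² + 0.01·I², threshold 10). If the exclusion moved with (a, b) the
  optimiser would be rewarded for pushing observations over the
  threshold; if the screen lacked the proportional floor it would clip
  the legitimate few-percent-of-I errors the model exists to measure.
* **Joint refinement.** `refine_error_models()` runs two alternating
  rounds: the second recomputes every χ denominator with the other
  datasets' round-one models. With a single isolated round, a cohort
  whose sigmas are collectively understated biases each b upward by
  roughly (1 + 1/(m−1)).
* **Leave-one-out references** come from observations kept by a robust
  pre-merge, so corrupt observations cannot poison the comparison
  means.

Degenerate inputs (noiseless data) drive a to its lower bound and are
flagged; fewer than 50 usable observations return (1, 0) flagged.

# Merging and statistics

Unique reflections take the inverse-variance weighted mean of scaled
intensities with σ′ weights. A single-pass robust rejection discards
observations deviating more than 4σ′ from the leave-one-out weighted
mean of their reflection (attempted only at multiplicity ≥ 3), with at
most a minority of a reflection's observations rejectable, worst
deviators first — without that cap one gross outlier among three makes
all three flag each other and the reflection disappears (masking).

Shells are equal reciprocal-space volume (equidistant in 1/d³), ten by
default. Completeness counts unique observed against the enumerated
point-group-unique set of the cell over the same resolution range;
multiplicity is observations per unique; Rmeas carries the √(m/(m−1))
multiplicity correction; CC1/2 is the Pearson correlation of weighted
half-set means from a seeded per-reflection random split (odd counts
give the extra observation to half A). In anomalous mode Friedel mates
count as separate reflections for multiplicity, CC1/2 and CCano, and
CCano correlates the half-set anomalous differences I⁺ − I⁻. Shells
with fewer than three unique reflections are flagged unreliable.
Anisotropy assigns each reflection to the reciprocal axis maximising
|cos| with its scattering vector and reports per-axis, count-weighted
CC1/2 curves.

# Outlier rejection cycles

Up to three cycles per cluster. Cycle 1 scales and merges everything
and screens *frames*: each (dataset, frame) gets a CC between its scaled
observations and a leave-self-out merged reference (a corrupt frame must
not vouch for itself through the merge), and frames below the Tukey
1.5×IQR lower fence are removed. The fence is applied on the Fisher
z-scale (atanh CC): per-frame correlations cluster near 1 with a long
left tail, and the raw-scale fence flagged ~4% of clean frames where the
z-scale fence flags ~0.5% at unchanged recall. Frames with fewer than 3
matched observations are never auto-rejected; datasets reduced below 20%
of their observations are dropped entirely. Cycle 2 rescales, remerges,
and screens *datasets* by Tukey fences on the chosen metrics (default
{b, B}; two-sided except CC, which is one-sided low — both extremes of
b and B are suspect). Cycle 3 is the final scale (smallest-B reference),
merge and statistics. A cycle that rejects nothing stops the iteration
early, so clean data cost two merges in total. If every dataset would be
rejected, the best-CC half is kept and the condition logged.

# Resolution cutoff and the automated driver

CC1/2 versus s = 1/d is fit with the sigmoid CC1/2(s) =
c/2·(1 − tanh((s − s0)/r)) by bounded least squares (c ∈ (0, 1],
r > 0); a pathological (non-decaying) curve falls back to monotone
interpolation, flagged. The cutoff is the smallest d with fitted CC1/2
≥ 0.5 (configurable), clamped to the data edge, optionally fine-tuned by
re-measuring the outer-shell CC1/2 and stepping one shell at a time
until it is within ±0.15 of the target.

`auto_multi_merge()` drives everything per sample-sheet row: discover
files, group lattices, vote the point group (each wedge votes its own
metric symmetry at `vote_tol = 0.005`; ambiguity operators are
enumerated at the looser `sym_tol = 0.02`), resolve the ambiguity
(reference file if given, else breeding), merge at the data edge,
estimate the cutoff from the best run's shell curve, merge once more at
that cutoff (clusters are reused, not recomputed), and keep the run with
the highest overall CC1/2, outer-shell CC1/2 breaking ties. Per-sample
failures are isolated and reported. Every stochastic step (half-set
splits, breeding restarts) is seeded, so identical inputs and seeds give
byte-identical JSON reports.

# The simulator: what it does and does not emulate

`generate_truth()` draws unique intensities from an acentric Wilson
(exponential) distribution damped by exp(−2Bs²), with optional anomalous
splitting (⟨|ΔI|⟩/⟨I⟩ equal to the requested fraction).
`simulate_wedges()` emulates wedge geometry by random subsetting — each
wedge observes a random fraction of the unique set spread uniformly over
its frames — rather than ray-tracing diffraction geometry, because the
pipeline under test uses nothing beyond frame numbers. Radiation damage
is linear-in-frame B inflation, matching what the decay correction can
represent. Noise is σ² = I + (cI)², c = 0.03 by default; `poisson =
FALSE` with c = 0 gives exact observations for identity tests, and
`sigma_model = "counting"` reports only the Poisson part so that the
error model has something to find. Outlier classes: `noisy` adds a 15%
intensity-proportional error (the signature of a large b),
`nonisomorphous` mixes intensities 70% with an independent truth,
`misindexed` perturbs the cell by 25%, and `bad_frame_rate` replaces a
fraction of frames (edges first, as with miscentred crystals) with
uncorrelated intensities.

A green test on these cohorts establishes that the algorithms recover a
*stated* world: real data add partiality, absorption and detector-surface
effects, correlated (non-Poisson) noise, and geometry-dependent
completeness patterns that random subsetting does not produce. The
scaler correspondingly implements only decay/overall-scale corrections;
modulation and absorption corrections would need image geometry that
text reflection files do not carry.

Cohort sizes in the test-suite were fixed from precision arguments, not
tuned: e.g. the error-model calibration check uses 10 wedges at 70%
completeness because the binned-moment estimator's sampling sd on a is
about 0.05 there, which a [0.8, 1.2] band over 20 seeds presumes; and
the resolution-cutoff cohort's mean intensity is solved from the
closed-form CC1/2 expectation so the true curve crosses 0.5 at exactly
2.0 Å.

# Known limitations

* Space-group determination (systematic absences) is out of scope; only
  point-group/Laue-level symmetry is handled.
* No MTZ output or amplitude conversion; the merged table is
  tab-separated text.
* Scaling corrects decay and overall scale only (no detector-surface
  modulation or absorption).
* The per-frame CC screen needs a few observations per frame; extremely
  fine-sliced data with very few reflections per frame leave frames in
  the low-evidence class, where only dataset-level screening applies.
* The breeding resolver evaluates full pairwise CC; cohorts of many
  thousands of wedges would need subsampling.
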