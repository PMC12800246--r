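---
title: "Quantifying morphological disparity through time from 2D landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphological disparity through time from 2D landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`paleodisp` implements a complete 2D geometric-morphometrics pipeline for
palaeobiological disparity studies: landmark input, generalized Procrustes
analysis (GPA) with sliding semi-landmarks, shape-space ordination,
group-wise disparity statistics, geological time binning, range-through
richness, and Lagerstätte-effect sensitivity analyses. Its motivating use
case is the disparity of early sarcopterygians (lobe-finned fishes and
their tetrapod relatives) across the Devonian–Carboniferous transition,
but every component is generic.

This vignette is the package's account of its methods: the model and its
assumptions, the parameters that matter, the numerical choices, what the
synthetic-data generator does and does not emulate, and known limitations.

## The data model

A *landmark configuration* is an ordered set of $k \ge 3$ points in the
plane digitized on one specimen — here, one fossil species represented by
an adult palaeontological reconstruction. Configurations live in long
tibbles (`specimen`, `point`, `x`, `y`), read from TPS files
(`read_tps()`; the `LM=`, `ID=`/`IMAGE=`, `SCALE=` dialect). y increases
upward (the tpsDig convention) and nothing is flipped on read. Missing
landmarks are a hard error by design: the analyses assume complete
configurations, and silently imputing or dropping points would corrupt
the shape space.

Points split into *fixed landmarks* (point-wise homologous anatomical
loci) and *semi-landmarks* (points along outlines with no point-wise
homology). The sliders table (`before`, `slider`, `after`) declares each
semi-landmark and its two curve neighbours. Indices are 1-based, the
natural convention in R; files produced by 0-based tooling import with
`read_sliders(zero_based = TRUE)`.

Species metadata carry closed vocabularies — eight early sarcopterygian
clades, three aquatic habitat classes (marine/estuarine/freshwater), ten
optional precise palaeoenvironments — plus locality, first and last
occurrence ages (`fad_ma` $\ge$ `lad_ma`, ages in Ma decreasing toward
the present), and an ontogeny marker. Validation is all-or-nothing and
reports every offending row.

## Superimposition

GPA removes translation, scale and rotation so that only shape remains.
Each configuration is centred and scaled to unit centroid size
($CS = \sqrt{\sum_i \lVert p_i - \bar p \rVert^2}$); configurations are
then iteratively rotated onto the evolving consensus by the proper
least-squares rotation (SVD of the $2\times2$ cross-product matrix with
the determinant constrained to $+1$ — reflections are disallowed because
all reconstructions are digitized in the same orientation). The loop
stops when the consensus changes by less than `tol` (root summed squared
difference, default $10^{-8}$) or after `max_iter` (default 100)
iterations; non-convergence returns the best state with
`converged = FALSE` and a warning.

Semi-landmarks are slid under the *Procrustes distance minimisation*
criterion, not bending energy: for slider $p$ with neighbours $b, a$,
the tangent is the unit chord $u = (x_a - x_b)/\lVert x_a - x_b\rVert$
in that specimen, and $p$ moves by $t\,u$ with
$t = (c_p - p)\cdot u$ — the projection of its deviation from the
consensus point $c_p$ onto the tangent line, which minimises its squared
distance to the consensus along that line. This step never increases a
slid point's distance to the consensus. Coincident neighbours (a
degenerate tangent) leave the point unslid with a warning.

Two numerical choices deserve emphasis:

* **Sliding passes are capped** (`slide_iter`, default 5), after which
  superimposition iterates to tolerance with slid positions frozen.
  Iterating sliding all the way to a coordinate fixed point does not
  work: tangent sliding lets semi-landmarks creep *along* the outline, an
  almost shape-neutral reparameterization that changes consensus
  coordinates indefinitely (we observe contraction ratios around 0.98
  per iteration) while improving the Procrustes fit negligibly. Five
  passes capture the fit improvement; the cap is exposed for users who
  want to check sensitivity.
* **Canonical orientation.** After convergence the whole aligned sample
  is rotated so the consensus' major principal axis lies along x, with a
  third-moment sign rule resolving the 180° ambiguity. GPA is otherwise
  only defined up to a global rotation (inherited from whichever
  specimen seeds the consensus), and the canonical frame makes the
  output exactly invariant to arbitrary similarity transforms of the
  input — a property the test suite checks directly.

The reported consensus is the arithmetic mean of the aligned
coordinates. The internal rotation reference is its unit-size rescaling.

## Ordination

`shape_pca()` performs PCA (covariance of the flattened
$(x_1, y_1, \dots, x_k, y_k)$ coordinates, divisor $n-1$) via SVD.
Axes with numerically zero eigenvalues are truncated — after GPA the
shape space has at most $2k-4$ dimensions, and with $n$ specimens at
most $n-1$ are estimable. Axis signs are arbitrary in principle, so they
are fixed deterministically (largest-magnitude loading positive);
comparisons with published morphospaces must remain sign-agnostic.

By default the PCA runs on Procrustes coordinates directly. Shape
variation in these data is small relative to the curvature of shape
space, so projecting to the tangent space first changes next to nothing;
`tangent = TRUE` performs the orthogonal projection off the consensus
direction for users who want to verify that insensitivity (a test in the
suite does).

## Disparity statistics

Four complementary statistics are provided, each with its own stated
divisor so conventions are never silently mixed:

* **Procrustes variance** (`procrustes_variance()`): a group's mean
  squared deviation from its own mean shape, divisor $n$ (the group-wise
  disparity convention of the established morphometrics tooling;
  `unbiased = TRUE` switches to $n-1$). A group's *share* of disparity
  is its PV divided by the sum of group PVs — the only definition under
  which shares total 100%.
* **Pairwise permutation tests** (`pairwise_pv_test()`): observed
  statistic $|PV_{g_1} - PV_{g_2}|$; the null permutes group labels
  across specimens (default 999 permutations), and
  $p = (\#\{\text{perm} \ge \text{obs}\} + 1)/(n_{perm} + 1)$. The seed
  is a mandatory part of a run configuration. Singleton groups are
  reported with `NA` p-values rather than dropped.
* **Convex-hull area** (`convex_hull_area()`, `hull_areas()`): the area
  of the smallest convex polygon containing a group's points on a PC
  plane (monotone-chain hull, shoelace area). Undefined (`NA`) for
  groups of fewer than three species, never zero — occupation of a
  plane by one or two points has no area worth reporting.
* **Variance-weighted hull area** (`weighted_hull_area()`): for each of
  the $\binom{5}{2}$ planes spanned by the first five PCs, the hull area
  weighted by the combined variance proportion of the two axes, summed.
  Whether such a statistic should sum or average over planes is
  ambiguous in the literature it mirrors; the raw sum is the default and
  `normalize = TRUE` divides by the total pair weight. The two differ
  only by a constant factor within one ordination, so group rankings are
  unaffected.
* **Sum of variances** (`sum_of_variances()`): summed per-axis score
  variances (divisor $n-1$) of a subset; on the full sample this equals
  the eigenvalue sum, and on any subset it equals the total coordinate
  variance of that subset about its own mean.

## Chronology

The built-in time scales span the Ludfordian (425.6 Ma) to the end of
the Gzhelian (298.9 Ma) — a 126.7 My window — at stage level (16
intervals, for richness) and as 7 epochs (Ludlow through Pennsylvanian,
for disparity). The precise boundary ages are pinned in the package (and
shipped as CSV under `extdata/`) because reproducibility requires *one*
declared chart; any table with contiguous `interval, start_ma, end_ma`
rows can replace them. `equal_bins(425.6, 298.9, 7)` yields the
scale-independent alternative binning of 18.1 My bins.

Species are assigned to intervals by **first occurrence**: a taxon
spanning several intervals counts, for disparity, only in its interval
of appearance. An age exactly on a shared boundary belongs to the
*older* interval (consistent with appearance semantics), and the oldest
interval is closed at its old edge. Range-through richness instead
counts a species in every interval its `[lad_ma, fad_ma]` range
intersects, under the same boundary rule. Intervals with fewer than two
species get `NA` disparity, not zero: the variance of one specimen is
undefined, and plotting zeros would fabricate signal.

`disparity_through_time()` supports both metrics (per-interval
Procrustes variance on aligned coordinates; sum of variances on PC
scores) and both binnings; on data simulated with interval-wise noise
levels the epoch-based and equal-bin curves are strongly rank-correlated,
which is the property that justifies presenting either.

## Pipeline and the Lagerstätte jackknife

`run_analysis()` chains the whole analysis from a `run_config()` (or a
YAML file): read and cross-validate inputs, GPA, PCA, a disparity table
per grouping variable, disparity-through-time under both binnings,
stage-level richness, and CSV artifacts plus a JSON run log (input MD5
hashes, seed, settings, versions) sufficient to reproduce every number.
All randomness derives from the single run seed through fixed per-stage
offsets. A thin command-line wrapper with `simulate`, `run-all`,
`jackknife` and per-stage subcommands ships under `inst/cli/`.

`jackknife_locality()` re-runs everything excluding all species from one
locality — deliberately re-running GPA from scratch rather than
subsetting aligned coordinates, because the superimposition (and hence
every downstream score) depends on the sample. The paired
disparity-through-time curves and their per-interval drop fractions
quantify how much of a peak rides on a single deposit of exceptional
preservation.

## The synthetic-data generator

`sim_truth()` + `simulate_dataset()` generate datasets with known truth
so that every stage is testable without external data. The default
census mirrors the motivating study's body dataset: 36 species in 8
clades (including groups of one and two species, the awkward cases
disparity code must tolerate), habitats drawn in 16:9:45 proportions,
ranges within 425.6–298.9 Ma, a 11 fixed + 196 semi-landmark fish-like
outline scheme, and one planted Lagerstätte locality ("Bear Gulch")
confined to the Serpukhovian interval. Defaults chosen where the
emulated structure does not pin them: isotropic digitization noise of
sd 0.02 shape units per coordinate and group mean-shape offsets of norm
0.08 shape units — within-group scatter a few times smaller than
between-group separation, which is what published sarcopterygian
morphospaces look like.

Three design points matter for interpreting test results:

* Group offsets are centred and projected orthogonal to the translation,
  scaling and rotation directions at the mean shape, so planted effects
  survive superimposition rather than being absorbed by it.
* Noise is added in shape units *before* the random similarity transform
  of each specimen: digitization error is part of the shape, and GPA
  must remove the transform, not the noise.
* For isotropic noise of sd $s$, superimposition removes 4 degrees of
  freedom, so a group's expected PV is approximately $s^2(2k-4)$
  (`expected_pv()`); this analytic target holds to ~10% at large $n$
  and anchors the recovery tests.

What the generator does **not** emulate: anatomically structured
covariance (real shape variation is far from isotropic), correlated
digitization error along outlines, phylogenetic autocorrelation of
shapes and ranges, and preservation-biased sampling other than the one
planted Lagerstätte. Passing recovery tests therefore demonstrate that
the estimators are correct and calibrated under known truth — not that
real fossil data satisfy their assumptions.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen to make Monte-Carlo answers stable: permutation calibration uses
500 null datasets × 199 permutations; planted-bin recovery 200
replicates of 42 species; the jackknife simulation 100 replicates of 35
species; PV-ratio recovery one dataset of 200 species per group with a
33-point sliding outline. Every stochastic step flows from an explicit
seed, and identical configurations produce byte-identical outputs.

## Known limitations

* 2D only; no missing-landmark estimation, no bending-energy sliding,
  no partial/weighted Procrustes.
* The canonical-orientation sign rule uses third moments of the
  consensus; a consensus that is exactly symmetric in both axes would
  make the choice unstable (no realistic outline is).
* Permutation tests compare variances only; they inherit the usual
  caveats of label-permutation under unequal group sizes.
* Published headline values from the motivating study can only be
  reproduced against its deposited landmark data, which are not bundled;
  `replicate_reference()` runs the comparison when a local copy is
  pointed to via `options(paleodisp.deposited_data = ...)`.
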