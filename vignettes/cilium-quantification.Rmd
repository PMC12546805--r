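---
title: "Quantifying primary cilia in 3D fluorescence stacks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying primary cilia in 3D fluorescence stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliometry)
```

## The measurement problem

Primary cilia are thin (~0.2-0.3 µm diameter), a few micrometers long, and
oriented arbitrarily in space. Measuring their length and morphology from
confocal z-stacks of a ciliary membrane marker (such as Arl13b) therefore has
to be done in 3D: a single focal plane or a maximum projection truncates any
cilium that leaves the plane. The pipeline in this package mirrors the
established workflow for this problem:

1. **Preparator** — preprocess the marker channel (rolling-ball background
   subtraction, slice-wise Gaussian blur), select an intensity threshold from
   the image histogram, and segment the stack.
2. **Quantifier** — label 26-connected voxel objects, filter them by size and
   border contact, and measure each surviving object: volume, surface,
   maximum span, intensity statistics, and skeleton-based parameters
   (tree length, cilium length, branch count, bending).
3. **Explorer** — pool per-condition folders of per-cilium tables, run an
   advisory quality-control screen, choose and execute statistical tests
   through a normality/homogeneity decision tree, embed the morphometric
   feature table with PCA/UMAP, rank features by LDA, and draw
   replicate-aware superplots.

A fourth, first-class component — the **phantom generator** — renders
synthetic cilia with analytically known centerline arc length so that the
entire pipeline can be validated against ground truth without any external
data.

## Segmentation model

Foreground is defined as intensity strictly above a cut `t`. The cut comes
from one of the classical histogram criteria (Otsu's between-class variance,
Li's minimum cross-entropy, Yen, Rényi entropy, Tsai's moment preservation,
the Minimum valley method, Shanbhag's fuzzy entropy), from a manual value, or
from hysteresis (low/high pair). Choices worth noting:

* Every criterion that is an optimum over cuts is computed **exhaustively**
  over all candidate cuts, with ties broken toward the lowest cut. This makes
  each method a deterministic, testable function of the histogram; the test
  suite verifies all seven against independently written reference
  implementations on random histograms.
* **Li** is implemented as exhaustive minimization of the cross-entropy
  objective rather than the iterative fixed-point scheme — the objective is
  the published definition, and exhaustive search cannot stop in a local
  minimum.
* **Rényi entropy** maximizes the two-class Rényi entropy at a single order
  (`alpha = 2` by default; `alpha -> 1` recovers the Kapur maximum-entropy
  method). Some implementations combine three orders with a weighting rule;
  the single-order criterion was chosen because it is the simplest published
  formulation and keeps the method a pure function of `(histogram, alpha)`.
* The histogram is taken from the **maximum-intensity projection** of the
  marker channel by default, mirroring how thresholds are chosen manually on
  projections; a full-stack histogram is available by setting.
* **Hysteresis** keeps every low-threshold 26-connected component that
  contains at least one voxel above the high threshold, so
  `mask(high) ⊆ result ⊆ mask(low)` always holds.

Background subtraction is slice-wise grayscale opening with a disc (the
rolling-ball semantics of the corresponding interactive operation); blur is a
slice-wise 2D Gaussian with border-renormalized kernels so that constant
images stay constant and total intensity is conserved away from borders.

## Skeleton morphometry

Each labeled object is reduced to a one-voxel-wide skeleton by
topology-preserving 3D thinning (sequential deletion of simple points, with
curve endpoints protected), and the skeleton becomes a graph whose nodes are
voxels and whose edges connect 26-neighbors with **anisotropic physical
weights** (a diagonal step costs `sqrt(dx² + dy² + dz²)`). From that graph:

* `tree_length_um` — total physical length of all skeleton edges;
* `n_branches` — edges of the condensed graph, i.e. maximal chains between
  junction/end nodes (a clean cilium has exactly 1);
* `cilia_length_um` — the largest shortest path between any two end nodes;
* `bending_ratio` — end-to-end Euclidean distance over `cilia_length_um`;
* `orientation` — unit vector between the two path ends.

Anisotropic grids need care; three documented mechanisms keep the digital
measurement close to the physical length:

* **z-refinement.** At `dz/dx ≈ 6` a thin object spans one or two z-planes
  and a thinned curve hops between planes, each hop costing a full `dz` that
  the physical centerline never traveled. The object mask is therefore
  resampled to near-isotropic voxels (slices replicated, then smoothed in z)
  before thinning, so the skeleton is localized at sub-slice precision and
  plane changes cost only the refined spacing.
* **Chain regularization.** Thinning leaves staircase corners; a
  regularization pass deletes a chain voxel whose two neighbors are mutually
  adjacent (corner cut) and relocates a chain voxel when an alternative
  in-mask position strictly shortens the chain. The result is still a voxel
  skeleton, and all reported lengths remain graph shortest-path lengths —
  the suite checks them against an independent Dijkstra implementation on
  the returned skeleton.
* **Component stitching.** An object merged by the connect-range rule
  (`increase_range`, a configurable dilation radius that bridges small
  background gaps) is by definition one cilium, but its voxel mask can still
  contain a physical gap where partial-volume dimming broke the signal. The
  skeleton components of one object are therefore joined by their shortest
  physical link before path lengths are computed.

Masks are optionally blurred in XY (`gauss_xy_sigma`) and re-binarized before
thinning; the re-binarization level defaults to the symmetric 0.5, and
slightly lower values (0.45 in the validated settings below) counteract tip
erosion of thin objects. A skeleton that spans at most one voxel step is
point-like at grid scale and is reported with `cilia_length_um = 0` — the
spherical-object case, reported rather than raised, and flagged
informationally by the QC screen.

The minimum object size follows the resolution: the default 10 voxels at
0.1 µm/px scales with the inverse square of the pixel size
(`suggest_min_size()`), since pixel size is a length while the mask is
(projected) area-like.

## The phantom generator

`generate_centerline()` draws a gently curved natural cubic spline through
five control points; arc length is computed by adaptive quadrature of the
spline speed and is exact under uniform scaling, which is how a target length
is hit exactly. `rasterize_scene()` renders tubes of radius `radius_um`
around each centerline into an anisotropic voxel grid, blurs with per-axis
PSF sigmas, adds a constant background and Gaussian noise, and rounds to the
bit depth. Defaults mirror recommended acquisition settings: voxels
`(0.08, 0.08, 0.5)` µm, 16-bit.

Generator semantics that matter for interpretation:

* **Partial volume.** Voxel occupancy is computed by sub-voxel supersampling
  (3×3×5 per voxel), emulating what an integrating detector records. With
  center-point sampling a tube thinner than `dz` vanishes wherever its
  centerline passes between slice centers, which no real detector does.
  `antialias = FALSE` restores the exact center-within-radius contract used
  by the exhaustive voxel-count oracle test.
* **snr** is the ratio of the *realized* (post-PSF) foreground amplitude to
  the background-noise standard deviation — the snr of the image as
  acquired. Defining it pre-blur would make the delivered image quality
  depend on the PSF setting.
* **PSF** defaults in the validation runs are `(0.1, 0.1, 0.3)` µm, the
  scale of a high-NA confocal at far-red emission.
* Tubes never touch the grid border by default, so border-exclusion behavior
  is tested explicitly, not accidentally.

What the phantoms do **not** emulate: realistic 3D PSF structure (only
separable Gaussian blur), autofluorescent background texture, neighboring
cell structures, basal-body staining, or densely packed touching cilia.
Passing the phantom validation therefore demonstrates the geometry and
statistics machinery, not robustness to every real-world imaging artifact.

`generate_grouped_tables()` plants statistical structure instead: one folder
per condition, one TSV per replicate, normal or lognormal measurement
distributions with per-measurement location shifts, and an identical
synthetic tool-version tag by default.

## Validated analysis settings

The phantom study conditions used by the validation suite are tubes of
2-10 µm length and 0.25 µm radius at snr 5 on `(0.08, 0.08, 0.5)` µm voxels.
For those conditions the package's validated analysis settings are: Moments
threshold on the maximum projection, preprocessing blur sigma 2 px,
keep-intensities style, minimum size 16 voxels (`suggest_min_size(0.08)`),
connect-range 2 voxels, `gauss_xy_sigma = 2`, re-binarization 0.45. Two
residual error sources remain and are worth knowing about:

* digital path lengths on a 26-neighbor grid overestimate oblique straight
  lines by up to ~8% (the chamfer-metric excess), and
* tubes lying exactly between two z-planes at `dz = 0.5` µm lose genuinely
  dim end stretches to partial volume.

Both are inherent to voxel-graph length measurement at this anisotropy; the
test suite measures the resulting recovery rate on 50 phantoms and the
acceptance script recomputes it from scratch.

## Statistics stage

For each measurement the decision tree is: one condition — no test; every
group Shapiro-normal at `alpha` **and** Levene-homogeneous — Student's t
(2 groups) or one-way ANOVA with Tukey HSD (>2); normal but heteroscedastic —
Welch's t or Welch ANOVA with Games-Howell; any group non-normal —
Mann-Whitney U or Kruskal-Wallis with Dunn's test (Holm-corrected). Every
intermediate p-value is recorded in a rationale trace. Details:

* Levene's test is median-centered (the robust Brown-Forsythe variant, the
  common software default).
* Each group needs at least 3 records, otherwise an "insufficient n" result
  is returned without testing.
* Shapiro's test is applied to a seeded subsample of 5000 for larger groups
  (the test's validity limit).
* Stars follow the fixed mapping `***` p ≤ 0.001, `**` p ≤ 0.01, `*`
  p ≤ 0.05, else `ns`.
* Integer-valued (ordinal) measurements are tested with the same tree but
  labeled with a warning, since rank/t procedures assume continuity.
* Games-Howell and Dunn are implemented in the package (no installed package
  provides them); Tukey, Shapiro, Levene, the t/ANOVA/rank tests and Holm
  correction use the standard R implementations.

The type-I behavior of the full adaptive procedure (Shapiro → Levene →
chosen test) is measured by simulation in the acceptance suite: 2000 null
datasets with two identical normal groups of n = 50.

The QC screen is **advisory**: Tukey fences (`1.5×IQR`, configurable) per
group on length, volume, span, mean intensity and intensity sd, a branch
limit (default 1), zero-length flags, and a tool-version consistency check.
Flags are reported, never auto-deleted — they mark records to scrutinize,
not records to drop, and record counts are conserved through all outputs.

Dimensionality reduction excludes columns that encode segmentation rather
than biology: ids, centroid coordinates, threshold columns, voxel-unit
duplicates of micrometer columns (detected by the `<stem>_voxels` /
`<stem>_um*` naming convention), non-numeric and zero-variance columns; the
rest are standardized. PCA fixes signs by making each component's
largest-magnitude loading positive. UMAP runs the reference umap-learn
implementation through the `python` interpreter with a fixed seed
(default 42, `n_neighbors = 15`, `min_dist = 0.1`, recorded in outputs); no R
implementation is involved, so coordinates are exactly reproducible per
seed. LDA uses `MASS::lda`; features are ranked by the magnitude of their
discriminant coefficients weighted by each axis's share of the between-group
variance.

## Problem sizes used in the validation suite

The suite and the acceptance script use: 50 phantoms (160×160×10 voxels
each) for length recovery; 20 phantoms for the preprocessing comparison;
2000 simulated null datasets (n = 50 per group) for the type-I rate; 50
random histograms per threshold method; 50 random stacks for hysteresis
nesting; random masks up to 32³ for labeling; 20 constructed skeletons for
the Dijkstra comparison. These sizes give stable estimates (binomial s.e.
~0.5% at 2000 replicates) while keeping a full run in a few minutes.

## Known limitations

* Surface area is the summed area of exposed voxel faces — exactly testable,
  but systematically above the surface of the smooth underlying object, and
  possibly different from other tools' marching-cubes-style definitions.
* Maximum span is exact for moderate objects and computed on boundary voxels
  for very large ones (which preserves the maximum).
* The largest-shortest-path length inherits the chamfer-metric excess of
  digital paths (up to ~8% for unlucky orientations).
* The decision tree tests each measurement marginally; no multiplicity
  correction is applied across measurements, and very large n makes tiny
  differences significant — the same caveats the underlying workflow carries.
* The Canny-style 3D edge-detection segmentation mode of the original tool
  chain is not implemented (no published parameterization to follow), and
  Bayesian alternatives to the decision tree are out of scope.
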