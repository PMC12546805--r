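# ciliometry

Quantitative 3D morphometry of primary cilia from multi-channel confocal
z-stacks, with replicate-aware downstream statistics — an end-to-end,
scriptable R implementation of the segment → measure → explore workflow used
for cilium quantification in fluorescence microscopy.

## The problem and who this is for

Primary cilia are thin microtubule-based organelles (a few µm long,
~0.2–0.3 µm wide) protruding from the cell surface; their length, volume,
bending and marker intensity are the readouts of choice in ciliary-biology
experiments. Because cilia point in arbitrary directions, accurate
measurement requires true 3D analysis of confocal z-stacks of a ciliary
marker (e.g. Arl13b immunostaining) on anisotropic voxel grids
(0.05–0.1 µm laterally, 0.5–0.8 µm axially). This package is for researchers
who want that full pipeline — segmentation, per-cilium morphometry, quality
control, statistics and plots — as composable, tested R functions rather
than an interactive GUI session.

## What it computes

**Segmentation** (`segment_stack`): the marker channel is optionally
background-subtracted (rolling-ball, slice-wise) and blurred, then
thresholded. Histogram criteria implemented exhaustively over all cuts:
Otsu (max between-class variance), Li (minimum cross-entropy
\\(\\min_t -[A_0\\log\\mu_0 + A_1\\log\\mu_1]\\)), Yen, Rényi entropy
(\\(\\max_t H_\\alpha(C_0)+H_\\alpha(C_1)\\)), Moments (Tsai), Minimum
(valley after iterated 3-bin smoothing), Shanbhag — plus manual values and
hysteresis (keep low-threshold 26-components containing a voxel above the
high threshold).

**Morphometry** (`quantify_stack`): 26-connected labeling with optional
gap-bridging ("increase range"), size and border filters, then per object:
volume (voxels and µm³), exposed-face surface (µm²), maximum span, centroid,
intensity statistics within the mask, and skeleton measures from
topology-preserving 3D thinning. The skeleton graph uses anisotropic
physical edge weights; the headline measures are

- *cilium length* \\(L = \\max_{u,v \\in \\text{ends}} d_G(u, v)\\) — the
  largest shortest path between skeleton end points,
- *tree length* — total skeleton length,
- *branches* — chains between junction/end nodes (a clean cilium has 1),
- *bending ratio* — end-to-end distance / \\(L\\).

**Explorer** (`pool_groups`, `qc_screen`, `run_stats`, `embed_cilia`,
`discriminate`, `make_superplot`, `write_outputs`): pools one folder per
condition (folder name = group label), checks tool-version consistency,
flags outliers (Tukey fences), picks tests by a Shapiro/Levene decision tree
(t / Welch t / Mann-Whitney U for two groups; ANOVA+Tukey, Welch
ANOVA+Games-Howell, Kruskal-Wallis+Dunn-Holm for more), computes PCA/UMAP
embeddings and LDA feature rankings after excluding
segmentation-property columns, and writes superplots plus an
`Analysis/Data` + `Analysis/Plots` output tree.

**Phantoms** (`generate_centerline`, `rasterize_scene`,
`generate_grouped_tables`): synthetic cilia with analytically known
centerline arc length (spline + adaptive quadrature), rendered with
partial-volume supersampling, PSF blur and Gaussian noise at a stated SNR —
the ground truth every stage is validated against.

## Worked example

Simulate one cilium phantom, segment it, and measure it:

```r
library(ciliometry)

cl <- generate_centerline(seed = 4, bounds_um = c(12, 12, 4),
                          length_range_um = c(2, 10), curvature = 0.05)
cat(sprintf("ground-truth arc length: %.3f um\n", cl$arc_length_um))
#> ground-truth arc length: 6.686 um

truth <- phantom_truth(list(cl), voxel_size_um = c(0.08, 0.08, 0.5),
                       snr = 5, background_level = 100,
                       psf_sigma_um = c(0.1, 0.1, 0.3), seed = 4)
stk <- rasterize_scene(truth, shape = c(160, 160, 10))
stk
#> <image_stack> 160 x 160 px, 10 slices, 1 channel(s), 16-bit
#>   voxel size: 0.08 x 0.08 x 0.5 um

seg <- segment_stack(stk, segmentation_settings(method = "Moments",
       blur_sigma_px = 2, include_unsegmented_copy = TRUE))
tab <- quantify_stack(seg, min_size_voxels = 16,
                      exclude_borders = c(FALSE, FALSE, FALSE),
                      range_voxels = 2, gauss_xy_sigma = 2,
                      rebinarize_level = 0.45)
tab$records[, c("cilia_length_um", "tree_length_um", "n_branches",
                "bending_ratio", "volume_um3", "max_span_um")]
#>   cilia_length_um tree_length_um n_branches bending_ratio volume_um3
#> 1           6.901          6.901          1         0.919     2.4608
#>   max_span_um
#> 1       7.077
```

The measured cilium length (6.901 µm) recovers the analytic ground truth
(6.686 µm) within ~3%; a single skeleton branch and a bending ratio of 0.92
describe a clean, gently curved cilium. The planning helper reproduces the
usual sampling advice — for Alexa Fluor 647 emission (668 nm) at NA 1.40,

```r
round(compute_sampling_limits(668, 1.4), 1)
#> resolution_nm    nyquist_nm
#>         291.1         145.5
```

i.e. ~290 nm lateral resolution and ~145 nm Nyquist spacing.

A full pipeline run (simulate → prepare → quantify → explore) is available
as `run_pipeline("all", read_config())` or from the shell via the thin
wrapper `inst/cli/cilia-pipeline`.

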