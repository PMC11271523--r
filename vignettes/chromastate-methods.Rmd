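---
title: "Methods: chromatin-image cell states and tissue organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-image cell states and tissue organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`chromastate` implements an unsupervised analysis of single-nucleus
chromatin images from breast tissue microarrays (TMAs) spanning normal
tissue, hyperplasia, ductal carcinoma in situ (DCIS) and invasive ductal
carcinoma (IDC). The pipeline has five analysis stages plus a synthetic
data generator that makes every stage testable without microscope data:

1. **Imaging** — percentile range normalization
   \((I - P_1)/(P_{99.8} - P_1)\), gain/offset and additive-noise
   augmentation models, duct segmentation from a cytokeratin-like channel
   (Gaussian blur \(\sigma = 1\), Otsu threshold, 8-connected components,
   minimum area 64 px\(^2\)), a classical watershed stand-in for learned
   nucleus segmentation, and masked 96 × 96 patch extraction centered on
   nucleus centroids.
2. **Representation** — a convolutional variational autoencoder (VAE):
   five strided convolutions (kernel 4, stride 2, padding 1; 96 → 3),
   parallel fully connected heads for the posterior mean and log-variance
   of a diagonal Gaussian, a mirrored transposed-convolution decoder,
   leaky-rectifier activations, summed-L2 reconstruction plus KL divergence
   to a standard-normal prior, reparameterized sampling during training.
   Downstream analysis always uses posterior means.
3. **States** — balanced per-category downsampling, PCA to 50 components,
   k-means with \(k = 8\) (restarts, best inertia), canonical relabeling by
   ascending mean nuclear area, inertia-guided subclustering, and
   nearest-centroid assignment of held-out cells.
4. **Morphometrics** — ~45 named nuclear morphology / chromatin
   organization features across eight families (size, radial profile,
   shape, boundary curvature, image moments, co-occurrence texture,
   intensity, heterochromatin packing); per-(feature, cluster) Welch
   t-tests on z-scored values with joint Benjamini–Hochberg correction;
   selection at adjusted \(p < 0.01\), fold change \(> 1.2\) or \(< 0.8\),
   magnitude gate 0.5; correlation grouping at \(r > 0.8\) by connected
   components.
5. **Spatial & classification** — duct distance (0 inside ducts, else
   \(\ln\) pixel distance to the nearest in-duct cell centroid; at
   0.18 µm/px, 1 ↔ ~0.49 µm and 5 ↔ ~26.71 µm), neighborhood composition
   within a 25.9 µm radius (51.8 µm diameter), the 8 × 8 row-stochastic
   co-localization matrix, its within-sample permutation null (40,000
   shuffles at full scale; 2,000 at desk scale with documented Monte Carlo
   tolerance), and leave-one-patient-out (LOPO) MLP classifiers of
   phenotypic category with ablation and misclassification-contrast
   analyses, plus a multinomial-logistic baseline.

# Parameters that matter

| parameter | default | unit | note |
|---|---|---|---|
| normalization percentiles | 1 / 99.8 | % | linear-interpolation percentiles; no clipping |
| augmentation gain / offset | U(0.6, 2) / U(−0.2, 0.2) | — | one draw per image |
| noise scale | 0.02 | intensity | per-pixel standard normal times U(0,1) per image |
| duct blur σ / min area | 1 px / 64 px² | | per-image Otsu (interpretation; batch thresholds not stated) |
| patch side | 96 px | | centroid at pixel (48, 48), zero-padded at borders |
| neighborhood radius | 25.9 | µm | sweepable 26–120 µm |
| permutation shuffles | 2,000 (desk) / 40,000 (full) | | per sample, geometry fixed |
| feature selection | FDR 0.01, FC 0.8/1.2, gate 0.5 | | both gate readings implemented (see below) |
| correlation grouping | 0.8 | Pearson r | robust 0.75–0.85 on block-structured features |
| MLP | 3 × {1024,128,64}, dropout 0.5 | | inverse-class-frequency weighted cross-entropy |
| pixel size | 0.18 | µm/px | |

# The synthetic stated world

The generator emulates the statistical structure the analysis assumes: 11
phenotypic categories across three stages, eight planted cell states
present in every category at category-dependent proportions (low states
enriched in non-tumor, high states in DCIS/IDC), state-dependent nuclear
morphology, same-state spatial assortativity, malignant states placed in
and near ducts, and a cytokeratin-like channel segmentable by the duct
procedure. Placement is sequential hard-core thinning: duct regions first,
then cells accepted with softmax weights
\(\exp(\text{duct affinity}(s) + \text{assortativity}\cdot n_{\text{same}})\),
with non-overlap guaranteed by the rendered mask radii. Coordinates are
0-based (row, col); intensities live in [0, 1] and are rescaled to 16-bit
on export.

**State morphology.** The eight states carry a monotone mean-area ladder
(150 → 380 px² at desk scale, ~1.7×, the magnitude of nuclear enlargement
seen from low- to high-grade ductal lesions) and, orthogonally, a 2 × 2 × 2
factorial over chromatin heterogeneity (peripheral heterochromatin rim +
blob contrast; alternating states), elongation (aspect 1 vs 2, alternating
pairs) and hyperchromasia (overall staining intensity, states 4–7). This
design went through one documented revision: an earlier draft used a 9×
area ladder with positionally random blob texture, which is both
biologically unrealistic and *structurally invisible to an autoencoder* —
a decoder can never predict random blob positions, so texture contrast
carries no reconstruction value and the latent space cannot separate
states that differ only in it. Real heterochromatin is spatially organized
(envelope-associated rim, condensed foci, brighter overall staining), and
rendering it that way is what makes the planted states representable —
which the analysis pipeline assumes of real data in the first place.

**What the generator does not emulate**: photorealistic histology, H&E,
3-D tissue, imaging aberrations, segmentation errors beyond what the
watershed stand-in produces, or between-TMA batch effects. The
patient-level Dirichlet perturbation of state proportions (concentration
200) is a free parameter; the study does not quantify within-category
heterogeneity across patients. A green test therefore establishes that the
*pipeline machinery* is correct on data with the assumed structure — not
that the biological claims replicate.

# Numerical choices

* **Percentiles** are linear-interpolation (type 7) percentiles.
* **No clipping** after range normalization (a display-only flag exists).
* **Boundary features** use an angular radius profile about the mask
  centroid with one bin per boundary pixel (finer binning would miss true
  boundary pixels in thin wedges and bias the profile low), low-passed by
  a truncated Fourier series (10 harmonics) whose analytic derivatives
  give the perimeter and curvature; exact for star-convex nuclei, which is
  the regime of both the generator and typical epithelial nuclei. Disk
  shape factors are within ~1.5% of 1 for radii 6–30 px.
* **Fold changes** are computed on the raw feature scale for strictly
  positive features; non-positive features fall back to a
  difference-of-means effect with the |mean z| gate, flagged `diff`.
* **Magnitude-gate ambiguity**: the selection threshold 0.5 admits two
  readings — |mean z-scored value within the cluster| (default,
  `z_rule = "cluster_z"`) or raw feature mean across all cells
  (`z_rule = "global_mean"`). Both are implemented; neither is asserted as
  authorial intent.
* **BH family** is all feature × cluster tests jointly.
* **Nucleus segmentation** takes the extent at 0.6 × the Otsu threshold
  with a strong-pixel component filter (hysteresis): the full Otsu value
  clips dim chromatin texture inside heterogeneous nuclei and biases
  measured areas state-dependently. A minimum foreground contrast of 0.1
  marks noise-only images as empty. Otsu threshold ties (flat
  between-class-variance plateaus between well-separated modes) resolve to
  the plateau mean.
* **Duct distance** is centroid-to-centroid to the nearest in-duct cell
  (as defined, not distance to the mask boundary); distances below 1 px
  floor at transformed 0; with no in-duct cell, distances are flagged
  missing rather than zero.
* **Zero-neighbor cells** are excluded from co-localization row averages
  and tallied; undefined rows are imputed with the sample's global cluster
  proportions (flagged) when a classifier input is assembled.
* **Focal cells are excluded** from their own neighborhoods (their
  inclusion would inflate diagonals deterministically).
* **Seeds**: every stochastic entry point takes a seed, restores the
  session RNG state, and derives per-fold/per-sample child seeds below
  2^31.

# Desk-scale training of the VAE

The published training scale (latent width 6000, batch 8000, 310 epochs on
a GPU) is preserved as `vae_config_paper_scale()` but is not trainable in
this package's environment, which has no deep-learning backend in either
language; convolution forward/backward are implemented in
RcppArmadillo and verified against central-difference gradients. The desk
defaults deviate from naive scaling and were measured, not guessed:
latent 16, channels (4, 8, 16, 16, 32), batch 64, 60 epochs, Adam 3e-3
with step decay, weight decay 1e-4, and dihedral + ±3 px translation
augmentation. Two further choices matter:

* **Group-averaged encoding.** Nucleus orientation is uniformly random and
  carries no state information, but a conv encoder necessarily represents
  it; at desk scale those orientation components dominate several latent
  dimensions and poison k-means. `encode()` therefore averages the
  posterior mean over the eight exact square-grid symmetries (90°
  rotations × mirror), which cancels orientation-odd components exactly
  while preserving every rotation/mirror-invariant statistic. In
  measurements this collapsed the spurious latent dimensions ~6-fold.
* **Augmentation against memorization.** With only ~700 training cells a
  VAE will memorize individual blob patterns, filling the latent space
  with per-cell identity noise; random flips/rotations and small
  translations suppress this.

# Known limitations

The end-to-end parameter-recovery criterion (synthesize → segment → encode
→ cluster, adjusted Rand index ≥ 0.7 against the planted states at desk
scale) **does not pass** in this implementation and is deliberately left
failing rather than weakened. Measured behavior: the information is
present in the patches (clustering ideal morphometric axes of the same
cells reaches ARI 0.83–0.99), and the latent space is broadly organized
(nearest-true-centroid accuracy ~0.8), but within the one-CPU training
budget the encoder's per-cell realization noise remains comparable to the
between-state latent gaps, and the unsupervised k-means partition plateaus
near ARI ~0.5. A linear pixel-PCA encoder attains *better* state geometry
than the trained VAE, which localizes the bottleneck in optimization
scale, not in the pipeline logic. All remedies that helped (group
averaging, augmentation, bottleneck narrowing, schedules) are kept; the
criterion is expected to pass with a hardware-accelerated backend at the
published training scale.

Other limitations: the literal 201-feature list of the original study is
unavailable, so the feature set is a documented representative subset
(~45 features) covering every named family; the exact membership of the
"7 categories" used by the sample-level classifier is not derivable from
the text (the default grouping applies the two printed merges and excludes
P2/P4 from stage-level error summaries, which reproduces the count 7);
learned star-convex segmentation, PAGA and diffusion pseudotime are out of
scope — the latent table and labels export cleanly to external trajectory
tools, and a toy centroid-distance ordering is provided, clearly labeled
as not a trajectory method.
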