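# chromastate

Cell states and tissue organization from chromatin images of breast
lesions — normal tissue, hyperplasia, ductal carcinoma in situ (DCIS) and
invasive ductal carcinoma (IDC).

## What it does, and for whom

A single DNA stain (e.g. Hoechst) is far cheaper than sequencing or
multiplexed imaging, yet nuclear morphology and chromatin organization
carry enough information to define cell states and read tissue
architecture. `chromastate` is for computational pathology / quantitative
biology groups who want that analysis as a tested, reusable R pipeline:

* **Representation**: a convolutional variational autoencoder (VAE) over
  masked 96 × 96 single-nucleus patches; encoder of five strided
  convolutions, Gaussian posterior heads, mirrored decoder; loss
  `‖x − x̂‖² + β · KL(q(z|x) ‖ N(0, I))`. Per-nucleus representations are
  posterior means.
* **Cell states**: k-means (k = 8) on the top 50 principal components of
  the latent features, balanced across phenotypic categories, with
  inertia-guided subclustering and held-out assignment.
* **Morphometrics**: ~45 interpretable features (area, radial profile,
  shape factor `P²/(4πA)`, curvature, image moments, co-occurrence
  texture, heterochromatin packing); Welch tests per (feature, cluster)
  with Benjamini–Hochberg correction, selection at FDR < 0.01 and
  fold change > 1.2 or < 0.8, and correlation grouping at r > 0.8.
* **Spatial organization**: duct distances (0 inside ducts, else log pixel
  distance to the nearest in-duct cell; 1 ↔ ~0.49 µm, 5 ↔ ~26.71 µm at
  0.18 µm/px) and the 8 × 8 neighborhood co-localization matrix (25.9 µm
  radius) with a within-sample permutation null and fold changes.
* **Classification**: leave-one-patient-out MLP classifiers of phenotypic
  category from co-localization summaries, with ablation and
  misclassification-contrast analyses and a logistic baseline.
* **Synthetic cohorts**: a seeded generator of tissue cores with planted
  states, duct masks and rendered chromatin/cytokeratin channels, so the
  whole pipeline is testable offline.

## Worked example

```r
library(chromastate)

cfg <- cohort_config(n_patients = 4, samples_per_patient = 1,
                     categories = c("P0", "P10"), cells_per_sample = 40,
                     image_size_px = 260, seed = 7)
cohort <- generate_cohort(cfg)
s <- cohort[[1]]

ducts  <- segment_ducts(s$cytokeratin_image)
labels <- segment_nuclei(s$chromatin_image)
nuclei <- extract_patches(s$chromatin_image, labels, duct_mask = ducts)
ft     <- feature_table(nuclei)
pn     <- permutation_null(cbind(s$nuclei$row, s$nuclei$col),
                           s$nuclei$state, n_shuffles = 500,
                           radius_um = 25.9, seed = 1)
```

Output of the session above:

```
sample S001 category P0 - 1 duct component(s)
segmented 40 nuclei ( 8 inside ducts )
feature table: 40 cells x 45 features
mean nuclear area: 233.1 px^2; mean shape factor: 1.116
log-distance 1 -> 0.49 um; 5 -> 26.71 um
diagonal co-localization fold change (defined states):
state0 state1 state2 state3 state4 state5
  1.29   0.91   1.01   0.87   1.81   1.55
```

Reading it: the duct procedure recovered the one planted duct region; all
40 planted nuclei were re-segmented, 8 of them inside the duct; the mean
nuclear area and near-circular shape factor match the planted morphology
of a non-tumor core; the log-pixel duct-distance calibration reproduces
the printed 0.49 µm / 26.71 µm correspondences; and diagonal
co-localization fold changes above 1 reflect the planted same-state
spatial attraction (per-state estimates are noisy at 40 cells — states 4-5
here sit in/near the duct, which concentrates them spatially).

Training the VAE and clustering states on a full desk cohort:

```r
model <- train_vae(build_vae(vae_config(seed = 1)), patches_matrix(nuclei))
lat   <- encode(model, nuclei)                   # group-averaged posterior means
st    <- fit_topclusters(lat, k = 8, order_by = ft[, "size_area"])
```

## Command line

```
chromastate synth   --out DIR --seed N [--patients P --samples-per-patient S]
chromastate segment --chromatin X.tif --cytokeratin Y.tif --out DIR
chromastate coloc   --nuclei T.csv --out DIR [--radius-um R --shuffles N]
```

(`inst/cli/chromastate`; single-channel uncompressed TIFF I/O is built in.)
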