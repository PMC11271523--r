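# End-to-end state-recovery chain used by the acceptance suite (and the
# acceptance script): synthesize the desk cohort, segment every sample,
# match detected nuclei to planted ones, train the desk VAE, encode, and
# cluster into 8 states.
run_state_recovery <- function(seed = 5, match_px = 6) {
  cfg <- cohort_config(seed = seed)
  coh <- generate_cohort(cfg)
  patches <- list(); truth <- integer(0); areas <- numeric(0)
  for (s in coh) {
    lab <- segment_nuclei(s$chromatin_image)
    nuc <- extract_patches(s$chromatin_image, lab)
    if (!length(nuc)) next
    tr <- cbind(s$nuclei$row, s$nuclei$col)
    for (i in seq_along(nuc)) {
      d <- sqrt((tr[, 1] - nuc[[i]]$centroid[1])^2 +
                  (tr[, 2] - nuc[[i]]$centroid[2])^2)
      j <- which.min(d)
      if (d[j] < match_px) {
        patches[[length(patches) + 1]] <- nuc[[i]]
        truth <- c(truth, s$nuclei$state[j])
        areas <- c(areas, nuc[[i]]$area)
      }
    }
  }
  X <- patches_matrix(patches)
  model <- train_vae(build_vae(vae_config(seed = seed)), X)
  lat <- encode(model, X)
  st <- fit_topclusters(lat, k = 8, order_by = areas, seed = seed)
  list(ari = adjusted_rand_index(st$labels, truth),
       n_cells = length(truth), labels = st$labels, truth = truth,
       latents = lat, model = model)
}

# The exchangeable-labels sample used for the permutation-null criterion.
make_exchangeable_core <- function(seed = 2) {
  morph <- default_state_morphology()
  morph$area_px2 <- 100; morph$aspect <- 1.1
  morph$heterogeneity <- 0.4; morph$base_intensity <- 0.5
  cfg <- cohort_config(
    n_patients = 1, samples_per_patient = 1, categories = "P0",
    state_proportions = matrix(rep(1 / 8, 8), 1, dimnames = list("P0", NULL)),
    assortativity = 0, duct_affinity = rep(0, 8),
    cells_per_sample = 800, image_size_px = 620,
    morphology = morph, patient_effect_conc = Inf, seed = seed)
  generate_cohort(cfg)[[1]]
}

# Cohort with planted category-specific co-localization (distinct state
# proportions per category plus same-state spatial attraction).
make_coloc_cohort <- function(seed = 17) {
  generate_cohort(cohort_config(
    n_patients = 8, samples_per_patient = 3,
    categories = c("P0", "P3", "P7", "P10"),
    cells_per_sample = 50, image_size_px = 300,
    assortativity = 0.8, seed = seed))
}

# Two-category cohort whose only class signal is the spatial arrangement of
# clusters 3 and 7 (identical proportions; one category clumps, the other
# is random). Ablating cluster 7 removes the signal.
make_ablation_cohort <- function(seed_a = 71, seed_b = 72) {
  p37 <- c(0.01, 0.01, 0.01, 0.48, 0.01, 0.01, 0.01, 0.46)
  mk <- function(cat, assort, seed) cohort_config(
    n_patients = 4, samples_per_patient = 2, categories = cat,
    state_proportions = matrix(p37, 1, dimnames = list(cat, NULL)),
    assortativity = assort, duct_affinity = rep(0, 8),
    cells_per_sample = 50, image_size_px = 300,
    patient_effect_conc = Inf, seed = seed)
  cohA <- generate_cohort(mk("P0", 1.5, seed_a))
  cohB <- generate_cohort(mk("P10", 0, seed_b))
  for (i in seq_along(cohB)) {
    cohB[[i]]$patient_id <- sub("PT0", "PT1", cohB[[i]]$patient_id)
  }
  c(cohA, cohB)
}
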