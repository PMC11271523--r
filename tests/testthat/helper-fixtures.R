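# Shared fixtures, built in code. Heavy objects are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

make_disk <- function(radius, size = 96, value = 0.5) {
  half <- size / 2
  m <- outer(seq_len(size) - half, seq_len(size) - half,
             function(y, x) as.integer(y^2 + x^2 <= radius^2))
  list(mask = m, patch = m * value)
}

make_ellipse <- function(a, b, size = 96, value = 0.5) {
  half <- size / 2
  m <- outer(seq_len(size) - half, seq_len(size) - half,
             function(y, x) as.integer((x / a)^2 + (y / b)^2 <= 1))
  list(mask = m, patch = m * value)
}

# Small two-category cohort used across module tests.
tiny_cohort <- function() {
  memo("tiny_cohort", {
    generate_cohort(cohort_config(
      n_patients = 2, samples_per_patient = 1,
      categories = c("P0", "P10"), cells_per_sample = 20,
      image_size_px = 220, seed = 101))
  })
}

# A cohort whose labels are exchangeable by construction: all states share
# one morphology, no duct affinity, no assortativity.
exchangeable_sample <- function(n_cells = 150, seed = 7) {
  memo(paste0("exch", n_cells, "_", seed), {
    morph <- default_state_morphology()
    morph$area_px2 <- 200
    morph$aspect <- 1.2
    morph$heterogeneity <- 0.4
    morph$base_intensity <- 0.5
    cfg <- cohort_config(
      n_patients = 1, samples_per_patient = 1, categories = "P0",
      state_proportions = matrix(rep(1 / 8, 8), 1,
                                 dimnames = list("P0", NULL)),
      assortativity = 0, duct_affinity = rep(0, 8),
      cells_per_sample = n_cells, image_size_px = 350,
      morphology = morph, patient_effect_conc = Inf, seed = seed)
    generate_cohort(cfg)[[1]]
  })
}

# Four visually distinct morphotypes for representation contract tests.
probe_patches <- function(n_per = 30, seed = 42) {
  memo(paste0("probe", n_per, "_", seed), {
    morph <- data.frame(
      state = 0:3,
      area_px2 = c(150, 600, 150, 600),
      aspect = c(1, 1, 2.2, 2.2),
      roughness = 0.04,
      heterogeneity = c(0.2, 0.9, 0.9, 0.2),
      base_intensity = c(0.35, 0.75, 0.75, 0.35))
    chromastate:::with_seed(seed, {
      out <- list(); lab <- integer(0)
      for (s in 0:3) for (i in seq_len(n_per)) {
        r <- render_nucleus(s, morph)
        out[[length(out) + 1]] <- list(nucleus_id = length(out) + 1,
                                       patch = r$patch, mask = r$mask)
        lab <- c(lab, s)
      }
      list(patches = out, labels = lab)
    })
  })
}
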