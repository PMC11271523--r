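#' Default per-state nuclear morphology parameters
#'
#' Eight planted cell states on four morphological axes: mean nuclear area
#' increases monotonically with state index (healthy-like small nuclei at
#' state 0 through malignant-like large nuclei at state 7, ~1.7x total — the
#' magnitude of nuclear enlargement typical of low-to-high-grade ductal
#' lesions). Orthogonally to size, the states form a factorial design over
#' chromatin heterogeneity (peripheral heterochromatin rim and blob
#' contrast; alternating states), elongation (aspect ratio; alternating
#' pairs), and hyperchromasia (overall staining intensity; states 4-7, as in
#' malignant nuclei). Each state is therefore identified by a distinct
#' combination of discrete, image-visible properties while sharing the
#' continuous size trend. Areas are in px^2 at the miniaturized desk scale.
#'
#' @return data.frame with one row per state 0..7: `state`, `area_px2`,
#'   `aspect`, `roughness`, `heterogeneity`, `base_intensity`.
#' @export
default_state_morphology <- function() {
  data.frame(
    state = 0:7,
    area_px2 = round(170 * 1.08^(0:7)),
    aspect = rep(c(1, 1, 2, 2), 2),
    roughness = 0.06,
    heterogeneity = rep(c(0.2, 0.9), 4),
    base_intensity = rep(c(0.40, 0.66), each = 4)
  )
}

#' Default per-category planted state proportions
#'
#' Smooth enrichment gradient over the phenotypic ordering P0..P10: states
#' 0-2 are enriched in non-tumor categories and states 5-7 in DCIS/IDC
#' categories, with every state present in every category.
#'
#' @param categories character vector of category codes `"P0".."P10"`.
#' @param kappa gradient strength (default 2.7).
#' @return matrix `length(categories)` x 8, rows summing to 1.
#' @export
default_state_proportions <- function(categories, kappa = 2.7) {
  m <- as.numeric(sub("^P", "", categories)) / 10
  w <- outer(2 * m - 1, (0:7) / 7)
  p <- exp(kappa * w)
  p <- p / rowSums(p)
  rownames(p) <- categories
  colnames(p) <- paste0("state", 0:7)
  p
}

#' Disease stage of a phenotypic category
#'
#' Default mapping: P0-P4 non-tumor, P5-P8 DCIS, P9-P10 IDC. (P2, tissue
#' adjacent to invasive carcinoma, is grouped with non-tumor here; it is
#' excluded from stage-level error summaries by the default grouping in the
#' classification module.)
#'
#' @param category character vector of `"P0".."P10"` codes.
#' @return character vector of `"non-tumor"`, `"DCIS"`, `"IDC"`.
#' @export
stage_of_category <- function(category) {
  k <- as.integer(sub("^P", "", category))
  ifelse(k <= 4, "non-tumor", ifelse(k <= 8, "DCIS", "IDC"))
}

#' Synthetic cohort configuration
#'
#' Describes a synthetic tissue-microarray cohort: patients, samples, planted
#' cell-state proportions per phenotypic category, spatial interaction
#' parameters, nucleus morphology and rendering noise.
#'
#' @param n_patients number of patients (default 6).
#' @param samples_per_patient samples (cores) per patient (default 2).
#' @param categories category codes used; patients are assigned to
#'   categories round-robin. Default 7 categories spanning the three stages.
#' @param pixel_size_um microns per pixel (default 0.18).
#' @param image_size_px square image side (default 300).
#' @param cells_per_sample nuclei per sample (default 60, must be >= 8).
#' @param state_proportions matrix `length(categories)` x 8 of planted state
#'   probabilities; every entry must be positive and rows sum to 1.
#' @param assortativity scalar >= 0; strength of same-state spatial
#'   attraction (default 0.6).
#' @param attract_radius_px radius of the same-state attraction kernel
#'   (default 50 px).
#' @param duct_affinity length-8 log-weights for placement inside ducts;
#'   default increases with state index so malignant-like states sit in and
#'   near ducts.
#' @param morphology per-state morphology, see [default_state_morphology()].
#' @param patient_effect_conc Dirichlet concentration of the patient-level
#'   random effect on state proportions; `Inf` disables it (default 200,
#'   mild between-patient heterogeneity).
#' @param n_ducts_range integer range of duct regions per sample.
#' @param noise rendering noise levels: `bg_level`, `bg_sd` (chromatin
#'   background), `ck_in`, `ck_out`, `ck_sd` (cytokeratin channel).
#' @param seed RNG seed.
#' @return object of class `chs_cohort_config`.
#' @export
cohort_config <- function(n_patients = 6,
                          samples_per_patient = 2,
                          categories = c("P0", "P1", "P3", "P5", "P7", "P9", "P10"),
                          pixel_size_um = 0.18,
                          image_size_px = 300,
                          cells_per_sample = 60,
                          state_proportions = default_state_proportions(categories),
                          assortativity = 0.6,
                          attract_radius_px = 50,
                          duct_affinity = c(0, 0, 0, 0.3, 0.6, 1.0, 1.4, 1.8),
                          morphology = default_state_morphology(),
                          patient_effect_conc = 200,
                          n_ducts_range = c(1L, 3L),
                          noise = list(bg_level = 0.04, bg_sd = 0.012,
                                       ck_in = 0.7, ck_out = 0.08, ck_sd = 0.05),
                          seed = 1L) {
  state_proportions <- as.matrix(state_proportions)
  if (is.null(rownames(state_proportions)))
    rownames(state_proportions) <- categories
  if (nrow(state_proportions) != length(categories) ||
      ncol(state_proportions) != 8)
    stop_config("state_proportions must be %d x 8", length(categories))
  if (any(state_proportions <= 0))
    stop_config("all state proportions must be > 0 (all states in all categories)")
  if (any(abs(rowSums(state_proportions) - 1) > 1e-6))
    stop_config("each state_proportions row must sum to 1")
  if (pixel_size_um <= 0) stop_config("pixel_size_um must be > 0")
  if (cells_per_sample < 8) stop_config("cells_per_sample must be >= 8")
  if (assortativity < 0) stop_config("assortativity must be >= 0")
  if (length(duct_affinity) != 8) stop_config("duct_affinity must have length 8")
  structure(list(
    n_patients = n_patients, samples_per_patient = samples_per_patient,
    categories = categories, pixel_size_um = pixel_size_um,
    image_size_px = image_size_px, cells_per_sample = cells_per_sample,
    state_proportions = state_proportions, assortativity = assortativity,
    attract_radius_px = attract_radius_px, duct_affinity = duct_affinity,
    morphology = morphology, patient_effect_conc = patient_effect_conc,
    n_ducts_range = as.integer(n_ducts_range), noise = noise,
    seed = as.integer(seed)
  ), class = "chs_cohort_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Render one synthetic nucleus
#'
#' Draws an ellipse with the state's mean area and aspect ratio, perturbs the
#' boundary with low-order Fourier roughness, and fills the interior with a
#' smoothed blob texture whose contrast scales with the heterogeneity
#' parameter. Pixels outside the mask are 0 and the nucleus is centered at
#' patch pixel (48, 48) (0-based).
#'
#' @param state state index 0..7 (used to look up `morphology`).
#' @param morphology data.frame as from [default_state_morphology()].
#' @param patch_size patch side (default 96).
#' @param jitter logical; sample per-cell area/aspect variability
#'   (lognormal, sd 0.1 / 0.05). `FALSE` renders the state mean exactly.
#' @return list with `mask` (binary matrix), `patch` (intensity matrix),
#'   `max_radius` (px from center to farthest mask pixel).
#' @export
render_nucleus <- function(state, morphology = default_state_morphology(),
                           patch_size = 96, jitter = TRUE) {
  mp <- morphology[morphology$state == state, ]
  if (nrow(mp) != 1) stop_config("unknown state %s", state)
  if (any(c(mp$area_px2, mp$aspect) <= 0)) stop_config("morphology params must be positive")
  area <- mp$area_px2
  aspect <- mp$aspect
  if (jitter) {
    area <- area * exp(rnorm(1, 0, 0.1))
    aspect <- aspect * exp(rnorm(1, 0, 0.05))
  }
  a <- sqrt(area * aspect / pi)   # semi-major
  b <- sqrt(area / (aspect * pi)) # semi-minor
  if (a * (1 + 3 * mp$roughness) >= patch_size / 2 - 1)
    stop_config("requested area %.0f px^2 too large for %dx%d patch",
                area, patch_size, patch_size)
  theta0 <- runif(1, 0, pi)
  # low-order Fourier boundary roughness
  nh <- 3:6
  ca <- rnorm(length(nh), 0, sqrt(1 / (2 * length(nh))))
  sa <- rnorm(length(nh), 0, sqrt(1 / (2 * length(nh))))
  half <- patch_size %/% 2
  off <- seq_len(patch_size) - 1 - half      # -48..47
  dy <- matrix(off, patch_size, patch_size)
  dx <- matrix(off, patch_size, patch_size, byrow = TRUE)
  th <- atan2(dy, dx)
  rr <- sqrt(dy^2 + dx^2)
  rough <- matrix(0, patch_size, patch_size)
  for (i in seq_along(nh)) {
    rough <- rough + ca[i] * cos(nh[i] * th) + sa[i] * sin(nh[i] * th)
  }
  r_ell <- a * b / sqrt((b * cos(th - theta0))^2 + (a * sin(th - theta0))^2)
  r_b <- r_ell * (1 + mp$roughness * rough)
  mask <- (rr <= r_b) * 1L
  inside <- mask == 1
  # chromatin texture: heterogeneity manifests as spatially organized
  # heterochromatin (a peripheral rim, as at the nuclear envelope, plus
  # condensed blobs), so that it is visible both to texture features and to
  # a learned image representation
  field <- gaussian_blur(matrix(rnorm(patch_size^2), patch_size), 3)
  f <- field[inside]
  f <- (f - mean(f)) / max(sd(f), 1e-9)
  rel <- rr[inside] / pmax(r_b[inside], 1e-9)
  rim <- pmin(pmax((rel - 0.72) / 0.28, 0), 1)
  base <- (mp$base_intensity %||% 0.5) + if (jitter) rnorm(1, 0, 0.012) else 0
  intens <- matrix(0, patch_size, patch_size)
  # heterochromatin-rich nuclei stain brighter (condensed DNA), carry a
  # peripheral rim (envelope-associated heterochromatin), and show stronger
  # blob contrast; the rim term is centered so rim shape and mean brightness
  # are separate readouts
  intens[inside] <- pmin(pmax(
    base + mp$heterogeneity * (0.18 + 0.3 * (rim - 0.2) + 0.22 * f),
    0.08), 1)
  list(mask = mask, patch = intens, max_radius = max(rr[inside]))
}

make_duct_mask <- function(H, W, n_ducts) {
  m <- matrix(0L, H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(n_ducts)) {
    ry <- runif(1, 0.10, 0.20) * H
    rx <- runif(1, 0.10, 0.20) * W
    cy <- runif(1, ry + 1, H - ry)
    cx <- runif(1, rx + 1, W - rx)
    ang <- runif(1, 0, pi)
    u <- (xx - cx) * cos(ang) + (yy - cy) * sin(ang)
    v <- -(xx - cx) * sin(ang) + (yy - cy) * cos(ang)
    m[(u / rx)^2 + (v / ry)^2 <= 1] <- 1L
  }
  m
}

place_cells <- function(states, radii, duct_mask, config) {
  H <- nrow(duct_mask); W <- ncol(duct_mask)
  n <- length(states)
  ord <- order(radii, decreasing = TRUE)
  ys <- xs <- rep(NA_real_, n)
  placed <- integer(0)
  margin <- 2
  R2 <- config$attract_radius_px^2
  n_cand <- 12L
  for (i in ord) {
    r <- radii[i]
    best <- NULL
    cand_y <- cand_x <- cand_s <- numeric(0)
    tries <- 0
    while (length(cand_y) < n_cand && tries < 300) {
      tries <- tries + 1
      py <- runif(1, r + 1, H - r - 2)
      px <- runif(1, r + 1, W - r - 2)
      if (length(placed)) {
        dd <- sqrt((ys[placed] - py)^2 + (xs[placed] - px)^2)
        if (any(dd < radii[placed] + r + margin)) next
      }
      inside <- duct_mask[round(py) + 1, round(px) + 1] > 0
      score <- config$duct_affinity[states[i] + 1] * inside
      if (config$assortativity > 0 && length(placed)) {
        same <- placed[states[placed] == states[i]]
        if (length(same)) {
          nsame <- sum((ys[same] - py)^2 + (xs[same] - px)^2 <= R2)
          score <- score + config$assortativity * min(nsame, 4)
        }
      }
      cand_y <- c(cand_y, py); cand_x <- c(cand_x, px); cand_s <- c(cand_s, score)
    }
    if (!length(cand_y)) next  # placement failure for this cell
    pick <- sample.int(length(cand_s), 1, prob = exp(cand_s - max(cand_s)))
    ys[i] <- cand_y[pick]; xs[i] <- cand_x[pick]
    placed <- c(placed, i)
  }
  list(row = round(ys), col = round(xs), ok = !is.na(ys))
}

generate_sample <- function(sample_id, patient_id, core_id, category, props,
                            config) {
  H <- W <- config$image_size_px
  n_ducts <- if (config$n_ducts_range[1] == config$n_ducts_range[2])
    config$n_ducts_range[1] else
    sample(config$n_ducts_range[1]:config$n_ducts_range[2], 1)
  duct <- make_duct_mask(H, W, n_ducts)
  states <- sample(0:7, config$cells_per_sample, replace = TRUE, prob = props)
  rend <- lapply(states, render_nucleus, morphology = config$morphology)
  radii <- vapply(rend, `[[`, numeric(1), "max_radius")
  pos <- place_cells(states, radii, duct, config)
  keep <- which(pos$ok)
  chrom <- matrix(0, H, W)
  half <- 48L
  for (i in keep) {
    p <- rend[[i]]$patch
    ys <- (pos$row[i] - half):(pos$row[i] + half - 1)
    xs <- (pos$col[i] - half):(pos$col[i] + half - 1)
    vy <- ys >= 0 & ys < H
    vx <- xs >= 0 & xs < W
    chrom[ys[vy] + 1, xs[vx] + 1] <- chrom[ys[vy] + 1, xs[vx] + 1] +
      p[vy, vx, drop = FALSE]
  }
  nz <- config$noise
  if (nz$bg_level > 0 || nz$bg_sd > 0) {
    chrom <- clamp01(chrom + nz$bg_level + nz$bg_sd * matrix(rnorm(H * W), H, W))
  }
  ck <- nz$ck_out + (nz$ck_in - nz$ck_out) * gaussian_blur(duct + 0, 2)
  if (nz$ck_sd > 0) ck <- ck + nz$ck_sd * matrix(rnorm(H * W), H, W)
  ck <- clamp01(ck)
  nuclei <- data.frame(
    nucleus_id = seq_along(keep),
    row = pos$row[keep], col = pos$col[keep],
    state = states[keep]
  )
  structure(list(
    sample_id = sample_id, patient_id = patient_id, core_id = core_id,
    category = category, stage = stage_of_category(category),
    chromatin_image = chrom, cytokeratin_image = ck,
    duct_mask_truth = duct, nuclei = nuclei,
    nucleus_masks = lapply(rend[keep], `[[`, "mask"),
    n_failed = sum(!pos$ok)
  ), class = "chs_sample")
}

#' Generate a seeded synthetic cohort
#'
#' Produces a list of synthetic tissue-core samples with planted cell states.
#' Patients are assigned to phenotypic categories round-robin; each patient
#' receives a Dirichlet-perturbed copy of their category's state proportions
#' (the patient random effect); per sample, duct regions are placed first and
#' cells are then placed sequentially with a hard-core non-overlap constraint
#' and softmax acceptance weights combining per-state duct affinity and a
#' same-state attraction kernel scaled by `assortativity`. The whole cohort
#' is deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `chs_cohort`: list of `chs_sample` with attribute
#'   `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 2, samples_per_patient = 1,
#'                      categories = c("P0", "P10"),
#'                      cells_per_sample = 10, image_size_px = 200, seed = 7)
#' coh <- generate_cohort(cfg)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "chs_cohort_config"))
  with_seed(config$seed, {
    cat_of_patient <- config$categories[
      (seq_len(config$n_patients) - 1) %% length(config$categories) + 1]
    samples <- list()
    sid <- 0
    for (p in seq_len(config$n_patients)) {
      cat <- cat_of_patient[p]
      base <- config$state_proportions[cat, ]
      props <- if (is.finite(config$patient_effect_conc))
        rdirichlet1(base * config$patient_effect_conc) else base
      for (s in seq_len(config$samples_per_patient)) {
        sid <- sid + 1
        samples[[sid]] <- generate_sample(
          sample_id = sprintf("S%03d", sid),
          patient_id = sprintf("PT%02d", p),
          core_id = s, category = cat, props = props, config = config)
      }
    }
    structure(samples, class = "chs_cohort", config = config)
  })
}

#' Ground-truth nucleus table of a synthetic cohort
#'
#' @param cohort a `chs_cohort`.
#' @return data.frame with one row per planted nucleus: `sample_id`,
#'   `patient_id`, `core_id`, `category`, `stage`, `nucleus_id`, `row`,
#'   `col`, `state`.
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    cbind(data.frame(sample_id = s$sample_id, patient_id = s$patient_id,
                     core_id = s$core_id, category = s$category,
                     stage = s$stage, stringsAsFactors = FALSE),
          s$nuclei)
  }))
}

#' Write a synthetic sample to disk
#'
#' Writes the chromatin and cytokeratin channels and the truth duct mask as
#' 16-bit grayscale TIFFs, plus the ground-truth nucleus table as CSV.
#'
#' @param sample a `chs_sample`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    chromatin = file.path(dir, paste0(sample$sample_id, "_chromatin.tif")),
    cytokeratin = file.path(dir, paste0(sample$sample_id, "_cytokeratin.tif")),
    duct = file.path(dir, paste0(sample$sample_id, "_duct_truth.tif")),
    truth = file.path(dir, paste0(sample$sample_id, "_nuclei.csv"))
  )
  write_tiff_gray16(sample$chromatin_image, paths["chromatin"])
  write_tiff_gray16(sample$cytokeratin_image, paths["cytokeratin"])
  write_tiff_gray16(sample$duct_mask_truth, paths["duct"])
  write.csv(cbind(sample_id = sample$sample_id, patient_id = sample$patient_id,
                  category = sample$category, sample$nuclei),
            paths["truth"], row.names = FALSE)
  invisible(paths)
}
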