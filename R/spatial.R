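#' Duct distance with log transform
#'
#' Cells inside ducts get distance 0. Every other cell gets the Euclidean
#' distance (in pixels) from its centroid to the centroid of the nearest
#' in-duct cell, then the natural log of that pixel distance; distances
#' below 1 px are floored at a transformed value of 0 so the transform stays
#' monotone and inside-duct cells are exactly 0. At 0.18 um/pixel the
#' transformed value 1 corresponds to about 0.49 um and 5 to about 26.71 um.
#'
#' @param centroids 2-column matrix (row, col) in pixels.
#' @param inside_duct logical vector per cell.
#' @param pixel_size_um microns per pixel (default 0.18).
#' @return data.frame `raw_px`, `transformed`, `um`, `inside_duct`. When no
#'   cell is inside a duct, out-of-duct distances are `NA` (flagged missing,
#'   not 0).
#' @export
duct_distance <- function(centroids, inside_duct, pixel_size_um = 0.18) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  stopifnot(length(inside_duct) == n)
  raw <- numeric(n)
  if (!any(inside_duct)) {
    raw[!inside_duct] <- NA_real_
  } else if (any(!inside_duct)) {
    ref <- centroids[inside_duct, , drop = FALSE]
    out_i <- which(!inside_duct)
    d2 <- outer(rowSums(centroids[out_i, , drop = FALSE]^2),
                rowSums(ref^2), "+") -
      2 * centroids[out_i, , drop = FALSE] %*% t(ref)
    raw[out_i] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  transformed <- ifelse(is.na(raw), NA_real_, ifelse(raw <= 1, 0, log(raw)))
  data.frame(raw_px = raw, transformed = transformed,
             um = duct_log_to_um(transformed, pixel_size_um),
             inside_duct = inside_duct)
}

#' Convert a log-pixel duct distance to microns
#'
#' `exp(transformed) * pixel_size_um`; the calibration used on duct-distance
#' axes (transformed value 1 is ~0.49 um and 5 is ~26.71 um at 0.18
#' um/pixel).
#'
#' @param transformed natural-log pixel distance.
#' @param pixel_size_um microns per pixel (default 0.18).
#' @return distance in microns.
#' @export
duct_log_to_um <- function(transformed, pixel_size_um = 0.18) {
  exp(transformed) * pixel_size_um
}

#' Neighborhood cluster counts around each cell
#'
#' Counts, for every focal cell, the cells of each cluster whose centroid
#' lies within `radius_um` of the focal centroid (the focal cell itself is
#' excluded). Implemented with a uniform-grid spatial index; a brute-force
#' O(n^2) scan is available via `method = "brute"` as the verification
#' oracle.
#'
#' @param centroids 2-column matrix (row, col) px.
#' @param labels integer cluster labels 0..k-1.
#' @param radius_um neighborhood radius in microns (default 25.9, i.e. a
#'   51.8 um diameter circle).
#' @param pixel_size_um microns per pixel (default 0.18).
#' @param k number of clusters (default 8).
#' @param method `"grid"` (default) or `"brute"`.
#' @return integer matrix n x k of neighbor counts.
#' @export
neighborhood_counts <- function(centroids, labels, radius_um = 25.9,
                                pixel_size_um = 0.18, k = 8,
                                method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(radius_um > 0, all(labels >= 0 & labels < k))
  r_px <- radius_um / pixel_size_um
  nb <- neighbor_pairs(centroids, r_px, method)
  counts <- matrix(0L, nrow(centroids), k)
  if (nrow(nb)) {
    counts <- as.matrix(Matrix::sparseMatrix(
      i = nb[, 1], j = labels[nb[, 2]] + 1L, x = 1,
      dims = c(nrow(centroids), k)))
    storage.mode(counts) <- "integer"
  }
  counts
}

# Symmetric neighbor pair list (i, j) with i != j and dist <= r_px.
neighbor_pairs <- function(centroids, r_px, method = "grid") {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) return(matrix(integer(0), 0, 2))
  if (method == "brute") {
    d <- as.matrix(dist(centroids))
    idx <- which(d <= r_px & row(d) != col(d), arr.ind = TRUE)
    return(unname(idx))
  }
  cell <- floor(centroids / r_px)
  key <- paste(cell[, 1], cell[, 2])
  buckets <- split(seq_len(n), key)
  coords <- unique(cell)
  out_i <- integer(0); out_j <- integer(0)
  for (b in seq_len(nrow(coords))) {
    cy <- coords[b, 1]; cx <- coords[b, 2]
    focal <- buckets[[paste(cy, cx)]]
    cand <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      bb <- buckets[[paste(cy + dy, cx + dx)]]
      if (!is.null(bb)) cand <- c(cand, bb)
    }
    if (length(cand) < 2) next
    d2 <- outer(rowSums(centroids[focal, , drop = FALSE]^2),
                rowSums(centroids[cand, , drop = FALSE]^2), "+") -
      2 * centroids[focal, , drop = FALSE] %*%
      t(centroids[cand, , drop = FALSE])
    hit <- which(d2 <= r_px^2 + 1e-9, arr.ind = TRUE)
    ii <- focal[hit[, 1]]; jj <- cand[hit[, 2]]
    keep <- ii != jj
    out_i <- c(out_i, ii[keep]); out_j <- c(out_j, jj[keep])
  }
  cbind(out_i, out_j)
}

#' Cell-state co-localization matrix
#'
#' For every focal cell with at least one neighbor, the neighbor counts are
#' normalized to proportions; row `i` of the matrix is the mean proportion
#' vector over focal cells of cluster `i`. Cells with zero neighbors are
#' excluded from the averages and tallied. Rows for clusters with no
#' eligible focal cell are `NA` and flagged undefined.
#'
#' @param counts n x k matrix from [neighborhood_counts()].
#' @param labels integer labels 0..k-1.
#' @return object of class `chs_coloc`: list with `matrix` (k x k),
#'   `defined` (logical per row), `n_focal` (per row), `n_excluded`.
#' @export
coloc_matrix <- function(counts, labels) {
  k <- ncol(counts)
  tot <- rowSums(counts)
  elig <- tot > 0
  P <- counts[elig, , drop = FALSE] / tot[elig]
  lab <- labels[elig]
  M <- matrix(NA_real_, k, k)
  n_focal <- integer(k)
  for (i in seq_len(k) - 1L) {
    sel <- lab == i
    n_focal[i + 1] <- sum(sel)
    if (any(sel)) M[i + 1, ] <- colMeans(P[sel, , drop = FALSE])
  }
  dimnames(M) <- list(paste0("state", seq_len(k) - 1),
                      paste0("state", seq_len(k) - 1))
  structure(list(matrix = M, defined = n_focal > 0, n_focal = n_focal,
                 n_excluded = sum(!elig)),
            class = "chs_coloc")
}

#' Permutation null and fold change for the co-localization matrix
#'
#' Shuffles the cluster assignment of all cells within the sample (geometry
#' fixed), recomputes the co-localization matrix per shuffle, and averages.
#' Fold change is observed / null-mean elementwise (NA where the null entry
#' is undefined or 0).
#'
#' @param centroids 2-column matrix px.
#' @param labels integer labels 0..k-1.
#' @param n_shuffles shuffles (desk default 2000; the full-scale reference
#'   setting is 40000).
#' @param radius_um,pixel_size_um,k as in [neighborhood_counts()].
#' @param seed RNG seed.
#' @return object of class `chs_perm_null`: `observed`, `null_mean`,
#'   `fold_change`, `log2_fold_change`, `n_shuffles`, `seed`.
#' @export
permutation_null <- function(centroids, labels, n_shuffles = 2000,
                             radius_um = 25.9, pixel_size_um = 0.18, k = 8,
                             seed = 1L) {
  if (n_shuffles < 1) stop_config("n_shuffles must be >= 1")
  if (length(unique(labels)) < 2) stop_config("need >= 2 clusters present")
  n <- nrow(centroids)
  r_px <- radius_um / pixel_size_um
  nb <- neighbor_pairs(centroids, r_px)
  A <- Matrix::sparseMatrix(i = nb[, 1], j = nb[, 2], x = 1,
                            dims = c(n, n))
  obs <- coloc_from_adjacency(A, labels, k)
  acc <- matrix(0, k, k)
  cnt <- matrix(0, k, k)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      lp <- labels[sample.int(n)]
      M <- coloc_from_adjacency(A, lp, k)$matrix
      def <- !is.na(M)
      acc[def] <- acc[def] + M[def]
      cnt <- cnt + def
    }
  })
  null_mean <- ifelse(cnt > 0, acc / cnt, NA_real_)
  fc <- obs$matrix / null_mean
  fc[!is.finite(fc)] <- NA_real_
  structure(list(observed = obs$matrix, null_mean = null_mean,
                 fold_change = fc, log2_fold_change = log2(fc),
                 n_shuffles = n_shuffles, seed = seed),
            class = "chs_perm_null")
}

# Row-averaged neighbor-proportion matrix from a sparse adjacency.
coloc_from_adjacency <- function(A, labels, k) {
  n <- length(labels)
  L <- Matrix::sparseMatrix(i = seq_len(n), j = labels + 1L, x = 1,
                            dims = c(n, k))
  counts <- as.matrix(A %*% L)
  coloc_matrix(counts, labels)
}

#' Sample-level co-localization representation for classification
#'
#' Flattens the k x k co-localization matrix (undefined rows imputed with
#' the sample's global cluster proportions, flagged) and appends the cell
#' density (cells per unit area). Variants: cluster proportions only, both,
#' or ablation of one cluster (7 x 7 matrix plus density).
#'
#' @param coloc `chs_coloc` for the sample.
#' @param labels integer labels of the sample's cells.
#' @param area sample area (e.g. px^2 or um^2; the unit only needs to be
#'   consistent across samples).
#' @param variant `"coloc"`, `"props"`, or `"both"`.
#' @param k number of clusters (default 8).
#' @return named numeric vector (length 65 for the default 8-state matrix
#'   plus density; 50 after one-cluster ablation).
#' @export
sample_representation <- function(coloc, labels, area,
                                  variant = c("coloc", "props", "both"),
                                  k = 8) {
  variant <- match.arg(variant)
  props <- tabulate(labels + 1L, nbins = k) / max(length(labels), 1)
  M <- coloc$matrix
  for (i in which(!coloc$defined)) M[i, ] <- props
  out <- switch(variant,
                coloc = as.numeric(t(M)),
                props = props,
                both = c(as.numeric(t(M)), props))
  nm <- switch(variant,
               coloc = as.vector(t(outer(rownames(M), colnames(M), paste,
                                         sep = "_to_"))),
               props = paste0("prop_", seq_len(k) - 1),
               both = c(as.vector(t(outer(rownames(M), colnames(M), paste,
                                          sep = "_to_"))),
                        paste0("prop_", seq_len(k) - 1)))
  res <- c(out, density = length(labels) / area)
  names(res) <- c(nm, "cell_density")
  res
}

#' Compute per-sample co-localization representations for a cohort
#'
#' Convenience wrapper running [neighborhood_counts()], [coloc_matrix()] and
#' [sample_representation()] over a synthetic cohort (or any list of
#' samples with `nuclei` tables), using the planted or assigned state
#' labels.
#'
#' @param cohort `chs_cohort` or list of `chs_sample`.
#' @param radius_um neighborhood radius (default 25.9 um).
#' @param variant passed to [sample_representation()].
#' @param ablate optional cluster id 0..7 whose cells are removed before the
#'   matrix is computed (the ablation study input).
#' @param labels_list optional list of per-sample label vectors overriding
#'   the planted states.
#' @return list with `X` (samples x features matrix), `meta` (data.frame of
#'   sample_id, patient_id, category, stage).
#' @export
cohort_representations <- function(cohort, radius_um = 25.9,
                                   variant = "coloc", ablate = NULL,
                                   labels_list = NULL) {
  cfg <- attr(cohort, "config")
  px_um <- if (!is.null(cfg)) cfg$pixel_size_um else 0.18
  rows <- list()
  meta <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    labs <- if (!is.null(labels_list)) labels_list[[i]] else s$nuclei$state
    cent <- cbind(s$nuclei$row, s$nuclei$col)
    keep_k <- 8L
    if (!is.null(ablate)) {
      keep <- labs != ablate
      if (!any(keep)) next
      cent <- cent[keep, , drop = FALSE]
      labs <- labs[keep]
      # compact remaining labels to 0..6 preserving order
      lv <- setdiff(0:7, ablate)
      labs <- match(labs, lv) - 1L
      keep_k <- 7L
    }
    cnt <- neighborhood_counts(cent, labs, radius_um = radius_um,
                               pixel_size_um = px_um, k = keep_k)
    cm <- coloc_matrix(cnt, labs)
    area <- nrow(s$chromatin_image) * ncol(s$chromatin_image)
    rows[[length(rows) + 1]] <-
      sample_representation(cm, labs, area, variant = variant, k = keep_k)
    meta[[length(meta) + 1]] <- data.frame(
      sample_id = s$sample_id, patient_id = s$patient_id,
      category = s$category, stage = s$stage, stringsAsFactors = FALSE)
  }
  list(X = do.call(rbind, rows), meta = do.call(rbind, meta))
}
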