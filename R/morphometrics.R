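# Nuclear morphometry / chromatin organization (NMCO) features.
#
# The feature set is a documented representative subset (~45 features)
# spanning the families used for cell-state characterization: size, radial
# profile, shape, boundary curvature, image moments, co-occurrence texture,
# intensity statistics, and heterochromatin packing. Names are namespaced by
# family prefix so the set can be extended without collisions.
#
# Boundary-dependent features (radius profile, perimeter, curvature) use an
# angular radius profile about the mask centroid, Gaussian-smoothed to
# suppress pixelation; this is exact for star-convex nuclei, which is the
# regime of both the synthetic generator and typical epithelial nuclei.

radius_profile <- function(mask, n_theta = NULL, smooth_sd = 2) {
  px <- which(mask == 1, arr.ind = TRUE)
  if (is.null(n_theta)) {
    # one bin per ~boundary pixel: finer binning would leave wedges without
    # a true boundary pixel and bias the profile low
    r_eq <- sqrt(nrow(px) / pi)
    n_theta <- min(180L, max(32L, floor(2 * pi * r_eq)))
  }
  cy <- mean(px[, 1]); cx <- mean(px[, 2])
  dy <- px[, 1] - cy; dx <- px[, 2] - cx
  th <- atan2(dy, dx)
  rr <- sqrt(dy^2 + dx^2)
  bin <- floor((th + pi) / (2 * pi) * n_theta) + 1
  bin[bin > n_theta] <- n_theta
  r <- rep(NA_real_, n_theta)
  agg <- tapply(rr, bin, max)
  r[as.integer(names(agg))] <- agg + 0.5   # half-pixel boundary correction
  # fill empty bins by circular linear interpolation
  if (anyNA(r)) {
    idx <- which(!is.na(r))
    if (!length(idx)) return(NULL)
    full <- stats::approx(x = c(idx, idx[1] + n_theta),
                          y = c(r[idx], r[idx[1]]),
                          xout = seq_len(n_theta) +
                            ifelse(seq_len(n_theta) < idx[1], n_theta, 0),
                          rule = 2)$y
    r <- full
  }
  # low-pass the profile by truncated Fourier series: analytic derivatives
  # suppress pixelation noise that finite differences would amplify
  n_harm <- min(10L, floor(n_theta / 4))
  ft <- stats::fft(r)
  theta <- (seq_len(n_theta) - 1) / n_theta * 2 * pi - pi
  a0 <- Re(ft[1]) / n_theta
  kk <- seq_len(n_harm)
  ak <- 2 * Re(ft[kk + 1]) / n_theta
  bk <- -2 * Im(ft[kk + 1]) / n_theta
  # fft is over index position; theta is an affine shift of it, harmless for
  # closed-curve geometry
  pos <- (seq_len(n_theta) - 1) / n_theta * 2 * pi
  cosm <- cos(outer(pos, kk))
  sinm <- sin(outer(pos, kk))
  r_s <- a0 + cosm %*% ak + sinm %*% bk
  rp <- (-sinm) %*% (kk * ak) + cosm %*% (kk * bk)
  rpp <- -(cosm %*% (kk^2 * ak) + sinm %*% (kk^2 * bk))
  list(r = as.numeric(r_s), rp = as.numeric(rp), rpp = as.numeric(rpp),
       theta = theta, centroid = c(cy, cx))
}

polar_curvature <- function(prof) {
  r <- prof$r; rp <- prof$rp; rpp <- prof$rpp
  (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
}

glcm_stats <- function(patch, mask, n_levels = 16) {
  v <- patch[mask == 1]
  rngv <- range(v)
  if (diff(rngv) <= 0) {
    lev <- matrix(1L, nrow(patch), ncol(patch))
  } else {
    lev <- matrix(findInterval(patch, seq(rngv[1], rngv[2],
                                          length.out = n_levels + 1),
                               all.inside = TRUE),
                  nrow(patch), ncol(patch))
  }
  lev[mask == 0] <- NA
  H <- nrow(lev); W <- ncol(lev)
  pairs <- rbind(
    cbind(as.vector(lev[-H, ]), as.vector(lev[-1, ])),   # vertical offset 1
    cbind(as.vector(lev[, -W]), as.vector(lev[, -1]))    # horizontal offset 1
  )
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(c(tex_contrast = 0, tex_homogeneity = 1, tex_energy = 1,
             tex_entropy = 0, tex_correlation = 0))
  }
  pairs <- rbind(pairs, pairs[, 2:1])                     # symmetric
  P <- table(factor(pairs[, 1], levels = 1:n_levels),
             factor(pairs[, 2], levels = 1:n_levels))
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 0
  c(tex_contrast = sum(P * (i - j)^2),
    tex_homogeneity = sum(P / (1 + (i - j)^2)),
    tex_energy = sum(P^2),
    tex_entropy = -sum(P[P > 0] * log(P[P > 0])),
    tex_correlation = corr)
}

#' Compute nuclear morphometry and chromatin features for one nucleus
#'
#' @param patch intensity matrix (masked: 0 outside the nucleus).
#' @param mask binary matrix, same shape, nonempty.
#' @return named numeric vector of ~45 features. Family is encoded in the
#'   name prefix: `size_`, `radius_`, `shape_`, `curv_`, `mom_`, `tex_`,
#'   `int_`, `chrom_`.
#' @export
#' @examples
#' disk <- outer(-25:25, -25:25, function(y, x) (y^2 + x^2 <= 20^2) * 1L)
#' f <- compute_features(disk * 0.5, disk)
#' f["size_area"] / (pi * 400)   # ~1
compute_features <- function(patch, mask) {
  if (sum(mask) == 0) stop_config("compute_features: empty mask")
  px <- which(mask == 1, arr.ind = TRUE)
  area <- nrow(px)
  prof <- radius_profile(mask)
  dtheta <- 2 * pi / length(prof$r)
  r <- prof$r
  # arc length of the smoothed polar boundary
  per <- sum(sqrt(r^2 + prof$rp^2)) * dtheta
  kappa <- polar_curvature(prof)
  # second moments -> orientation-free shape
  cy <- prof$centroid[1]; cx <- prof$centroid[2]
  dy <- px[, 1] - cy; dx <- px[, 2] - cx
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 1e-12)
  aspect <- sqrt(ev[1] / ev[2])
  ecc <- sqrt(1 - ev[2] / ev[1])
  # central moments (pixel-count normalization) and scale invariants
  m <- function(p, q) sum(dx^p * dy^q)
  eta <- function(p, q) m(p, q) / area^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  hu1 <- e20 + e02
  hu2 <- (e20 - e02)^2 + 4 * e11^2
  hu3 <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  hu4 <- (e30 + e12)^2 + (e21 + e03)^2
  # convex hull via grDevices::chull on boundary points
  hull <- grDevices::chull(px[, 2], px[, 1])
  hx <- px[hull, 2]; hy <- px[hull, 1]
  convex_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  convex_area <- max(convex_area, area)    # discrete hulls can undercount
  bbox_area <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)
  v <- patch[mask == 1]
  int_sd <- sd(v)
  skew <- if (int_sd > 0) mean((v - mean(v))^3) / int_sd^3 else 0
  # heterochromatin: high-intensity compartment by within-nucleus Otsu
  if (diff(range(v)) > 0) {
    thr <- otsu_threshold(v)
    het <- v > thr
    het_frac <- mean(het)
    het_ratio <- if (any(het) && any(!het) && mean(v[!het]) > 0)
      mean(v[het]) / mean(v[!het]) else 1
  } else {
    het_frac <- 0; het_ratio <- 1
  }
  c(
    size_area = area,
    size_perimeter = per,
    size_equiv_diameter = 2 * sqrt(area / pi),
    size_convex_area = convex_area,
    radius_mean = mean(r),
    radius_sd = sd(r),
    radius_min = min(r),
    radius_max = max(r),
    radius_cv = sd(r) / mean(r),
    shape_factor = per^2 / (4 * pi * area),
    shape_aspect_ratio = aspect,
    shape_eccentricity = ecc,
    shape_extent = area / bbox_area,
    shape_solidity = area / convex_area,
    curv_mean = mean(kappa),
    curv_sd = sd(kappa),
    curv_max = max(kappa),
    curv_frac_positive = mean(kappa > 0),
    mom_mu20 = mu20, mom_mu02 = mu02, mom_mu11 = mu11,
    mom_eta20 = e20, mom_eta02 = e02, mom_eta11 = e11,
    mom_eta30 = e30, mom_eta03 = e03, mom_eta21 = e21, mom_eta12 = e12,
    mom_hu1 = hu1, mom_hu2 = hu2, mom_hu3 = hu3, mom_hu4 = hu4,
    glcm_stats(patch, mask),
    int_mean = mean(v),
    int_sd = int_sd,
    int_cv = if (mean(v) > 0) int_sd / mean(v) else 0,
    int_skew = skew,
    int_median = stats::median(v),
    int_iqr = stats::IQR(v),
    chrom_hetero_fraction = het_frac,
    chrom_hetero_euchro_ratio = het_ratio
  )
}

#' Feature table for a set of nuclei
#'
#' @param nuclei `chs_nuclei` list (from [extract_patches()]) or a list of
#'   `list(patch=, mask=)` records.
#' @return numeric matrix cells x features of class `chs_feature_table`,
#'   with a `families` attribute mapping names to families.
#' @export
feature_table <- function(nuclei) {
  rows <- lapply(nuclei, function(r) compute_features(r$patch, r$mask))
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(seq_along(nuclei), function(i)
    as.character(nuclei[[i]]$nucleus_id %||% i), character(1))
  attr(X, "families") <- sub("_.*$", "", colnames(X))
  class(X) <- c("chs_feature_table", class(X))
  X
}

#' Per-feature, per-cluster discriminative testing
#'
#' Each feature is z-score normalized; for every (feature, cluster) pair a
#' Welch two-sample t-test compares cells in the cluster against all other
#' cells on the z-scored values. p-values are Benjamini-Hochberg corrected
#' jointly across all feature x cluster tests. Fold changes are computed on
#' the raw (pre-z-score) scale for strictly positive features; features that
#' are not strictly positive get a difference-of-means effect flagged
#' `fc_type = "diff"`.
#'
#' @param table `chs_feature_table` (cells x features).
#' @param labels integer cluster labels (0-based), aligned with rows.
#' @return data.frame of class `chs_feature_stats`: `feature`, `cluster`,
#'   `p`, `p_adj`, `fold_change`, `fc_type`, `mean_z`, `global_mean`.
#' @export
test_cluster_features <- function(table, labels) {
  X <- as.matrix(table)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop_config("need >= 2 clusters")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance feature(s): %s",
                    sum(sds == 0),
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  res <- list()
  for (f in colnames(X)) {
    pos <- all(X[, f] > 0)
    for (cl in clusters) {
      inz <- Z[labels == cl, f]
      outz <- Z[labels != cl, f]
      if (length(inz) < 2 || length(outz) < 2) next
      p <- tryCatch(t.test(inz, outz, var.equal = FALSE)$p.value,
                    error = function(e) NA_real_)
      fc <- if (pos) mean(X[labels == cl, f]) / mean(X[labels != cl, f])
      else mean(X[labels == cl, f]) - mean(X[labels != cl, f])
      res[[length(res) + 1]] <- data.frame(
        feature = f, cluster = cl, p = p,
        fold_change = fc, fc_type = if (pos) "ratio" else "diff",
        mean_z = mean(inz), global_mean = mean(X[, f]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  class(out) <- c("chs_feature_stats", class(out))
  out
}

#' Select significantly altered features
#'
#' A feature is selected if in at least one cluster it passes all three
#' gates: BH-adjusted p below `fdr`, fold change above `fc_high` or below
#' `fc_low` (for difference-type features the effect gate is
#' `|mean_z| > z_min`, since a ratio is undefined), and the magnitude gate.
#' The magnitude gate has two documented readings: `"cluster_z"` (default)
#' requires `|mean z within cluster| > z_min`; `"global_mean"` requires the
#' raw feature mean across all cells to exceed `z_min`.
#'
#' @param stats `chs_feature_stats`.
#' @param fdr adjusted-p threshold (default 0.01).
#' @param fc_low,fc_high fold-change gates (defaults 0.8 and 1.2).
#' @param z_min magnitude threshold (default 0.5).
#' @param z_rule `"cluster_z"` or `"global_mean"`.
#' @return character vector of selected feature names; the per-test flags
#'   are attached as attribute `flags`.
#' @export
select_significant <- function(stats, fdr = 0.01, fc_low = 0.8, fc_high = 1.2,
                               z_min = 0.5, z_rule = c("cluster_z", "global_mean")) {
  z_rule <- match.arg(z_rule)
  fc_gate <- ifelse(stats$fc_type == "ratio",
                    stats$fold_change > fc_high | stats$fold_change < fc_low,
                    abs(stats$mean_z) > z_min)
  mag_gate <- if (z_rule == "cluster_z") abs(stats$mean_z) > z_min
  else stats$global_mean > z_min
  sel <- !is.na(stats$p_adj) & stats$p_adj < fdr & fc_gate & mag_gate
  features <- sort(unique(stats$feature[sel]))
  attr(features, "flags") <- cbind(stats[, c("feature", "cluster")],
                                   selected = sel)
  features
}

#' Group correlated features
#'
#' Builds a graph over the selected features with edges where the pairwise
#' Pearson correlation exceeds `corr_threshold`; connected components of
#' size >= 2 become numbered groups ordered by decreasing size (ties broken
#' by first feature name); singleton features are collected into a remainder
#' group whose id is one past the last numbered group.
#'
#' @param selected character vector of feature names.
#' @param table `chs_feature_table`.
#' @param corr_threshold edge threshold (default 0.8, strict inequality).
#' @return data.frame `feature`, `group` with attribute `remainder_id`.
#' @export
group_features <- function(selected, table, corr_threshold = 0.8) {
  if (length(selected) < 1) stop_config("no selected features")
  X <- as.matrix(table)[, selected, drop = FALSE]
  cm <- stats::cor(X)
  adj <- abs(cm) * 0
  adj[cm > corr_threshold] <- 1
  diag(adj) <- 0
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  sizes <- comp$csize
  big <- which(sizes >= 2)
  first_feature <- vapply(big, function(ci)
    min(selected[comp$membership == ci]), character(1))
  big <- big[order(-sizes[big], first_feature)]
  group <- integer(length(selected))
  for (g in seq_along(big)) group[comp$membership == big[g]] <- g
  remainder_id <- length(big) + 1L
  group[group == 0] <- remainder_id
  out <- data.frame(feature = selected, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "remainder_id") <- remainder_id
  out
}
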