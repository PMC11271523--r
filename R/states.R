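#' Balanced downsampling across phenotypic categories
#'
#' Selects the same number of cells from every category (sampling without
#' replacement, seeded) so that clustering is not dominated by the cells of
#' one stage.
#'
#' @param categories character vector, one category per cell.
#' @param per_category_n cells to keep from each category.
#' @param seed RNG seed.
#' @return integer vector of selected cell indices (ascending).
#' @export
balanced_downsample <- function(categories, per_category_n, seed = 1L) {
  counts <- table(categories)
  too_small <- names(counts)[counts < per_category_n]
  if (length(too_small))
    stop_config("category %s has fewer than %d cells",
                paste(too_small, collapse = ", "), per_category_n)
  with_seed(seed, {
    sel <- unlist(lapply(names(counts), function(cat) {
      sample(which(categories == cat), per_category_n)
    }))
    sort(sel)
  })
}

#' Fit the top-level cell-state clustering
#'
#' PCA to the top `n_components` principal components of the latent features
#' followed by k-means with `k` clusters (multiple restarts, best inertia
#' kept). Cluster ids 0..k-1 are relabeled into a canonical order: ascending
#' mean of `order_by` (typically nucleus area) so that state 0 is the
#' smallest/healthiest-like and state k-1 the largest/malignant-like; when
#' `order_by` is absent, ascending cluster mean along PC1.
#'
#' @param latents numeric matrix, cells x latent dims.
#' @param k number of clusters (default 8).
#' @param n_components PCA components (default 50, capped at input dim).
#' @param order_by optional per-cell numeric used to order cluster labels.
#' @param nstart k-means restarts (default 3).
#' @param seed RNG seed.
#' @return object of class `chs_states`: PCA basis, centroids (in PCA
#'   space), `labels` (0-based, training cells), `inertia`.
#' @export
fit_topclusters <- function(latents, k = 8, n_components = 50,
                            order_by = NULL, nstart = 3, seed = 1L) {
  latents <- as.matrix(latents)
  if (k > nrow(latents)) stop_config("k = %d exceeds number of cells", k)
  n_components <- min(n_components, ncol(latents), nrow(latents) - 1)
  with_seed(seed, {
    pca <- prcomp(latents, center = TRUE, scale. = FALSE, rank. = n_components)
    scores <- pca$x
    km <- kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
    raw <- km$cluster                     # 1..k
    key <- if (!is.null(order_by)) {
      tapply(order_by, raw, mean)
    } else {
      tapply(scores[, 1], raw, mean)
    }
    ord <- order(key)                     # ord[j] = raw id of canonical j-1
    remap <- integer(k)
    remap[ord] <- 0:(k - 1)
    labels <- remap[raw]
    centers <- km$centers[ord, , drop = FALSE]
    rownames(centers) <- 0:(k - 1)
    structure(list(center = pca$center, rotation = pca$rotation,
                   centroids = centers, k = k, labels = labels,
                   inertia = km$tot.withinss, seed = seed,
                   subclusters = vector("list", k)),
              class = "chs_states")
  })
}

project_pca <- function(model, latents) {
  sweep(as.matrix(latents), 2, model$center) %*% model$rotation
}

#' Assign cells to fitted cell states
#'
#' Nearest-centroid assignment in the fitted PCA space; deterministic. Cells
#' are also assigned to subclusters where subcluster models exist.
#'
#' @param model a fitted `chs_states`.
#' @param latents latent matrix (any cells, including held-out).
#' @return data.frame with `cluster` (0-based) and `subcluster` (0-based,
#'   NA where no subcluster model is fitted).
#' @export
assign_states <- function(model, latents) {
  stopifnot(inherits(model, "chs_states"))
  if (ncol(latents) != length(model$center))
    stop_config("latent dimension mismatch")
  sc <- project_pca(model, latents)
  d2 <- outer(rowSums(sc^2), rowSums(model$centroids^2), "+") -
    2 * sc %*% t(model$centroids)
  cl <- max.col(-d2, ties.method = "first") - 1L
  sub <- rep(NA_integer_, length(cl))
  for (j in seq_len(model$k)) {
    sm <- model$subclusters[[j]]
    if (is.null(sm)) next
    in_j <- which(cl == j - 1L)
    if (!length(in_j)) next
    scj <- sc[in_j, , drop = FALSE]
    d2j <- outer(rowSums(scj^2), rowSums(sm$centroids^2), "+") -
      2 * scj %*% t(sm$centroids)
    sub[in_j] <- max.col(-d2j, ties.method = "first") - 1L
  }
  data.frame(cluster = cl, subcluster = sub)
}

#' Inertia-guided subclustering of one top-level cluster
#'
#' Computes the k-means inertia curve over `candidate_ks`, picks the initial
#' subcluster count at the sharpest relative inertia decrease, then
#' decrements the count while any two sibling subclusters are "identical" -
#' operationalized as total-variation distance below `tau` between their
#' phenotypic-category composition vectors.
#'
#' @param model fitted `chs_states`.
#' @param latents latent matrix of the training cells (same cells used in
#'   [fit_topclusters()]).
#' @param cluster_id top-level cluster 0..k-1.
#' @param categories per-cell category codes, aligned with `latents`.
#' @param candidate_ks candidate subcluster counts (default 2:6).
#' @param tau total-variation threshold below which two siblings are deemed
#'   identical (default 0.1).
#' @param seed RNG seed.
#' @return the updated `chs_states` with the subcluster model installed; the
#'   decision trace is in `model$subclusters[[id+1]]$trace`.
#' @export
fit_subclusters <- function(model, latents, cluster_id, categories,
                            candidate_ks = 2:6, tau = 0.1, seed = 1L) {
  stopifnot(inherits(model, "chs_states"))
  sc <- project_pca(model, latents)
  in_cl <- which(model$labels == cluster_id)
  if (!length(in_cl)) stop_config("cluster %d is empty", cluster_id)
  if (max(candidate_ks) > length(in_cl))
    stop_config("cluster %d smaller than max candidate k", cluster_id)
  scj <- sc[in_cl, , drop = FALSE]
  catj <- categories[in_cl]
  with_seed(seed, {
    ks <- sort(unique(c(1L, candidate_ks)))
    inertia <- vapply(ks, function(kk) {
      if (kk == 1) sum(scale(scj, scale = FALSE)^2)
      else kmeans(scj, centers = kk, nstart = 3, iter.max = 100)$tot.withinss
    }, numeric(1))
    rel_drop <- c(NA, -diff(inertia) / head(inertia, -1))
    k0 <- ks[which.max(rel_drop[-1]) + 1]
    tv_identical <- function(kk) {
      if (kk < 2) return(FALSE)
      km <- kmeans(scj, centers = kk, nstart = 3, iter.max = 100)
      comp <- prop.table(table(factor(km$cluster, levels = 1:kk),
                               factor(catj)), margin = 1)
      for (i in seq_len(kk - 1)) for (j in (i + 1):kk) {
        if (0.5 * sum(abs(comp[i, ] - comp[j, ])) < tau) return(TRUE)
      }
      FALSE
    }
    kk <- k0
    trace <- data.frame(k = ks, inertia = inertia, rel_drop = rel_drop)
    while (kk >= 2 && tv_identical(kk)) kk <- kk - 1
    final <- if (kk >= 2) kmeans(scj, centers = kk, nstart = 3, iter.max = 100)
    else list(cluster = rep(1L, length(in_cl)),
              centers = matrix(colMeans(scj), 1))
    model$subclusters[[cluster_id + 1]] <- list(
      n_sub = kk, centroids = final$centers,
      labels = final$cluster - 1L, cells = in_cl,
      trace = trace, k_initial = k0, tau = tau)
    model
  })
}

#' Cluster composition by category or sample
#'
#' Cross-tabulates cells by grouping variable x cluster and normalizes along
#' the requested axis. The display convention is that of a
#' category-by-cluster heatmap whose columns (clusters) each sum to 1.
#'
#' @param labels integer cluster labels (0-based).
#' @param groups character vector (category or sample id per cell).
#' @param normalize one of `"cluster"` (each cluster column sums to 1),
#'   `"group"` (each group row sums to 1), or `"none"`.
#' @return matrix groups x clusters with attribute `normalize`.
#' @export
composition <- function(labels, groups, normalize = c("cluster", "group", "none")) {
  normalize <- match.arg(normalize)
  if (length(labels) != length(groups))
    stop_config("labels and groups must be aligned")
  tab <- table(factor(groups), factor(labels, levels = sort(unique(labels))))
  m <- unclass(as.matrix(tab))
  out <- switch(normalize,
                cluster = sweep(m, 2, pmax(colSums(m), 1), "/"),
                group = sweep(m, 1, pmax(rowSums(m), 1), "/"),
                none = m)
  attr(out, "normalize") <- normalize
  out
}

#' Centroid-distance state ordering (toy pseudo-ordering utility)
#'
#' Orders clusters by latent-centroid distance from a chosen root cluster.
#' This is a deliberately simple stand-in for graph-based trajectory tools
#' (the latent table and labels can be exported for those); it is not PAGA
#' or diffusion pseudotime.
#'
#' @param model fitted `chs_states`.
#' @param root cluster id used as origin (default 0).
#' @return data.frame of cluster ids and centroid distances, ordered.
#' @export
centroid_ordering <- function(model, root = 0) {
  d <- sqrt(rowSums(sweep(model$centroids, 2,
                          model$centroids[as.character(root), ])^2))
  data.frame(cluster = as.integer(rownames(model$centroids)),
             distance = d)[order(d), ]
}
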