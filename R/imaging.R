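#' Percentile range normalization of an intensity image
#'
#' Rescales an image using its low and high intensity percentiles so that the
#' low percentile maps to 0 and the high percentile maps to 1:
#' `(I - P_low) / (P_high - P_low)`. Values outside `[0, 1]` are retained
#' (no clipping) unless `clip = TRUE`, which is provided for display only.
#' Percentiles use the linear-interpolation definition (`quantile` type 7).
#'
#' @param image numeric matrix.
#' @param params list with `low_percentile` (default 1) and `high_percentile`
#'   (default 99.8), in percent.
#' @param clip clip the result into `[0, 1]`? Default `FALSE`.
#' @return normalized numeric matrix.
#' @export
#' @examples
#' img <- matrix(runif(100, 10, 110), 10)
#' rn <- range_normalize(img)
range_normalize <- function(image, params = normalization_params(), clip = FALSE) {
  stopifnot(is.numeric(image))
  lo <- quantile(image, params$low_percentile / 100, names = FALSE)
  hi <- quantile(image, params$high_percentile / 100, names = FALSE)
  if (hi <= lo) {
    stop_config("range_normalize: degenerate image (P%.1f == P%.1f)",
                params$low_percentile, params$high_percentile)
  }
  out <- (image - lo) / (hi - lo)
  if (clip) out <- clamp01(out)
  out
}

#' Normalization parameters
#'
#' @param low_percentile lower percentile (percent), default 1.
#' @param high_percentile upper percentile (percent), default 99.8.
#' @return list of class `chs_norm_params`.
#' @export
normalization_params <- function(low_percentile = 1, high_percentile = 99.8) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100)) {
    stop_config("normalization percentiles must satisfy 0 <= low < high <= 100")
  }
  structure(list(low_percentile = low_percentile,
                 high_percentile = high_percentile),
            class = "chs_norm_params")
}

#' Intensity-augmentation parameters
#'
#' Gain/offset and additive-noise ranges used to augment normalized images
#' during segmentation-model training. Defaults: gain `a ~ Unif(0.6, 2)`,
#' offset `b ~ Unif(-0.2, 0.2)`, noise scale 0.02.
#'
#' @param gain_range length-2 numeric, lower bound must be positive.
#' @param offset_range length-2 numeric.
#' @param noise_scale scalar multiplier for the additive Gaussian noise.
#' @return list of class `chs_aug_params`.
#' @export
augmentation_params <- function(gain_range = c(0.6, 2),
                                offset_range = c(-0.2, 0.2),
                                noise_scale = 0.02) {
  if (gain_range[1] <= 0) stop_config("gain_range lower bound must be > 0")
  structure(list(gain_range = gain_range, offset_range = offset_range,
                 noise_scale = noise_scale),
            class = "chs_aug_params")
}

#' Random gain/offset intensity augmentation
#'
#' Applies `I * a + b` with `a` and `b` each drawn once per image, uniformly
#' from the configured ranges.
#'
#' @param image normalized numeric matrix.
#' @param params [augmentation_params()].
#' @param a,b optional forced values (used in tests); when `NULL` they are
#'   drawn from the session RNG.
#' @return augmented image.
#' @export
augment_intensity <- function(image, params = augmentation_params(),
                              a = NULL, b = NULL) {
  a <- a %||% runif(1, params$gain_range[1], params$gain_range[2])
  b <- b %||% runif(1, params$offset_range[1], params$offset_range[2])
  image * a + b
}

#' Additive-noise augmentation
#'
#' Applies `I + scale * c * sigma` where `c ~ Unif(0, 1)` is drawn once per
#' image and `sigma ~ Normal(0, 1)` per pixel.
#'
#' @param image normalized numeric matrix.
#' @param params [augmentation_params()].
#' @param c_val optional forced value of `c`.
#' @return augmented image.
#' @export
augment_noise <- function(image, params = augmentation_params(), c_val = NULL) {
  c_val <- c_val %||% runif(1)
  image + params$noise_scale * c_val * matrix(rnorm(length(image)),
                                              nrow(image), ncol(image))
}

#' Separable Gaussian blur
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix, same size. Borders use renormalized truncated
#'   kernels (no padding bias).
#' @export
gaussian_blur <- function(image, sigma = 1) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  band <- function(n) {
    m <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) m[cbind(idx, idx + d)] <- k[d + r + 1]
      else m[cbind(idx - d, idx)] <- k[d + r + 1]
    }
    m / rowSums(m)
  }
  Kr <- band(nrow(image))
  Kc <- band(ncol(image))
  Kr %*% image %*% t(Kc)
}

#' Otsu threshold
#'
#' Maximizes between-class variance over a histogram of the image.
#'
#' @param image numeric matrix or vector.
#' @param n_bins histogram bins (default 256).
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  rng <- range(x)
  if (diff(rng) <= 0) stop_config("otsu_threshold: constant image")
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, brk, all.inside = TRUE), nbins = n_bins)
  w <- cumsum(h)
  mids <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  mu <- cumsum(h * mids)
  n <- length(x)
  w1 <- w
  w2 <- n - w
  valid <- w1 > 0 & w2 > 0
  m1 <- mu / w1
  m2 <- (mu[n_bins] - mu) / w2
  bcv <- ifelse(valid, w1 * w2 * (m1 - m2)^2, -Inf)
  # average over the argmax plateau (flat between well-separated modes)
  mean(mids[bcv >= max(bcv) - 1e-12 * abs(max(bcv))])
}

#' Segment duct regions from a cytokeratin image
#'
#' Gaussian blur (sigma = 1) then Otsu thresholding of the cytokeratin-like
#' channel, followed by 8-connected component labeling; components smaller
#' than `min_area` pixels are removed and labels compacted to 1..k.
#'
#' @param cytokeratin_image numeric matrix with nonzero dynamic range.
#' @param sigma blur standard deviation (default 1).
#' @param min_area minimum component area in pixels (default 64).
#' @param min_contrast minimum foreground/background mean separation for any
#'   duct to be called; below it an empty mask is returned (default 0.1).
#' @return object of class `chs_duct_mask`: list with `labels` (integer
#'   matrix, 0 = background), `n_components`, `threshold`.
#' @export
segment_ducts <- function(cytokeratin_image, sigma = 1, min_area = 64,
                          min_contrast = 0.1) {
  if (diff(range(cytokeratin_image)) <= 0)
    stop_config("segment_ducts: constant image")
  sm <- gaussian_blur(cytokeratin_image, sigma)
  thr <- otsu_threshold(sm)
  if (mean(sm[sm > thr]) - mean(sm[sm <= thr]) < min_contrast) {
    return(structure(list(labels = matrix(0L, nrow(sm), ncol(sm)),
                          n_components = 0L, threshold = thr),
                     class = "chs_duct_mask"))
  }
  fg <- matrix(as.integer(sm > thr), nrow(sm), ncol(sm))
  lab <- cpp_label(fg, 8L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  structure(list(labels = lab, n_components = max(lab), threshold = thr),
            class = "chs_duct_mask")
}

#' Stand-in nucleus segmentation
#'
#' A classical watershed pipeline standing in for a learned star-convex
#' segmentation model: Gaussian smoothing, Otsu foreground, Euclidean
#' distance transform, seeded watershed from smoothed-distance maxima, and
#' small-hole removal. Externally produced label masks can be used anywhere
#' a label image is accepted (see [extract_patches()]).
#'
#' @param chromatin_image normalized numeric matrix.
#' @param sigma smoothing sigma before thresholding (default 1).
#' @param min_area discard segments smaller than this (default 30 px).
#' @param seed_sigma smoothing of the distance map before maxima detection.
#' @param min_seed_dist minimum distance-map value for a seed (suppresses
#'   boundary seeds; default 2).
#' @param threshold_factor nucleus extent is taken at this fraction of the
#'   Otsu threshold (default 0.6); the full Otsu value clips dim chromatin
#'   texture inside heterogeneous nuclei, biasing areas state-dependently.
#' @param min_contrast minimum separation between foreground and background
#'   mean intensity for the image to count as containing nuclei; below it a
#'   zero label image is returned (default 0.1).
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(chromatin_image, sigma = 1, min_area = 30,
                           seed_sigma = 2, min_seed_dist = 2,
                           threshold_factor = 0.6, min_contrast = 0.1) {
  sm <- gaussian_blur(chromatin_image, sigma)
  if (diff(range(sm)) <= 0) stop_config("segment_nuclei: constant image")
  thr <- otsu_threshold(sm)
  if (mean(sm[sm > thr]) - mean(sm[sm <= thr]) < min_contrast)
    return(matrix(0L, nrow(sm), ncol(sm)))
  fg <- matrix(as.integer(sm > threshold_factor * thr), nrow(sm), ncol(sm))
  # drop weak components that contain no pixel above the full Otsu value
  comp <- cpp_label(fg, 8L)
  if (max(comp) > 0) {
    strong <- unique(comp[sm > thr & comp > 0])
    fg[!(comp %in% strong)] <- 0L
  }
  fg <- fill_holes(fg)
  if (sum(fg) == 0) return(matrix(0L, nrow(fg), ncol(fg)))
  d <- cpp_edt(fg)
  ds <- gaussian_blur(d, seed_sigma)
  seeds <- local_maxima(ds, min_value = min_seed_dist) & fg == 1
  if (!any(seeds)) seeds <- ds == max(ds) & fg == 1
  markers <- cpp_label(matrix(as.integer(seeds), nrow(fg), ncol(fg)), 8L)
  lab <- cpp_watershed(-d, markers, fg)
  # drop small segments, compact labels
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

# Fill background holes not connected to the image border (4-connectivity).
fill_holes <- function(mask) {
  bg <- matrix(as.integer(mask == 0), nrow(mask), ncol(mask))
  lab <- cpp_label(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- lab > 0 & !(lab %in% border)
  out <- mask
  out[hole] <- 1L
  out
}

# 3x3 local maxima above a floor value.
local_maxima <- function(x, min_value = 0) {
  H <- nrow(x); W <- ncol(x)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- x
  res <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & x >= pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  }
  res & x >= min_value
}

#' Extract masked, centered patches for each segmented nucleus
#'
#' For every label in the segmentation, crops a `patch_size` x `patch_size`
#' window centered at the nucleus centroid (zero-padded at image borders) and
#' zeroes all pixels outside that nucleus's mask. A nucleus whose mask
#' extends beyond the window is truncated and flagged.
#'
#' @param image intensity matrix.
#' @param labels integer label matrix, same shape.
#' @param duct_mask optional [segment_ducts()] result (or 0/1 matrix) used to
#'   set `inside_duct` from centroid membership.
#' @param patch_size side of the square patch (default 96).
#' @return list of class `chs_nuclei`: per-nucleus records with fields
#'   `nucleus_id`, `centroid` (row, col; 0-based), `patch`
#'   (patch_size x patch_size), `mask` (same size binary), `area`,
#'   `inside_duct`, `truncated`.
#' @export
extract_patches <- function(image, labels, duct_mask = NULL, patch_size = 96) {
  stopifnot(all(dim(image) == dim(labels)))
  dm <- NULL
  if (!is.null(duct_mask)) {
    dm <- if (inherits(duct_mask, "chs_duct_mask")) duct_mask$labels else duct_mask
    stopifnot(all(dim(dm) == dim(image)))
  }
  n <- max(labels)
  half <- patch_size %/% 2
  out <- vector("list", n)
  idx_all <- which(labels > 0, arr.ind = TRUE)
  lab_vals <- labels[labels > 0]
  H <- nrow(image); W <- ncol(image)
  for (k in seq_len(n)) {
    px <- idx_all[lab_vals == k, , drop = FALSE]
    if (nrow(px) == 0) next
    # 0-based centroid, rounded to the pixel grid
    cy <- round(mean(px[, 1]) - 1)
    cx <- round(mean(px[, 2]) - 1)
    patch <- matrix(0, patch_size, patch_size)
    pm <- matrix(0L, patch_size, patch_size)
    y0 <- cy - half; x0 <- cx - half           # 0-based origin of window
    ys <- max(0, y0):min(H - 1, y0 + patch_size - 1)
    xs <- max(0, x0):min(W - 1, x0 + patch_size - 1)
    sub_lab <- labels[ys + 1, xs + 1, drop = FALSE]
    sub_img <- image[ys + 1, xs + 1, drop = FALSE]
    sel <- sub_lab == k
    pr <- (ys[1] - y0) + row(sub_lab)[sel]   # 1-based rows in the patch
    pc <- (xs[1] - x0) + col(sub_lab)[sel]
    patch[cbind(pr, pc)] <- sub_img[sel]
    pm[cbind(pr, pc)] <- 1L
    truncated <- sum(sel) < nrow(px)
    inside <- FALSE
    if (!is.null(dm)) inside <- dm[cy + 1, cx + 1] > 0
    out[[k]] <- list(nucleus_id = k, centroid = c(cy, cx), patch = patch,
                     mask = pm, area = sum(pm), inside_duct = inside,
                     truncated = truncated)
  }
  structure(out[!vapply(out, is.null, logical(1))], class = "chs_nuclei")
}
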