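#' Convolutional VAE configuration
#'
#' The encoder is a stack of strided convolutions (kernel 4, stride 2,
#' padding 1; each halves the spatial size, 96 -> 3 over five layers)
#' followed by two parallel fully connected heads computing the posterior
#' mean and log-variance ("dispersion") of a diagonal Gaussian. The decoder
#' mirrors the encoder with transposed convolutions. All hidden layers use a
#' leaky rectifier. The full-scale reference configuration
#' ([vae_config_paper_scale()]) keeps the published training scale (latent
#' width 6000, batch 8000, 310 epochs); the desk-scale defaults here are the
#' test surface of this package.
#'
#' @param n_conv_layers encoder depth (default 5).
#' @param latent_dim width of the latent space (desk default 16; the published
#'   model used 6000).
#' @param channels per-layer output channels, length `n_conv_layers`.
#' @param input_size input patch side (default 96).
#' @param leaky_slope negative-slope of the leaky rectifier (default 0.01).
#' @param batch_size minibatch size (desk default 128).
#' @param epochs training epochs (desk default 45; the published run used 310).
#' @param kl_weight weight of the KL term (default 1).
#' @param lr adaptive-moment (Adam) learning rate (default 1e-3); decayed by
#'   3x at 60% and again at 85% of the epoch budget.
#' @param weight_decay L2 penalty on weight matrices (default 1e-4); limits
#'   patch memorization at desk-scale cell counts.
#' @param ema_decay per-step exponential-moving-average factor for Polyak
#'   weight averaging (default 0.98); the averaged weights are what the
#'   validation selection and the final model use. `NULL` disables.
#' @param split_fractions train/validation/test fractions, must sum to 1
#'   (default 0.85/0.05/0.10).
#' @param augment_flips randomly flip training patches horizontally /
#'   vertically (probability 0.5 each, per image per epoch)? Default `TRUE`;
#'   regularizes training at desk-scale cell counts.
#' @param augment_shift_px random integer translation of training patches,
#'   uniform in `[-shift, shift]` per axis (default 3; 0 disables). Together
#'   with flips this prevents the decoder from memorizing individual cells,
#'   which otherwise fills the latent space with per-cell identity noise.
#' @param seed RNG seed for initialization, splits and sampling.
#' @return object of class `chs_vae_config`.
#' @export
vae_config <- function(n_conv_layers = 5, latent_dim = 16,
                       channels = c(4, 8, 16, 16, 32),
                       input_size = 96, leaky_slope = 0.01,
                       batch_size = 64, epochs = 60, kl_weight = 1,
                       lr = 3e-3, weight_decay = 1e-4, ema_decay = 0.98,
                       split_fractions = c(0.85, 0.05, 0.10),
                       augment_flips = TRUE, augment_shift_px = 3, seed = 1L) {
  if (latent_dim < 2) stop_config("latent_dim must be >= 2")
  if (length(channels) != n_conv_layers)
    stop_config("channels must have length n_conv_layers")
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop_config("split_fractions must sum to 1")
  if (input_size %% 2^n_conv_layers != 0)
    stop_config("input size %d not divisible by 2^%d", input_size, n_conv_layers)
  structure(list(
    n_conv_layers = n_conv_layers, latent_dim = latent_dim,
    channels = channels, input_size = input_size, leaky_slope = leaky_slope,
    batch_size = batch_size, epochs = epochs, kl_weight = kl_weight,
    lr = lr, weight_decay = weight_decay, ema_decay = ema_decay,
    split_fractions = split_fractions,
    augment_flips = augment_flips,
    augment_shift_px = as.integer(augment_shift_px), seed = as.integer(seed)
  ), class = "chs_vae_config")
}

#' @rdname vae_config
#' @export
vae_config_paper_scale <- function() {
  vae_config(latent_dim = 6000, channels = c(32, 64, 128, 256, 512),
             batch_size = 8000, epochs = 310)
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build an untrained convolutional VAE
#'
#' @param config a [vae_config()].
#' @return object of class `chs_vae`: parameter list plus layer geometry.
#' @export
build_vae <- function(config) {
  stopifnot(inherits(config, "chs_vae_config"))
  with_seed(config$seed, {
    L <- config$n_conv_layers
    cin <- c(1, config$channels[-L])
    cout <- config$channels
    sizes <- config$input_size / 2^(0:L)
    conv <- lapply(seq_len(L), function(l) {
      list(W = he_init(cout[l], 16 * cin[l], 16 * cin[l]),
           b = numeric(cout[l]))
    })
    flat <- cout[L] * sizes[L + 1]^2
    fc_mu <- list(W = he_init(flat, config$latent_dim, flat),
                  b = numeric(config$latent_dim))
    fc_lv <- list(W = he_init(flat, config$latent_dim, flat) * 0.1,
                  b = numeric(config$latent_dim) - 2)
    fc_dec <- list(W = he_init(config$latent_dim, flat, config$latent_dim),
                   b = numeric(flat))
    dc <- c(rev(cout), 1)
    tconv <- lapply(seq_len(L), function(l) {
      list(V = he_init(dc[l], 16 * dc[l + 1], 16 * dc[l]),
           b = numeric(dc[l + 1]))
    })
    structure(list(config = config,
                   params = list(conv = conv, fc_mu = fc_mu, fc_lv = fc_lv,
                                 fc_dec = fc_dec, tconv = tconv),
                   sizes = sizes, cin = cin, cout = cout, dc = dc,
                   flat = flat, trained = FALSE, history = NULL),
              class = "chs_vae")
  })
}

leaky <- function(x, s) {
  neg <- x < 0
  x[neg] <- s * x[neg]
  x
}
dleaky <- function(x, s) {
  g <- (x >= 0) * (1 - s)
  g + s
}

vae_forward <- function(model, X, eps = NULL) {
  cf <- model$config
  p <- model$params
  L <- cf$n_conv_layers
  s <- cf$leaky_slope
  acts <- vector("list", L + 1)
  pre <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- cpp_conv_fwd(acts[[l]], p$conv[[l]]$W, p$conv[[l]]$b,
                      model$cin[l], model$sizes[l], model$sizes[l], 4L, 2L, 1L)
    pre[[l]] <- z
    acts[[l + 1]] <- leaky(z, s)
  }
  h <- acts[[L + 1]]
  mu <- h %*% p$fc_mu$W + rep(p$fc_mu$b, each = nrow(h))
  lv <- h %*% p$fc_lv$W + rep(p$fc_lv$b, each = nrow(h))
  lv <- pmin(pmax(lv, -10), 10)
  if (is.null(eps)) eps <- matrix(0, nrow(mu), ncol(mu))
  z <- mu + exp(0.5 * lv) * eps
  d0 <- z %*% p$fc_dec$W + rep(p$fc_dec$b, each = nrow(z))
  dacts <- vector("list", L + 1)
  dpre <- vector("list", L)
  dacts[[1]] <- leaky(d0, s)
  for (l in seq_len(L)) {
    sz <- model$sizes[L + 2 - l]
    zz <- cpp_tconv_fwd(dacts[[l]], p$tconv[[l]]$V, p$tconv[[l]]$b,
                        model$dc[l], sz, sz, 4L, 2L, 1L, model$dc[l + 1])
    dpre[[l]] <- zz
    dacts[[l + 1]] <- if (l < L) leaky(zz, s) else zz  # linear output
  }
  list(acts = acts, pre = pre, mu = mu, lv = lv, eps = eps, z = z, d0 = d0,
       dacts = dacts, dpre = dpre, xhat = dacts[[L + 1]])
}

vae_loss_grads <- function(model, X, fw) {
  cf <- model$config
  p <- model$params
  L <- cf$n_conv_layers
  s <- cf$leaky_slope
  N <- nrow(X)
  recon <- sum((fw$xhat - X)^2) / N
  kl <- sum(-0.5 * (1 + fw$lv - fw$mu^2 - exp(fw$lv))) / N
  g <- list(conv = vector("list", L), tconv = vector("list", L))
  dxhat <- 2 * (fw$xhat - X) / N
  dd <- dxhat
  for (l in rev(seq_len(L))) {
    if (l < L) dd <- dd * dleaky(fw$dpre[[l]], s)
    sz <- model$sizes[L + 2 - l]
    bw <- cpp_tconv_bwd(fw$dacts[[l]], p$tconv[[l]]$V, dd,
                        model$dc[l], sz, sz, 4L, 2L, 1L, model$dc[l + 1])
    g$tconv[[l]] <- list(V = bw$dV, b = as.numeric(bw$db))
    dd <- bw$dX
  }
  dd0 <- dd * dleaky(fw$d0, s)
  g$fc_dec <- list(W = t(fw$z) %*% dd0, b = colSums(dd0))
  dz <- dd0 %*% t(p$fc_dec$W)
  dmu <- dz + cf$kl_weight * fw$mu / N
  dlv <- dz * fw$eps * 0.5 * exp(0.5 * fw$lv) +
    cf$kl_weight * 0.5 * (exp(fw$lv) - 1) / N
  h <- fw$acts[[L + 1]]
  g$fc_mu <- list(W = t(h) %*% dmu, b = colSums(dmu))
  g$fc_lv <- list(W = t(h) %*% dlv, b = colSums(dlv))
  dh <- dmu %*% t(p$fc_mu$W) + dlv %*% t(p$fc_lv$W)
  for (l in rev(seq_len(L))) {
    dh <- dh * dleaky(fw$pre[[l]], s)
    bw <- cpp_conv_bwd(fw$acts[[l]], p$conv[[l]]$W, dh,
                       model$cin[l], model$sizes[l], model$sizes[l], 4L, 2L, 1L)
    g$conv[[l]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dh <- bw$dX
  }
  list(recon = recon, kl = kl,
       loss = recon + cf$kl_weight * kl, grads = g)
}

adam_init <- function(params) {
  walk <- function(p) {
    if (is.numeric(p)) return(list(m = p * 0, v = p * 0))
    lapply(p, walk)
  }
  walk(params)
}

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      mh <- s$m / (1 - b1^t)
      vh <- s$v / (1 - b2^t)
      p <- p - lr * mh / (sqrt(vh) + eps)
      return(list(p = p, s = s))
    }
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (j in keys) {
      r <- walk(p[[j]], g[[j]], s[[j]])
      p[[j]] <- r$p
      s[[j]] <- r$s
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

#' Train a convolutional VAE
#'
#' Minimizes the summed-per-image L2 reconstruction loss plus
#' `kl_weight` times the KL divergence between the diagonal Gaussian
#' posterior and a standard normal prior, with reparameterized sampling
#' during training. Cells are split into train/validation/test per the
#' config fractions; the parameters with the lowest validation loss are
#' kept.
#'
#' @param model a [build_vae()] model.
#' @param patches numeric matrix, one row per cell (`as.vector()` of the
#'   96 x 96 masked patch), or a `chs_nuclei` list.
#' @param epochs optional override of `config$epochs`.
#' @return the model with trained parameters, `history` (per-epoch train and
#'   validation losses), and `split` indices.
#' @export
train_vae <- function(model, patches, epochs = NULL) {
  stopifnot(inherits(model, "chs_vae"))
  X <- patches_matrix(patches)
  cf <- model$config
  epochs <- epochs %||% cf$epochs
  if (nrow(X) < cf$batch_size)
    stop_config("need at least batch_size = %d patches, got %d",
                cf$batch_size, nrow(X))
  with_seed(derive_seed(cf$seed, 1), {
    n <- nrow(X)
    idx <- sample.int(n)
    n_tr <- floor(cf$split_fractions[1] * n)
    n_va <- floor(cf$split_fractions[2] * n)
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(max(n_va, 1))]
    te <- setdiff(idx, c(tr, va))
    st <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params)
    hist <- data.frame(epoch = integer(0), train = numeric(0),
                       val = numeric(0))
    t_step <- 0
    ema <- model$params
    use_ema <- !is.null(cf$ema_decay)
    val_model <- model
    for (ep in seq_len(epochs)) {
      lr_ep <- cf$lr *
        if (ep > 0.85 * epochs) 1 / 9 else if (ep > 0.6 * epochs) 1 / 3 else 1
      ord <- sample(tr)
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = cf$batch_size)) {
        bi <- ord[b0:min(b0 + cf$batch_size - 1, length(ord))]
        if (length(bi) < 2) next
        Xb <- X[bi, , drop = FALSE]
        if (isTRUE(cf$augment_flips)) Xb <- flip_augment(Xb, cf$input_size)
        if ((cf$augment_shift_px %||% 0L) > 0)
          Xb <- shift_augment(Xb, cf$input_size, cf$augment_shift_px)
        eps <- matrix(rnorm(length(bi) * cf$latent_dim), length(bi))
        fw <- vae_forward(model, Xb, eps = eps)
        lg <- vae_loss_grads(model, Xb, fw)
        if (!is.finite(lg$loss))
          stop_config("non-finite loss at epoch %d (recon %.3g, kl %.3g)",
                      ep, lg$recon, lg$kl)
        t_step <- t_step + 1
        if (cf$weight_decay > 0)
          lg$grads <- add_weight_decay(lg$grads, model$params, cf$weight_decay)
        up <- adam_step(model$params, lg$grads, st, lr_ep, t_step)
        model$params <- up$p
        st <- up$s
        if (use_ema) ema <- ema_update(ema, model$params, cf$ema_decay)
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1
      }
      val_model$params <- if (use_ema) ema else model$params
      fw_va <- vae_forward(val_model, X[va, , drop = FALSE],
                           eps = matrix(0, length(va), cf$latent_dim))
      va_recon <- sum((fw_va$xhat - X[va, , drop = FALSE])^2) / length(va)
      va_kl <- sum(-0.5 * (1 + fw_va$lv - fw_va$mu^2 - exp(fw_va$lv))) / length(va)
      va_loss <- va_recon + cf$kl_weight * va_kl
      hist <- rbind(hist, data.frame(epoch = ep, train = ep_loss / max(nb, 1),
                                     val = va_loss))
      if (va_loss < best$loss)
        best <- list(loss = va_loss, params = val_model$params)
    }
    model$params <- best$params
    model$trained <- TRUE
    model$history <- hist
    model$split <- list(train = tr, val = va, test = te)
    model
  })
}

#' Encode patches to posterior means
#'
#' Deterministic evaluation-mode encoding: returns the posterior mean of
#' each cell (no sampling), the representation used by all downstream
#' clustering and spatial analysis. By default the posterior mean is
#' averaged over the eight exact square-grid symmetries of the patch (the
#' dihedral group: 90-degree rotations times mirroring). Nucleus orientation
#' is uniformly random and carries no cell-state information, but a conv
#' encoder necessarily represents it; group averaging cancels those
#' orientation components exactly while preserving all rotation/mirror
#' invariant structure (size, brightness, elongation, texture statistics).
#'
#' @param model a trained (or untrained) `chs_vae`.
#' @param patches patch matrix or `chs_nuclei` list.
#' @param average_group average over the 8 dihedral transforms (default
#'   `TRUE`); `FALSE` encodes the patch as-is.
#' @return a `chs_latent` matrix, `n_cells` x `latent_dim`.
#' @export
encode <- function(model, patches, average_group = TRUE) {
  stopifnot(inherits(model, "chs_vae"))
  X <- patches_matrix(patches)
  if (ncol(X) != model$config$input_size^2)
    stop_config("patch size mismatch: expected %d pixels, got %d",
                model$config$input_size^2, ncol(X))
  sz <- model$config$input_size
  transforms <- if (average_group) dihedral_index(sz) else
    list(seq_len(sz * sz))
  out <- matrix(0, nrow(X), model$config$latent_dim)
  for (tr in transforms) {
    out <- out + encode_raw(model, X[, tr, drop = FALSE])
  }
  out <- out / length(transforms)
  rownames(out) <- rownames(X)
  class(out) <- c("chs_latent", class(out))
  out
}

# Column index permutations realizing the 8 dihedral symmetries of an
# s x s patch stored column-major.
dihedral_index <- function(s) {
  m <- matrix(seq_len(s * s), s, s)
  rots <- list(m,
               t(m)[s:1, ],            # 90 deg
               m[s:1, s:1],            # 180 deg
               t(m)[, s:1])            # 270 deg
  out <- vector("list", 8)
  for (i in 1:4) {
    out[[i]] <- as.vector(rots[[i]])
    out[[i + 4]] <- as.vector(rots[[i]][, s:1])  # mirrored
  }
  out
}

encode_raw <- function(model, X) {
  p <- model$params
  L <- model$config$n_conv_layers
  s <- model$config$leaky_slope
  out <- matrix(NA_real_, nrow(X), model$config$latent_dim)
  step <- 512L
  for (b0 in seq(1, nrow(X), by = step)) {
    bi <- b0:min(b0 + step - 1, nrow(X))
    a <- X[bi, , drop = FALSE]
    for (l in seq_len(L)) {
      a <- leaky(cpp_conv_fwd(a, p$conv[[l]]$W, p$conv[[l]]$b,
                              model$cin[l], model$sizes[l], model$sizes[l],
                              4L, 2L, 1L), s)
    }
    out[bi, ] <- a %*% p$fc_mu$W + rep(p$fc_mu$b, each = length(bi))
  }
  out
}

#' Reconstruct patches through the VAE (posterior mean path)
#'
#' @param model trained `chs_vae`.
#' @param patches patch matrix or `chs_nuclei`.
#' @return matrix of reconstructions, same shape as the input matrix.
#' @export
reconstruct <- function(model, patches) {
  X <- patches_matrix(patches)
  fw <- vae_forward(model, X, eps = matrix(0, nrow(X), model$config$latent_dim))
  fw$xhat
}

# Random integer translation (zero fill) of flattened square patches.
shift_augment <- function(X, s, max_shift) {
  n <- nrow(X)
  dy <- sample(-max_shift:max_shift, n, replace = TRUE)
  dx <- sample(-max_shift:max_shift, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (dy[i] == 0 && dx[i] == 0) next
    m <- matrix(X[i, ], s, s)
    out <- matrix(0, s, s)
    ys <- seq_len(s) + dy[i]
    xs <- seq_len(s) + dx[i]
    vy <- ys >= 1 & ys <= s
    vx <- xs >= 1 & xs <= s
    out[ys[vy], xs[vx]] <- m[vy, vx]
    X[i, ] <- as.vector(out)
  }
  X
}

ema_update <- function(ema, params, decay) {
  walk <- function(e, p) {
    if (is.numeric(e)) return(decay * e + (1 - decay) * p)
    keys <- if (!is.null(names(e))) names(e) else seq_along(e)
    for (j in keys) e[[j]] <- walk(e[[j]], p[[j]])
    e
  }
  walk(ema, params)
}

add_weight_decay <- function(grads, params, wd) {
  walk <- function(g, p, nm) {
    if (is.numeric(g)) {
      # decay weight matrices only, not biases
      if (is.matrix(p)) g <- g + wd * p
      return(g)
    }
    keys <- if (!is.null(names(g))) names(g) else seq_along(g)
    for (j in keys) g[[j]] <- walk(g[[j]], p[[j]], j)
    g
  }
  walk(grads, params, "")
}

# Random dihedral-group transform (8 exact grid symmetries) per image.
flip_augment <- function(X, s) {
  tr <- dihedral_index(s)
  pick <- sample.int(8, nrow(X), replace = TRUE)
  for (g in 2:8) {
    sel <- pick == g
    if (any(sel)) X[sel, ] <- X[sel, tr[[g]], drop = FALSE]
  }
  X
}

#' Stack nucleus patches into a matrix
#'
#' @param patches a `chs_nuclei` list (from [extract_patches()]) or an
#'   already-stacked numeric matrix (returned unchanged).
#' @return numeric matrix, one row per nucleus.
#' @export
patches_matrix <- function(patches) {
  if (is.matrix(patches)) return(patches)
  if (inherits(patches, "chs_nuclei") || is.list(patches)) {
    X <- t(vapply(patches, function(r) as.vector(r$patch),
                  numeric(length(patches[[1]]$patch))))
    rownames(X) <- vapply(patches, function(r) as.character(r$nucleus_id),
                          character(1))
    return(X)
  }
  stop_config("cannot interpret patches input")
}
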