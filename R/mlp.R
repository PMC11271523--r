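#' Multilayer perceptron specification
#'
#' Architecture and training hyperparameters of the small MLP classifiers:
#' hidden layers with leaky rectifier activation and dropout, a linear
#' output layer, and cross-entropy loss weighted proportionally to the
#' inverse class frequency. The published designs map to `hidden =
#' c(1024, 1024, 1024)` (phenotype from latent), `c(128, 128, 128)` (cluster
#' from NMCO features) and `c(64, 64, 64)` (phenotype from co-localization).
#'
#' @param hidden integer vector of hidden sizes (default `c(64, 64, 64)`);
#'   empty for multinomial logistic regression.
#' @param dropout dropout rate after each hidden activation (default 0.5).
#' @param leaky_slope leaky-rectifier negative slope (default 0.01).
#' @param epochs full-batch training epochs (default 300).
#' @param lr Adam learning rate (default 1e-2; full-batch training on
#'   sample-level data needs a larger step than minibatch conventions).
#' @param val_fraction fraction of the training split held out for early
#'   stopping (default 0.15; early stopping is skipped when the resulting
#'   validation set would have fewer than 4 samples).
#' @param patience early-stopping patience in epochs (default 40).
#' @param seed RNG seed.
#' @return object of class `chs_mlp_spec`.
#' @export
mlp_spec <- function(hidden = c(64, 64, 64), dropout = 0.5,
                     leaky_slope = 0.01, epochs = 300, lr = 1e-2,
                     val_fraction = 0.15, patience = 40, seed = 1L) {
  if (length(hidden) && any(hidden <= 0)) stop_config("hidden sizes must be positive")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  structure(list(hidden = hidden, dropout = dropout,
                 leaky_slope = leaky_slope, epochs = epochs, lr = lr,
                 val_fraction = val_fraction, patience = patience,
                 seed = as.integer(seed)),
            class = "chs_mlp_spec")
}

#' Inverse-class-frequency loss weights
#'
#' @param y factor of class labels.
#' @return numeric vector per class, proportional to 1 / class count,
#'   normalized to mean 1.
#' @export
class_weights <- function(y) {
  counts <- table(y)
  w <- 1 / as.numeric(counts)
  w <- w / mean(w)
  names(w) <- names(counts)
  w
}

mlp_forward <- function(params, X, slope, dropout = 0, train = FALSE) {
  acts <- list(X)
  pre <- list()
  masks <- list()
  nl <- length(params)
  A <- X
  for (l in seq_len(nl)) {
    Z <- A %*% params[[l]]$W + rep(params[[l]]$b, each = nrow(A))
    pre[[l]] <- Z
    if (l < nl) {
      A <- leaky(Z, slope)
      if (train && dropout > 0) {
        m <- matrix(stats::rbinom(length(A), 1, 1 - dropout),
                    nrow(A)) / (1 - dropout)
        A <- A * m
        masks[[l]] <- m
      }
      acts[[l + 1]] <- A
    } else {
      A <- Z
    }
  }
  list(logits = A, acts = acts, pre = pre, masks = masks)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train an MLP classifier
#'
#' Full-batch Adam on weighted cross-entropy. If `splits` provides a test
#' set, the test confusion matrix is computed after training. Early
#' stopping uses a small validation carve-out of the training split when it
#' is large enough, otherwise the full epoch budget is used.
#'
#' @param X numeric feature matrix.
#' @param y factor (or coercible) of class labels.
#' @param spec a [mlp_spec()].
#' @param splits optional list with integer `train` and `test` indices
#'   (default: train on everything, no test confusion).
#' @return object of class `chs_mlp`: parameters, class levels, spec, and
#'   (when a test split was given) `confusion` and `test_pred`.
#' @export
train_mlp <- function(X, y, spec = mlp_spec(), splits = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(splits)) splits <- list(train = seq_len(nrow(X)), test = integer(0))
  ytr <- droplevels(y[splits$train])
  if (nlevels(ytr) < 2) stop_config("need >= 2 classes in training split")
  missing_cl <- setdiff(levels(y), levels(ytr))
  if (length(missing_cl) && length(splits$test)) {
    te_cl <- unique(as.character(y[splits$test]))
    bad <- intersect(missing_cl, te_cl)
    if (length(bad))
      warning(sprintf("class(es) %s absent from training split",
                      paste(bad, collapse = ", ")))
  }
  lev <- levels(ytr)
  with_seed(spec$seed, {
    Xtr <- X[splits$train, , drop = FALSE]
    yi <- as.integer(ytr)
    w_class <- class_weights(ytr)
    sizes <- c(ncol(X), spec$hidden, length(lev))
    params <- lapply(seq_len(length(sizes) - 1), function(l) {
      list(W = he_init(sizes[l], sizes[l + 1], sizes[l]),
           b = numeric(sizes[l + 1]))
    })
    n_tr <- nrow(Xtr)
    n_val <- floor(spec$val_fraction * n_tr)
    use_es <- n_val >= 4
    if (use_es) {
      vi <- sample.int(n_tr, n_val)
      # keep every class in the inner training part
      if (nlevels(droplevels(ytr[-vi])) < length(lev)) use_es <- FALSE
    }
    ti <- if (use_es) setdiff(seq_len(n_tr), vi) else seq_len(n_tr)
    st <- adam_init(params)
    best <- list(loss = Inf, params = params, since = 0)
    loss_of <- function(P, idx, train = FALSE) {
      fw <- mlp_forward(P, Xtr[idx, , drop = FALSE], spec$leaky_slope,
                        spec$dropout, train = train)
      pr <- softmax_rows(fw$logits)
      wi <- w_class[yi[idx]]
      ll <- -sum(wi * log(pmax(pr[cbind(seq_along(idx), yi[idx])], 1e-12))) /
        sum(wi)
      list(loss = ll, fw = fw, pr = pr)
    }
    for (ep in seq_len(spec$epochs)) {
      fwl <- loss_of(params, ti, train = TRUE)
      fw <- fwl$fw
      wi <- w_class[yi[ti]]
      dlogits <- fwl$pr
      dlogits[cbind(seq_along(ti), yi[ti])] <-
        dlogits[cbind(seq_along(ti), yi[ti])] - 1
      dlogits <- dlogits * wi / sum(wi)
      grads <- vector("list", length(params))
      dA <- dlogits
      for (l in rev(seq_along(params))) {
        grads[[l]] <- list(W = t(fw$acts[[l]]) %*% dA, b = colSums(dA))
        if (l > 1) {
          dA <- dA %*% t(params[[l]]$W)
          if (length(fw$masks) >= l - 1 && !is.null(fw$masks[[l - 1]]))
            dA <- dA * fw$masks[[l - 1]]
          dA <- dA * dleaky(fw$pre[[l - 1]], spec$leaky_slope)
        }
      }
      up <- adam_step(params, grads, st, spec$lr, ep)
      params <- up$p
      st <- up$s
      if (use_es) {
        vl <- loss_of(params, vi)$loss
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, params = params, since = 0)
        } else {
          best$since <- best$since + 1
          if (best$since >= spec$patience) break
        }
      }
    }
    if (use_es) params <- best$params
    model <- structure(list(params = params, levels = lev, spec = spec,
                            class_weights = w_class),
                       class = "chs_mlp")
    if (length(splits$test)) {
      pred <- predict(model, X[splits$test, , drop = FALSE])
      truth <- factor(as.character(y[splits$test]), levels = levels(y))
      model$test_pred <- pred
      model$confusion <- table(truth = truth,
                               pred = factor(pred, levels = levels(y)))
    }
    model
  })
}

#' @export
predict.chs_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fw <- mlp_forward(object$params, as.matrix(newdata),
                    object$spec$leaky_slope, dropout = 0, train = FALSE)
  pr <- softmax_rows(fw$logits)
  colnames(pr) <- object$levels
  if (type == "prob") return(pr)
  object$levels[max.col(pr, ties.method = "first")]
}
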