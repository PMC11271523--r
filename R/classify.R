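#' Phenotypic-category grouping for classification
#'
#' Default grouping merges "DCIS" (P5) with "DCIS and breast tissue" (P6)
#' and "DCIS with early infiltration" (P7) with "Micropapillary DCIS with
#' early infiltration" (P8). The stage map used for the six stage-transition
#' error types covers non-tumor (P0, P1, P3), DCIS (P5-P8) and invasive
#' (P9, P10); P2 and P4 map to `NA` and are excluded from stage-level error
#' summaries (but still classified).
#'
#' @param extra_merges optional named character vector mapping additional
#'   category codes onto merged labels.
#' @return object of class `chs_grouping`: `map` (category -> class label)
#'   and `stage` (category -> stage or NA).
#' @export
category_grouping <- function(extra_merges = NULL) {
  codes <- paste0("P", 0:10)
  map <- setNames(codes, codes)
  map[c("P5", "P6")] <- "P5+P6"
  map[c("P7", "P8")] <- "P7+P8"
  if (!is.null(extra_merges)) map[names(extra_merges)] <- extra_merges
  stage <- setNames(rep(NA_character_, 11), codes)
  stage[c("P0", "P1", "P3")] <- "non-tumor"
  stage[c("P5", "P6", "P7", "P8")] <- "DCIS"
  stage[c("P9", "P10")] <- "IDC"
  structure(list(map = map, stage = stage), class = "chs_grouping")
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: all of that patient's samples are held out, a
#' classifier is retrained on the remaining samples (per-fold seeds derived
#' from the spec seed), and predictions are pooled. Training and test
#' patient sets are programmatically asserted disjoint in every fold.
#'
#' @param X samples x features matrix.
#' @param categories per-sample category codes (P0-P10) or ready class
#'   labels.
#' @param patient_ids per-sample patient identifiers.
#' @param spec a [mlp_spec()].
#' @param grouping a [category_grouping()], or `NULL` to use `categories`
#'   as-is.
#' @return object of class `chs_cv`: `predictions` (per-sample data.frame),
#'   `confusion` (raw counts, rows = truth), `confusion_norm`
#'   (row-normalized), `accuracy`, `per_class_error`, `error_types`
#'   (stage-transition tallies), `excluded_classes`.
#' @export
lopo_cv <- function(X, categories, patient_ids, spec = mlp_spec(),
                    grouping = category_grouping()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(categories) == n, length(patient_ids) == n)
  if (!is.null(grouping)) {
    cls <- unname(grouping$map[as.character(categories)])
    cls[is.na(cls)] <- as.character(categories)[is.na(cls)]
    stage <- unname(grouping$stage[as.character(categories)])
  } else {
    cls <- as.character(categories)
    stage <- rep(NA_character_, n)
  }
  patients <- unique(patient_ids)
  if (length(patients) < 2) stop_config("need >= 2 patients")
  y <- factor(cls)
  cls_patients <- tapply(patient_ids, cls, function(p) length(unique(p)))
  excluded <- names(cls_patients)[cls_patients < 2]
  if (length(excluded))
    warning(sprintf("class(es) confined to a single patient: %s",
                    paste(excluded, collapse = ", ")))
  preds <- rep(NA_character_, n)
  fold <- rep(NA_integer_, n)
  for (f in seq_along(patients)) {
    te <- which(patient_ids == patients[f])
    tr <- which(patient_ids != patients[f])
    stopifnot(length(intersect(patient_ids[tr], patient_ids[te])) == 0)
    sp <- spec
    sp$seed <- derive_seed(spec$seed, f)
    m <- suppressWarnings(
      train_mlp(X, y, sp, splits = list(train = tr, test = te)))
    preds[te] <- m$test_pred
    fold[te] <- f
  }
  stopifnot(!anyNA(preds))
  truth <- factor(cls, levels = levels(y))
  predf <- factor(preds, levels = levels(y))
  conf <- table(truth = truth, pred = predf)
  conf_norm <- sweep(conf, 1, pmax(rowSums(conf), 1), "/")
  per_class_err <- 1 - diag(as.matrix(conf)) / pmax(rowSums(conf), 1)
  per_class_err[names(per_class_err) %in% excluded] <- NA
  # six stage-transition error types (plus within-stage misclassification)
  pred_stage <- stage[match(preds, cls)]
  err_types <- error_type_table(stage, pred_stage, cls, preds)
  structure(list(
    predictions = data.frame(patient_id = patient_ids, truth = cls,
                             pred = preds, stage = stage, fold = fold,
                             correct = cls == preds, stringsAsFactors = FALSE),
    confusion = conf, confusion_norm = conf_norm,
    accuracy = mean(cls == preds),
    per_class_error = per_class_err,
    error_types = err_types, excluded_classes = excluded
  ), class = "chs_cv")
}

error_type_table <- function(true_stage, pred_stage, truth, pred) {
  stages <- c("non-tumor", "DCIS", "IDC")
  types <- expand.grid(from = stages, to = stages,
                       stringsAsFactors = FALSE)
  types <- types[types$from != types$to, ]
  counts <- mapply(function(a, b)
    sum(!is.na(true_stage) & !is.na(pred_stage) &
          true_stage == a & pred_stage == b),
    types$from, types$to)
  denom <- vapply(types$from, function(a) sum(true_stage == a, na.rm = TRUE),
                  numeric(1))
  within_err <- sum(!is.na(true_stage) & !is.na(pred_stage) &
                      true_stage == pred_stage & truth != pred)
  data.frame(type = paste(types$from, "->", types$to),
             count = as.integer(counts),
             rate = ifelse(denom > 0, counts / denom, NA),
             row.names = NULL)
}

#' Co-localization ablation study
#'
#' Reruns leave-one-patient-out classification after removing all cells of
#' each cluster in turn from the co-localization computation (7 x 7 matrix
#' plus density), alongside the "None" baseline with all clusters.
#'
#' @param cohort `chs_cohort` (or list of samples, see
#'   [cohort_representations()]).
#' @param spec a [mlp_spec()].
#' @param grouping a [category_grouping()] or `NULL`.
#' @param radius_um neighborhood radius (default 25.9 um).
#' @param labels_list optional per-sample label override.
#' @return list with `results` (named list of `chs_cv`, "None" and "0".."7")
#'   and `summary` (data.frame of ablation x overall error and
#'   stage-transition error counts).
#' @export
ablation_study <- function(cohort, spec = mlp_spec(),
                           grouping = category_grouping(),
                           radius_um = 25.9, labels_list = NULL) {
  run <- function(ablate) {
    rep <- cohort_representations(cohort, radius_um = radius_um,
                                  ablate = ablate, labels_list = labels_list)
    lopo_cv(rep$X, rep$meta$category, rep$meta$patient_id, spec, grouping)
  }
  results <- list(None = run(NULL))
  for (k in 0:7) results[[as.character(k)]] <- run(k)
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    cv <- results[[nm]]
    data.frame(ablated = nm, error = 1 - cv$accuracy,
               t(setNames(cv$error_types$count, cv$error_types$type)),
               check.names = FALSE)
  }))
  list(results = results, summary = summary)
}

#' Misclassification contrast analysis
#'
#' For each requested error type ("true -> predicted" class pair), compares
#' the mean co-localization matrix of the misclassified samples to that of
#' the correctly classified samples of the true class, elementwise as log2
#' fold change; likewise for the per-cluster cell proportions ("%cluster").
#'
#' @param cv a `chs_cv` result.
#' @param matrices named list (by sample order of `cv$predictions`) or list
#'   of k x k observed co-localization matrices per sample.
#' @param proportions matrix samples x k of per-cluster cell proportions.
#' @param pairs optional data.frame with `from`, `to` class labels; default:
#'   every observed misclassification pair.
#' @return named list keyed `"from -> to"`; each element has
#'   `log2fc_matrix`, `log2fc_proportions`, `n_mis`, `n_correct`. Undefined
#'   entries (zero denominators) are `NA`.
#' @export
misclassification_contrast <- function(cv, matrices, proportions,
                                       pairs = NULL) {
  pr <- cv$predictions
  if (is.null(pairs)) {
    mis <- pr[pr$truth != pr$pred, c("truth", "pred")]
    pairs <- unique(data.frame(from = mis$truth, to = mis$pred,
                               stringsAsFactors = FALSE))
  }
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$from[r]; b <- pairs$to[r]
    mis_i <- which(pr$truth == a & pr$pred == b)
    cor_i <- which(pr$truth == a & pr$pred == a)
    if (!length(mis_i) || !length(cor_i)) next
    mean_mat <- function(idx) {
      Reduce(`+`, lapply(matrices[idx], function(m) {
        m[is.na(m)] <- 0
        m
      })) / length(idx)
    }
    m_mis <- mean_mat(mis_i)
    m_cor <- mean_mat(cor_i)
    lfc <- log2(m_mis / m_cor)
    lfc[!is.finite(lfc)] <- NA
    p_mis <- colMeans(proportions[mis_i, , drop = FALSE])
    p_cor <- colMeans(proportions[cor_i, , drop = FALSE])
    pfc <- log2(p_mis / p_cor)
    pfc[!is.finite(pfc)] <- NA
    out[[paste(a, "->", b)]] <- list(log2fc_matrix = lfc,
                                     log2fc_proportions = pfc,
                                     n_mis = length(mis_i),
                                     n_correct = length(cor_i))
  }
  out
}

#' Classifier restricted to a category subset
#'
#' Restricts the cohort to the requested categories (e.g. hyperplasia and
#' DCIS variants) and runs leave-one-patient-out CV on that subset only.
#'
#' @param X samples x features matrix.
#' @param categories,patient_ids per-sample metadata.
#' @param subset character vector of category codes to keep.
#' @param spec a [mlp_spec()].
#' @param grouping a [category_grouping()] or `NULL`.
#' @return `chs_cv` for the subset.
#' @export
subset_classifier <- function(X, categories, patient_ids, subset,
                              spec = mlp_spec(),
                              grouping = category_grouping()) {
  keep <- categories %in% subset
  if (!any(keep)) stop_config("subset matches no samples")
  cls <- if (!is.null(grouping)) {
    v <- unname(grouping$map[as.character(categories[keep])])
    v[is.na(v)] <- as.character(categories[keep])[is.na(v)]
    v
  } else as.character(categories[keep])
  if (length(unique(cls)) < 2)
    stop_config("subset task is degenerate: only one class")
  lopo_cv(X[keep, , drop = FALSE], categories[keep], patient_ids[keep],
          spec, grouping)
}

#' Multinomial logistic-regression baseline
#'
#' The same leave-one-patient-out machinery with a linear (no hidden layer)
#' softmax model, provided as the comparison baseline for the MLP
#' classifiers.
#'
#' @inheritParams lopo_cv
#' @return `chs_cv`.
#' @export
logistic_baseline_cv <- function(X, categories, patient_ids,
                                 grouping = category_grouping(),
                                 spec = mlp_spec()) {
  sp <- spec
  sp$hidden <- integer(0)
  sp$dropout <- 0
  lopo_cv(X, categories, patient_ids, sp, grouping)
}
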