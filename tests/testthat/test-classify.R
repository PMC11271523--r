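test_that("inverse-frequency class weights are proportional to 1/count", {
  y <- factor(rep(c("a", "b"), c(10, 40)))
  w <- class_weights(y)
  expect_equal(unname(w["a"] / w["b"]), 4)
  expect_equal(mean(w), 1)
})

test_that("MLP separates linearly separable classes and validates input", {
  set.seed(18)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 6), 50))
  y <- rep(c("lo", "hi"), each = 50)
  tr <- c(1:35, 51:85)
  m <- train_mlp(X, y, mlp_spec(hidden = c(16), dropout = 0.2, epochs = 300,
                                seed = 1),
                 splits = list(train = tr, test = setdiff(1:100, tr)))
  expect_equal(sum(diag(m$confusion)), 30)   # zero test error
  expect_error(train_mlp(X, rep("one", 100), mlp_spec()), "2 classes")
  expect_error(mlp_spec(dropout = 1), "dropout")
  expect_error(mlp_spec(hidden = c(0, 4)), "positive")
})

test_that("an uninformative task yields near-chance accuracy", {
  set.seed(19)
  X <- matrix(rnorm(300 * 5), 300)             # identical class distributions
  y <- rep(c("p", "q"), each = 150)
  tr <- sample(300, 200)
  m <- suppressWarnings(
    train_mlp(X, y, mlp_spec(hidden = c(16, 16), epochs = 150, seed = 2),
              splits = list(train = tr, test = setdiff(1:300, tr))))
  acc <- sum(diag(m$confusion)) / sum(m$confusion)
  expect_lt(acc, 0.75)
})

test_that("default grouping merges the printed category pairs", {
  g <- category_grouping()
  expect_equal(unname(g$map["P5"]), unname(g$map["P6"]))
  expect_equal(unname(g$map["P7"]), unname(g$map["P8"]))
  expect_false(g$map["P0"] == g$map["P1"])
  expect_equal(unname(g$stage[c("P0", "P1", "P3")]), rep("non-tumor", 3))
  expect_equal(unname(g$stage[c("P9", "P10")]), rep("IDC", 3)[1:2])
  expect_true(is.na(g$stage["P2"]) && is.na(g$stage["P4"]))
})

make_sep_cohort_features <- function(n_pat = 6, sps = 2, seed = 23) {
  # patient-structured features with a class-dependent mean
  chromastate:::with_seed(seed, {
    cats <- rep(c("P0", "P10"), length.out = n_pat)
    rows <- list(); meta <- list()
    for (p in seq_len(n_pat)) for (s in seq_len(sps)) {
      mu <- if (cats[p] == "P0") 0 else 5
      rows[[length(rows) + 1]] <- rnorm(6, mu)
      meta[[length(meta) + 1]] <- data.frame(
        patient_id = sprintf("PT%02d", p), category = cats[p])
    }
    list(X = do.call(rbind, rows), meta = do.call(rbind, meta))
  })
}

test_that("leave-one-patient-out CV predicts each sample once, no leakage", {
  d <- make_sep_cohort_features(6, 2)
  cv <- lopo_cv(d$X, d$meta$category, d$meta$patient_id,
                mlp_spec(hidden = c(8), dropout = 0.2, epochs = 400, seed = 5))
  expect_s3_class(cv, "chs_cv")
  expect_equal(nrow(cv$predictions), 12)
  expect_equal(sum(cv$confusion), 12)
  expect_equal(length(unique(cv$predictions$fold)), 6)
  # a patient's samples share a fold and never straddle train/test
  for (f in unique(cv$predictions$fold)) {
    pats <- unique(cv$predictions$patient_id[cv$predictions$fold == f])
    expect_length(pats, 1)
  }
  expect_gt(cv$accuracy, 0.9)                 # separable by construction
  expect_error(lopo_cv(d$X, d$meta$category, rep("PT01", 12), mlp_spec()),
               "2 patients")
  # two patients (each holding both classes) -> exactly two folds
  set.seed(77)
  X2 <- rbind(matrix(rnorm(12, 0), 2), matrix(rnorm(12, 5), 2),
              matrix(rnorm(12, 0), 2), matrix(rnorm(12, 5), 2))
  meta2 <- data.frame(patient_id = rep(c("PT01", "PT02"), each = 4),
                      category = rep(c("P0", "P0", "P10", "P10"), 2))
  cv2 <- suppressWarnings(
    lopo_cv(X2, meta2$category, meta2$patient_id,
            mlp_spec(hidden = c(8), dropout = 0.2, epochs = 200, seed = 5)))
  expect_equal(length(unique(cv2$predictions$fold)), 2)
  expect_equal(nrow(cv2$predictions), 8)
})

test_that("classes confined to one patient are warned and excluded", {
  d <- make_sep_cohort_features(5, 2)     # P0 x3 patients, P10 x2
  d$meta$category[d$meta$patient_id == "PT05"] <- "P4"
  expect_warning(
    cv <- lopo_cv(d$X, d$meta$category, d$meta$patient_id,
                  mlp_spec(hidden = c(8), dropout = 0.2, epochs = 120,
                           seed = 3)),
    "single patient")
  expect_true(is.na(cv$per_class_error["P4"]))
})

test_that("error types are keyed by stage transitions", {
  d <- make_sep_cohort_features(6, 2)
  cv <- lopo_cv(d$X, d$meta$category, d$meta$patient_id,
                mlp_spec(hidden = c(8), dropout = 0.2, epochs = 300, seed = 5))
  expect_equal(nrow(cv$error_types), 6)
  expect_true(all(grepl("->", cv$error_types$type)))
})

test_that("misclassification contrast computes log2 fold changes", {
  pr <- data.frame(patient_id = "x", truth = rep(c("A", "B"), each = 4),
                   pred = c("A", "A", "B", "A", "B", "B", "B", "B"),
                   stage = NA, fold = 1,
                   correct = c(TRUE, TRUE, FALSE, TRUE, rep(TRUE, 4)))
  cv <- structure(list(predictions = pr), class = "chs_cv")
  base <- matrix(0.125, 2, 2)
  mats <- rep(list(base), 8)
  props <- matrix(0.5, 8, 2)
  # identical groups: all log2 fold changes are 0
  out <- misclassification_contrast(cv, mats, props)
  expect_equal(unname(out[["A -> B"]]$log2fc_matrix), matrix(0, 2, 2))
  expect_equal(unname(out[["A -> B"]]$log2fc_proportions), c(0, 0))
  # doubled cluster-2 proportion in the misclassified sample
  props2 <- props; props2[3, 2] <- 1.0   # row 3 is the A->B misclassified
  out2 <- misclassification_contrast(cv, mats, props2)
  expect_equal(unname(out2[["A -> B"]]$log2fc_proportions[2]), 1)
  expect_named(out2, "A -> B")
})

test_that("subset classifier isolates the requested categories", {
  d <- make_sep_cohort_features(8, 2, seed = 29)
  d$meta$category <- rep(c("P3", "P5", "P7", "P9"), each = 4)
  # planted separation between all four
  d$X <- d$X + 2 * match(d$meta$category, c("P3", "P5", "P7", "P9"))
  cv <- subset_classifier(d$X, d$meta$category, d$meta$patient_id,
                          subset = c("P3", "P5"),
                          spec = mlp_spec(hidden = c(8), dropout = 0.2,
                                          epochs = 300, seed = 2))
  expect_equal(sum(cv$confusion), 8)   # only the subset samples predicted
  expect_error(subset_classifier(d$X, d$meta$category, d$meta$patient_id,
                                 subset = "P3"), "one class")
  expect_error(subset_classifier(d$X, d$meta$category, d$meta$patient_id,
                                 subset = "P99"), "no samples")
})

test_that("logistic baseline runs through identical CV machinery", {
  d <- make_sep_cohort_features(6, 2)
  cv <- logistic_baseline_cv(d$X, d$meta$category, d$meta$patient_id)
  expect_s3_class(cv, "chs_cv")
  expect_gt(cv$accuracy, 0.9)
})

test_that("ablation study returns a baseline plus eight ablations", {
  coh <- memo("abl_cohort", {
    generate_cohort(cohort_config(
      n_patients = 4, samples_per_patient = 2,
      categories = c("P0", "P10"), cells_per_sample = 25,
      image_size_px = 220, seed = 61))
  })
  res <- suppressWarnings(ablation_study(
    coh, spec = mlp_spec(hidden = c(8), epochs = 60, seed = 7),
    grouping = NULL, radius_um = 15))
  expect_equal(nrow(res$summary), 9)
  expect_equal(res$summary$ablated, c("None", as.character(0:7)))
  # ablating a cluster absent from the cohort changes nothing: the 7x7
  # representation equals the 8x8 one with the empty row/column dropped
  labs <- lapply(coh, function(s) {
    l <- s$nuclei$state
    l[l == 4L] <- 3L          # remove state 4 entirely
    l
  })
  rep8 <- cohort_representations(coh, labels_list = labs, radius_um = 15)
  rep7 <- cohort_representations(coh, labels_list = labs, radius_um = 15,
                                 ablate = 4)
  keep <- !grepl("state4", colnames(rep8$X))
  expect_equal(unname(rep8$X[, keep]), unname(rep7$X), tolerance = 1e-12)
})
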