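test_that("closed-form features are recovered on disks and ellipses", {
  d <- make_disk(20)
  f <- compute_features(d$patch, d$mask)
  expect_lt(abs(f[["size_area"]] / (pi * 400) - 1), 0.02)
  expect_lt(abs(f[["shape_factor"]] - 1), 0.05)
  expect_lt(abs(f[["shape_aspect_ratio"]] - 1), 0.05)
  expect_lt(abs(f[["radius_mean"]] - 20.5) / 20.5, 0.05)
  expect_lt(f[["radius_cv"]], 0.03)
  expect_lt(abs(f[["curv_mean"]] - 1 / 20.5) / (1 / 20.5), 0.25)

  e <- make_ellipse(28, 14)
  fe <- compute_features(e$patch, e$mask)
  expect_lt(abs(fe[["shape_aspect_ratio"]] / 2 - 1), 0.10)
  expect_gt(fe[["shape_factor"]], f[["shape_factor"]])  # less circular

  # uniform intensity: no texture contrast, no intensity spread
  expect_equal(f[["tex_contrast"]], 0)
  expect_equal(f[["int_sd"]], 0)
  expect_error(compute_features(d$patch, d$mask * 0), "empty")
})

test_that("features scale correctly with object size", {
  f1 <- compute_features(make_disk(10)$patch, make_disk(10)$mask)
  f2 <- compute_features(make_disk(20)$patch, make_disk(20)$mask)
  expect_lt(abs(f2[["size_area"]] / f1[["size_area"]] - 4), 0.25)
  expect_lt(abs(f2[["size_perimeter"]] / f1[["size_perimeter"]] - 2), 0.15)
  # scale-invariant moments are (approximately) unchanged
  expect_lt(abs(f2[["mom_hu1"]] - f1[["mom_hu1"]]) / f1[["mom_hu1"]], 0.05)
})

test_that("feature table covers the documented families", {
  pp <- probe_patches(2)
  ft <- feature_table(pp$patches[1:8])
  expect_gte(ncol(ft), 40)
  fams <- unique(attr(ft, "families"))
  expect_true(all(c("size", "radius", "shape", "curv", "mom", "tex", "int",
                    "chrom") %in% fams))
  expect_false(anyDuplicated(colnames(ft)) > 0)
  expect_true(all(is.finite(ft)))
  # heterochromatin fraction responds to planted heterogeneity
  het_lo <- ft[pp$labels[1:8] %in% c(0), "chrom_hetero_euchro_ratio"]
  het_hi <- ft[pp$labels[1:8] %in% c(1), "chrom_hetero_euchro_ratio"]
  if (length(het_lo) && length(het_hi)) expect_gt(mean(het_hi), mean(het_lo))
})

test_that("BH step-up matches a hand-computed oracle", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.05)
  # brute-force step-up oracle: adj_i = min_{j >= i} (m * p_(j) / j), capped
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_oracle(p), p.adjust(p, "BH"))
  expect_equal(bh_oracle(p), c(0.005, 0.025, 1 / 30, 0.05, 0.05),
               tolerance = 1e-12)
  set.seed(8)
  p2 <- runif(100)
  expect_equal(bh_oracle(p2), p.adjust(p2, "BH"))
})

sim_features <- function(n_per = 120, n_feat = 20, shift_feat = NULL,
                         shift_sd = 0, seed = 1) {
  chromastate:::with_seed(seed, {
    n <- n_per * 2
    X <- matrix(abs(rnorm(n * n_feat, mean = 5)), n, n_feat)
    colnames(X) <- paste0("f", seq_len(n_feat))
    labels <- rep(0:1, each = n_per)
    if (!is.null(shift_feat)) {
      X[labels == 1, shift_feat] <- X[labels == 1, shift_feat] + shift_sd
    }
    class(X) <- c("chs_feature_table", class(X))
    list(X = X, labels = labels)
  })
}

test_that("cluster feature testing controls the null and finds planted shifts", {
  # permuted-label null: selection is (near) empty at FDR 0.01
  null <- sim_features(150, 25, seed = 10)
  st <- test_cluster_features(null$X, sample(null$labels))
  expect_true(all(st$p_adj >= st$p, na.rm = TRUE))
  sel <- select_significant(st)
  expect_lte(length(sel), 1)

  # a planted 2-SD shift at n = 200/cluster is selected
  pow <- sim_features(200, 20, shift_feat = 3, shift_sd = 2, seed = 11)
  st2 <- test_cluster_features(pow$X, pow$labels)
  sel2 <- select_significant(st2)
  expect_true("f3" %in% sel2)

  # AND semantics: passing significance but failing the fold-change gate
  row <- st2[st2$feature == "f3" & st2$cluster == 1, ]
  expect_true(row$p_adj < 0.01 && row$fold_change > 1.2)
  sel_strict <- select_significant(st2, fc_low = 0.01, fc_high = 100)
  expect_false("f3" %in% sel_strict)

  # zero-variance features are excluded with a warning
  bad <- null$X; bad[, 5] <- 1
  expect_warning(test_cluster_features(bad, null$labels), "zero-variance")
})

test_that("both readings of the magnitude gate are available", {
  pow <- sim_features(200, 10, shift_feat = 2, shift_sd = 2, seed = 12)
  st <- test_cluster_features(pow$X, pow$labels)
  s1 <- select_significant(st, z_rule = "cluster_z")
  s2 <- select_significant(st, z_rule = "global_mean")
  expect_true("f2" %in% s1)
  expect_true("f2" %in% s2)  # raw means ~5 > 0.5
})

test_that("correlation grouping forms components and a remainder group", {
  set.seed(13)
  n <- 300
  base1 <- rnorm(n); base2 <- rnorm(n)
  X <- cbind(A = base1, B = base1 + rnorm(n, sd = 0.3),
             C = base1 + rnorm(n, sd = 0.45), D = rnorm(n),
             E = base2, F = base2 + rnorm(n, sd = 0.3))
  stopifnot(cor(X[, "A"], X[, "B"]) > 0.8, cor(X[, "C"], X[, "D"]) < 0.5)
  gr <- group_features(colnames(X), X, corr_threshold = 0.8)
  g <- setNames(gr$group, gr$feature)
  expect_equal(g[["A"]], g[["B"]])
  expect_equal(g[["E"]], g[["F"]])
  expect_false(g[["A"]] == g[["E"]])
  expect_equal(unname(g[["D"]]), attr(gr, "remainder_id"))
  # exclusive threshold 1: everything is a singleton -> all remainder
  gr1 <- group_features(colnames(X), X, corr_threshold = 1)
  expect_true(all(gr1$group == attr(gr1, "remainder_id")))
  expect_equal(attr(gr1, "remainder_id"), 1L)
  # grouping is stable across thresholds 0.75-0.85 for clear blocks
  for (thr in c(0.75, 0.8, 0.85)) {
    gi <- group_features(colnames(X), X, corr_threshold = thr)
    gg <- setNames(gi$group, gi$feature)
    expect_equal(gg[["A"]], gg[["B"]])
    expect_false(gg[["A"]] == gg[["E"]])
  }
  expect_error(group_features(character(0), X), "no selected")
})

test_that("planted monotone size trend is detected by the feature pipeline", {
  set.seed(14)
  recs <- list(); states <- integer(0)
  for (s in 0:7) for (i in 1:12) {
    r <- render_nucleus(s)
    recs[[length(recs) + 1]] <- list(nucleus_id = length(recs) + 1,
                                     patch = r$patch, mask = r$mask)
    states <- c(states, s)
  }
  ft <- feature_table(recs)
  m <- tapply(ft[, "size_area"], states, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))
})
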