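test_that("duct distances follow the log-pixel calibration", {
  expect_equal(duct_log_to_um(1), exp(1) * 0.18)
  expect_equal(duct_log_to_um(5), exp(5) * 0.18)
  cents <- rbind(c(0, 0), c(0, 10), c(30, 0))
  dd <- duct_distance(cents, c(TRUE, FALSE, FALSE))
  expect_equal(dd$raw_px, c(0, 10, 30))
  expect_equal(dd$transformed, c(0, log(10), log(30)))
  expect_equal(dd$um[1], 0.18)            # inside duct: transformed 0
  # sub-pixel distances floor at 0; monotone in raw distance
  dd2 <- duct_distance(rbind(c(0, 0), c(0, 0.5), c(0, 2), c(0, 8)),
                       c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(dd2$transformed[2], 0)
  expect_true(all(diff(dd2$transformed) >= 0))
  # no in-duct cells: distances are missing, not zero
  dd3 <- duct_distance(cents, rep(FALSE, 3))
  expect_true(all(is.na(dd3$raw_px)))
})

test_that("neighborhood counts match hand geometry and the brute-force oracle", {
  # isolated cell
  expect_equal(unname(neighborhood_counts(rbind(c(5, 5)), 0L, k = 8)[1, ]),
               rep(0L, 8))
  # two cells 10 um apart within the 25.9 um radius, clusters 2 and 5
  px <- 10 / 0.18
  cents <- rbind(c(0, 0), c(0, px))
  cnt <- neighborhood_counts(cents, c(2L, 5L), radius_um = 25.9, k = 8)
  expect_equal(unname(cnt[1, ]), c(0, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(unname(cnt[2, ]), c(0, 0, 1, 0, 0, 0, 0, 0))
  # spatial index identical to the O(n^2) scan
  set.seed(15)
  cents2 <- matrix(runif(1000, 0, 600), ncol = 2)
  labs <- sample(0:7, 500, replace = TRUE)
  g <- neighborhood_counts(cents2, labs, radius_um = 20, method = "grid")
  b <- neighborhood_counts(cents2, labs, radius_um = 20, method = "brute")
  expect_identical(g, b)
})

test_that("co-localization matrix averages neighbor proportions per state", {
  # all cells share cluster 3: row 3 is the indicator of column 3
  cents <- matrix(runif(40, 0, 30), ncol = 2)
  labs <- rep(3L, 20)
  cnt <- neighborhood_counts(cents, labs, radius_um = 25.9, k = 8)
  cm <- coloc_matrix(cnt, labs)
  expect_equal(unname(cm$matrix[4, ]), c(0, 0, 0, 1, 0, 0, 0, 0))
  expect_true(all(is.na(cm$matrix[-4, ])))
  expect_equal(cm$defined, seq_len(8) == 4)

  # two-cluster checkerboard at spacing below the radius: off-diagonal rows
  gr <- expand.grid(r = seq(0, 90, by = 10), c = seq(0, 90, by = 10))
  labs2 <- as.integer((gr$r / 10 + gr$c / 10) %% 2)
  cnt2 <- neighborhood_counts(as.matrix(gr), labs2, radius_um = 2.2,
                              pixel_size_um = 0.18, k = 2)  # ~12 px radius
  cm2 <- coloc_matrix(cnt2, labs2)
  expect_gt(cm2$matrix[1, 2], 0.9)
  expect_gt(cm2$matrix[2, 1], 0.9)
  # defined rows sum to one
  expect_equal(unname(rowSums(cm2$matrix)), c(1, 1))
})

test_that("permutation null matches exhaustive enumeration on 3 cells", {
  cents <- rbind(c(0, 0), c(0, 20), c(20, 0))  # all mutually within radius
  labs <- c(0L, 0L, 1L)
  # oracle: the 3 distinct labelings of (0,0,1) over fixed positions
  perms <- list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  macc <- matrix(0, 2, 2); mcnt <- matrix(0, 2, 2)
  for (pm in perms) {
    cnt <- neighborhood_counts(cents, pm, radius_um = 25.9, k = 2)
    M <- coloc_matrix(cnt, pm)$matrix
    ok <- !is.na(M)
    macc[ok] <- macc[ok] + M[ok]; mcnt <- mcnt + ok
  }
  oracle <- macc / mcnt
  pn <- permutation_null(cents, labs, n_shuffles = 2000, k = 2, seed = 9)
  expect_lt(max(abs(pn$null_mean - oracle)), 0.035)
  expect_error(permutation_null(cents, labs, n_shuffles = 0), "n_shuffles")
  expect_error(permutation_null(cents, rep(0L, 3), 10), "clusters")
})

test_that("exchangeable labels give fold changes near one", {
  s <- exchangeable_sample()
  labs <- s$nuclei$state
  cents <- cbind(s$nuclei$row, s$nuclei$col)
  pn <- permutation_null(cents, labs, n_shuffles = 600, radius_um = 25.9,
                         seed = 3)
  fc <- pn$fold_change[!is.na(pn$fold_change)]
  expect_gt(min(fc), 0.7)
  expect_lt(max(fc), 1.3)
  expect_lt(abs(mean(fc) - 1), 0.05)
})

test_that("co-localization is invariant to rigid motion of all centroids", {
  set.seed(16)
  cents <- matrix(runif(160, 0, 200), ncol = 2)
  labs <- sample(0:3, 80, replace = TRUE)
  cm <- coloc_matrix(neighborhood_counts(cents, labs, radius_um = 10, k = 4),
                     labs)
  th <- 0.7
  rot <- cents %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) + 35
  cm2 <- coloc_matrix(neighborhood_counts(rot, labs, radius_um = 10, k = 4),
                      labs)
  expect_equal(cm$matrix, cm2$matrix, tolerance = 1e-9)
})

test_that("sample representations have the documented layout", {
  set.seed(17)
  cents <- matrix(runif(200, 0, 300), ncol = 2)
  labs <- sample(0:7, 100, replace = TRUE)
  cm <- coloc_matrix(neighborhood_counts(cents, labs, radius_um = 25.9), labs)
  v <- sample_representation(cm, labs, area = 300^2)
  expect_length(v, 65)                                # 64 + density
  expect_equal(unname(v["cell_density"]), 100 / 300^2)
  vp <- sample_representation(cm, labs, 300^2, variant = "props")
  expect_length(vp, 9)
  vb <- sample_representation(cm, labs, 300^2, variant = "both")
  expect_length(vb, 73)
  # representation is invariant to cell order
  ord <- sample(length(labs))
  cm_o <- coloc_matrix(neighborhood_counts(cents[ord, ], labs[ord],
                                           radius_um = 25.9), labs[ord])
  expect_equal(sample_representation(cm_o, labs[ord], 300^2), v,
               tolerance = 1e-12)
})

test_that("ablated cohort representations are 7x7 plus density", {
  coh <- tiny_cohort()
  rep7 <- cohort_representations(coh, ablate = 7)
  expect_equal(ncol(rep7$X), 50)                      # 49 + density
  rep_full <- cohort_representations(coh)
  expect_equal(ncol(rep_full$X), 65)
  expect_equal(nrow(rep_full$X), length(coh))
  # radius sweep is supported across the documented band
  for (r in c(26, 60, 120)) {
    expect_silent(cohort_representations(coh[1], radius_um = r))
  }
})
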