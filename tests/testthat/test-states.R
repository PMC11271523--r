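test_that("balanced downsampling takes exactly n per category, seeded", {
  cats <- rep(c("A", "B", "C"), c(100, 50, 200))
  sel <- balanced_downsample(cats, 50, seed = 4)
  expect_length(sel, 150)
  expect_true(all(table(cats[sel]) == 50))
  expect_identical(sel, balanced_downsample(cats, 50, seed = 4))
  expect_error(balanced_downsample(cats, 60, seed = 1), "B")
  # full-scale value accepted
  expect_silent(balanced_downsample(rep("A", 30000), 24224, seed = 1))
})

make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  chromastate:::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
    list(X = X, y = rep(seq_len(nrow(centers)) - 1, each = n_per))
  })
}

test_that("well-separated blobs are partitioned exactly", {
  bl <- make_blobs(50, rbind(c(0, 0, 0), c(10, 0, 0)), sd = 0.5)
  st <- fit_topclusters(bl$X, k = 2, n_components = 3, seed = 1)
  expect_equal(adjusted_rand_index(st$labels, bl$y), 1)
  # inertia monotone in k (best of restarts)
  st4 <- fit_topclusters(bl$X, k = 4, n_components = 3, nstart = 5, seed = 1)
  expect_lte(st4$inertia, st$inertia)
  expect_error(fit_topclusters(bl$X[1:3, ], k = 8), "exceeds")
})

test_that("canonical relabeling orders clusters by the order_by statistic", {
  bl <- make_blobs(40, rbind(c(0, 0), c(6, 0), c(12, 0)), sd = 0.3)
  sizes <- c(rep(300, 40), rep(100, 40), rep(200, 40))
  st <- fit_topclusters(bl$X, k = 3, order_by = sizes, seed = 2)
  m <- tapply(sizes, st$labels, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))
})

test_that("assignment is deterministic, idempotent, and checks dimensions", {
  bl <- make_blobs(60, rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)), sd = 0.4)
  st <- fit_topclusters(bl$X, k = 3, n_components = 3, seed = 5)
  asg <- assign_states(st, bl$X)
  expect_equal(asg$cluster, st$labels)       # assign o fit is idempotent
  # a centroid maps to its own cluster
  cent_latent <- st$centroids %*% t(st$rotation) +
    matrix(st$center, nrow(st$centroids), length(st$center), byrow = TRUE)
  asg_c <- assign_states(st, cent_latent)
  expect_equal(asg_c$cluster, as.integer(rownames(st$centroids)))
  expect_error(assign_states(st, bl$X[, 1:2]), "mismatch")
})

test_that("held-out assignment matches training-set quality", {
  bl <- make_blobs(80, rbind(c(0, 0), c(7, 0), c(0, 7), c(7, 7)), sd = 0.5)
  tr <- seq_len(nrow(bl$X)) %% 2 == 1
  st <- fit_topclusters(bl$X[tr, ], k = 4, n_components = 2, seed = 3)
  ari_tr <- adjusted_rand_index(st$labels, bl$y[tr])
  ari_te <- adjusted_rand_index(assign_states(st, bl$X[!tr, ])$cluster,
                                bl$y[!tr])
  expect_lt(abs(ari_tr - ari_te), 0.1)
})

test_that("subclustering stops when siblings share category composition", {
  # cluster 0: one homogeneous Gaussian, categories mixed everywhere
  bl <- make_blobs(400, rbind(c(0, 0), c(20, 0)), sd = 0.7, seed = 6)
  cats <- rep(c("P0", "P10"), length.out = length(bl$y))
  st <- fit_topclusters(bl$X, k = 2, n_components = 2, seed = 6)
  st <- fit_subclusters(st, bl$X, cluster_id = 0, categories = cats,
                        candidate_ks = 2:4, seed = 6)
  expect_equal(st$subclusters[[1]]$n_sub, 1)
  tr <- st$subclusters[[1]]$trace
  expect_true(all(diff(tr$inertia) <= 1e-8))   # nonincreasing in k

  # a cluster made of two planted morphologies with disjoint composition
  sub <- make_blobs(100, rbind(c(0, 0), c(6, 0)), sd = 0.4, seed = 7)
  shift <- cbind(sub$X[, 1] + 40, sub$X[, 2])
  X2 <- rbind(bl$X, shift)
  cats2 <- c(cats, rep(c("P0", "P10"), each = 100))
  st2 <- fit_topclusters(X2, k = 3, n_components = 2, seed = 8)
  big <- as.integer(names(which.max(table(st2$labels[-(seq_along(cats))]))))
  st2 <- fit_subclusters(st2, X2, cluster_id = big, categories = cats2,
                         candidate_ks = 2:4, seed = 8)
  expect_equal(st2$subclusters[[big + 1]]$n_sub, 2)
  expect_error(fit_subclusters(st2, X2, big, cats2, candidate_ks = 2:10000),
               "smaller")
})

test_that("composition tables normalize along the requested axis", {
  labels <- c(3, 3, 3, 1, 2)
  groups <- c("P0", "P0", "P0", "P5", "P5")
  cm <- composition(labels, groups, normalize = "cluster")
  expect_equal(unname(colSums(cm)), rep(1, 3))
  expect_equal(unname(cm["P0", "3"]), 1)   # single category in cluster 3
  cm2 <- composition(labels, groups, normalize = "group")
  expect_equal(unname(rowSums(cm2)), rep(1, 2))
  expect_error(composition(labels, groups[1:3]), "aligned")
})

test_that("cohort composition recovers planted proportions", {
  coh <- tiny_cohort()
  tt <- cohort_truth_table(coh)
  cm <- composition(tt$state, tt$category, normalize = "group")
  planted <- attr(coh, "config")$state_proportions
  for (cat in rownames(cm)) {
    n <- sum(tt$category == cat)
    p <- planted[cat, sort(unique(tt$state)) + 1]
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(cm[cat, ] - p) < 4 * se + 0.08))
  }
})

test_that("centroid ordering starts at the root and is sorted", {
  bl <- make_blobs(30, rbind(c(0, 0), c(5, 0), c(10, 0)), sd = 0.2)
  st <- fit_topclusters(bl$X, k = 3, n_components = 2,
                        order_by = bl$X[, 1], seed = 1)
  ord <- centroid_ordering(st, root = 0)
  expect_equal(ord$cluster[1], 0)
  expect_true(all(diff(ord$distance) >= 0))
})
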