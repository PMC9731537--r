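make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
        rep(centers[i, ], each = n_per)
    }))
    list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

test_that("umap embedding has the right shape and is seed-deterministic", {
  blobs <- make_blobs(50, rbind(c(0, 0, 0), c(8, 8, 8)), seed = 2)
  e1 <- embed_umap(blobs$x, neighbours = 15, dims = 3, seed = 42)
  expect_equal(dim(e1$coords), c(100L, 3L))
  expect_true(all(is.finite(e1$coords)))
  e2 <- embed_umap(blobs$x, neighbours = 15, dims = 3, seed = 42)
  expect_equal(e1$coords, e2$coords)
})

test_that("embedding rejects parameters exceeding the sample count", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(embed_umap(x, dims = 10), "dims")
  expect_error(embed_umap(x, neighbours = 10), "neighbours")
  x[1, 1] <- NA
  expect_error(embed_umap(x), "missing")
})

test_that("well-separated blobs stay pure in the embedded space", {
  blobs <- make_blobs(100, rbind(rep(0, 8), rep(10, 8)), seed = 3)
  emb <- embed_umap(blobs$x, neighbours = 30, min_dist = 0, dims = 2,
                    seed = 7)
  # nearest-centroid purity against the generating labels
  cents <- rbind(colMeans(emb$coords[blobs$labels == 1, ]),
                 colMeans(emb$coords[blobs$labels == 2, ]))
  d1 <- rowSums(sweep(emb$coords, 2, cents[1, ])^2)
  d2 <- rowSums(sweep(emb$coords, 2, cents[2, ])^2)
  assigned <- ifelse(d1 < d2, 1, 2)
  purity <- max(mean(assigned == blobs$labels),
                mean(assigned != blobs$labels))
  expect_gte(purity, 0.95)
})

test_that("k-means respects its contracts on edge cases", {
  x <- matrix(rnorm(30), 15, 2)
  all_one <- kmeans_cluster(x, k = 1, seed = 1)
  expect_true(all(all_one$assignment == 1L))
  expect_error(kmeans_cluster(x, k = 16, seed = 1), "exceeds")
  expect_error(kmeans_cluster(x, k = 0, seed = 1), "positive")
  same1 <- kmeans_cluster(x, k = 3, seed = 5)
  same2 <- kmeans_cluster(x, k = 3, seed = 5)
  expect_identical(same1$assignment, same2$assignment)
})

test_that("k-means matches the exhaustive two-partition optimum", {
  blobs <- make_blobs(5, rbind(c(0, 0), c(6, 6)), sd = 0.8, seed = 9)
  cl <- kmeans_cluster(blobs$x, k = 2, seed = 3)
  expect_equal(attr(cl, "inertia"), best_two_partition_wss(blobs$x),
               tolerance = 1e-8)
  # assignment matches blob identity up to relabelling
  expect_equal(length(unique(cl$assignment[blobs$labels == 1])), 1L)
  expect_equal(length(unique(cl$assignment[blobs$labels == 2])), 1L)
})

test_that("k-means objective does not get worse with more restarts", {
  x <- withr::with_seed(13, matrix(rnorm(400), 200, 2))
  inertia <- vapply(c(1, 5, 25), function(ni) {
    attr(kmeans_cluster(x, k = 6, seed = 2, n_init = ni), "inertia")
  }, numeric(1))
  expect_true(all(diff(inertia) <= 1e-8))
})

test_that("information gain reproduces hand-computed values", {
  cl <- cluster_assignment(c(1, 1, 2, 2))
  tab <- feature_table(
    data.frame(aligned = c(0, 0, 1, 1),
               constant = c(5, 5, 5, 5),
               independent = c(0, 1, 0, 1)),
    kind = "categorical", block = "cfa")
  r <- rank_features_infogain(tab, cl, top_n = 3)
  scores <- setNames(r$info_gain, r$feature)
  expect_equal(unname(scores["aligned"]), 1)           # H=1, H(cond)=0
  expect_equal(unname(scores["constant"]), 0)
  expect_equal(unname(scores["independent"]), 0)
  expect_equal(r$feature[1], "aligned")
  expect_true(all(diff(r$info_gain) <= 0))             # non-increasing
  expect_true(all(r$info_gain >= 0))
})

test_that("information gain equals the mutual-information oracle", {
  for (case in 1:20) {
    withr::with_seed(case, {
      n <- sample(4:12, 1)
      cl_raw <- sample(1:3, n, replace = TRUE)
      cl_raw[1:2] <- c(1, 2)  # at least two clusters
      v <- sample(0:2, n, replace = TRUE)
      tab <- feature_table(data.frame(f = v), kind = "categorical",
                           block = "cfa")
      cl <- cluster_assignment(match(cl_raw, sort(unique(cl_raw))))
      r <- rank_features_infogain(tab, cl, top_n = 1)
      expect_equal(r$info_gain[1], mi_oracle(v, cl$assignment),
                   tolerance = 1e-12)
    })
  }
})

test_that("information gain is invariant under cluster relabelling", {
  withr::with_seed(31, {
    tab <- feature_table(data.frame(a = rnorm(60), b = rnorm(60)))
    cl <- sample(1:3, 60, replace = TRUE)
    perm <- c(3L, 1L, 2L)
    r1 <- rank_features_infogain(tab, cluster_assignment(cl), top_n = 2)
    r2 <- rank_features_infogain(tab, cluster_assignment(perm[cl]),
                                 top_n = 2)
    expect_equal(r1, r2)
  })
})

test_that("single-cluster assignments score zero with a warning", {
  tab <- feature_table(data.frame(a = c(1, 2, 3, 4)))
  expect_warning(
    r <- rank_features_infogain(tab, cluster_assignment(rep(1L, 4)),
                                top_n = 1),
    "single-cluster")
  expect_equal(r$info_gain, 0)
})

test_that("cluster naming follows the characteristic-based rule", {
  n <- 80
  tab <- withr::with_seed(41, feature_table(
    data.frame(
      gender = c(rep(1, 20), rep(0, 20), rep(c(0, 1), 20)),
      age = c(rnorm(20, 78, 1), rnorm(20, 76, 1), rnorm(20, 70, 1),
              rnorm(20, 75, 1)),
      mother_ad = c(rbinom(40, 1, 0.1), rbinom(20, 1, 0.9),
                    rbinom(20, 1, 0.1))),
    block = "sociodemo",
    kind = c("categorical", "numeric", "categorical")))
  cl <- cluster_assignment(rep(1:4, each = 20))
  labels <- label_set(c(rep("CN", 60), rep(c("AD", "MCI"), 10)))
  named <- name_clusters(cl, tab, labels)
  expect_equal(named$names, c("Male", "Female", "Young-FH", "AD"))
})

test_that("naming falls back to indexed catchall clusters", {
  tab <- feature_table(
    data.frame(gender = rep(c(0, 1), 20),
               age = rep(75, 40),
               mother_ad = rep(0, 40)),
    block = "sociodemo", kind = c("categorical", "numeric", "categorical"))
  cl <- cluster_assignment(rep(1:2, each = 20))
  labels <- label_set(rep("CN", 40))
  expect_warning(named <- name_clusters(cl, tab, labels), "duplicate")
  expect_equal(named$names, c("Catchall-NRF-1", "Catchall-NRF-2"))
})
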